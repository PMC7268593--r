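# Analysis recipe for digital holograms of isolated HL60 cell nuclei in
# suspension, recorded through the cell cycle.  Acquisition metadata
# (wavelength, pixel size, medium index) is dataset-specific and must be
# supplied by the user (interactive prompt or --set meta.<key>=<value>).

[meta]
wavelength_nm = NA
pixel_size_um = NA
medium_index = NA

[holo]
# smooth disk: unbiased spectrum, no ringing
filter_name = smooth disk
filter_size_rel = 0.333333333333333

[roi]
# approximate nucleus diameter
size_um = 7
# trimmed-maximum threshold for nuclei containing bright nucleoli
threshold = dm-nuclei
# ROIs excluded after visual inspection go here, e.g. 9.4, 12.1
ignore data =

[bg]
# skewed background phase: second-order polynomial over a wide border
roi_profile = poly2o
roi_border_px = 35

[sphere]
method = image
model = rytov-sc
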