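---
title: "Models and methods behind spherepipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spherepipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spherepipe turns raw off-axis holograms (or pre-computed phase maps) of
sparse, spherical, cell-sized objects into per-object refractive index,
radius and dry mass.  This vignette explains the models the package
implements, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic tests do and do not
demonstrate about real data.

## The measurement model

Quantitative phase imaging measures the optical path delay a specimen
imposes on transmitted light.  For an object of refractive index $n$
suspended in a medium of index $n_\mathrm{med}$, the simplest forward model
is the *projection approximation*: light travels in straight rays and the
phase is proportional to the chord length through the sphere,

$$\varphi(x, y) \;=\; \frac{2\pi}{\lambda}\,(n - n_\mathrm{med})\,
  2\sqrt{r^2 - \rho^2}, \qquad \rho \le r ,$$

with peak $\varphi_\mathrm{max} = (4\pi/\lambda)(n - n_\mathrm{med})\,r$ and
disk average $\langle\varphi\rangle = (2\pi/\lambda)(n-n_\mathrm{med})\,4r/3$.
This ignores diffraction and refraction; it is accurate for weak contrast
and small phase, and `projection_phase()` implements it evaluated at pixel
centers (rim anti-aliasing is performed by the fitting layer through
supersampling, not by the base model).

The *Rytov approximation* linearizes the complex logarithm of the field
instead of the field itself and remains accurate at substantially larger
total phase.  `rytov_field()` computes it through the Fourier diffraction
theorem: the 3-D transform of the sphere's scattering potential
$f(\mathbf r) = k_m^2\,[(n/n_\mathrm{med})^2 - 1]$ is known in closed form,

$$F(q) = k_m^2\,\chi\; 4\pi\,\frac{\sin(qR) - qR\cos(qR)}{q^3},$$

each detector frequency $(k_x, k_y)$ receives
$\hat u_B = \tfrac{i}{2k_z} F(k_x, k_y, k_z - k_m)$ with
$k_z = \sqrt{k_m^2 - k_x^2 - k_y^2}$ (evanescent components zeroed, the
standard far-field practice), and an inverse 2-D transform yields the Born
field $u_B$ backpropagated to the in-focus plane through the sphere
center.  The Rytov exponent is $\psi = u_B/u_0$; phase is
$\operatorname{Im}\psi$ and amplitude $\exp(\operatorname{Re}\psi)$.  The
field is computed on a two-fold zero-padded grid and cropped, so periodic
FFT wrap-around does not leak into fit residuals.

Two facts about this model shape the tests.  First, its normalization is
pinned analytically: in the weak-contrast limit $\operatorname{Im}\psi$
reduces exactly to the projection phase, which the test suite verifies
numerically.  Second, the scattered field is band-limited at the medium
wavenumber while the geometric projection has a sharp square-root rim, so
the *pointwise* difference between the two models never vanishes at the
rim — it saturates at a contrast-independent diffraction floor of roughly
13% of the peak for a 4 µm sphere.  The weak-scattering convergence check
therefore uses the frame RMS deviation (≈1.3% of peak, strictly decreasing
with contrast) and the pointwise maximum over the inner sphere
($\rho \le 0.95\,r$, ≈1.1%), both reported by
`weak_scatter_deviation()`.

### Independent oracles

Two independent routes validate the scattered-field engine:

* `born_integral_direct()` integrates the Born integral
  $u_s = \int G\,f\,u_0\,\mathrm d^3r'$ voxel by voxel in direct space
  (singularity handled by an equal-volume-sphere correction).  Because the
  in-focus plane cuts through the scatterer, where the direct near-field
  integral and the backpropagated far field legitimately differ, the
  comparison is made on a detector plane *beyond* the sphere, to which the
  k-space field is propagated; both fields are referenced to the incident
  wave at that plane.  Agreement is within 1% (peak-normalized) on a
  64³ voxelization and improves with refinement.
* `bpm_field()` is a multislice beam-propagation model: per-slice phase
  screens $\exp[i k_0 (n - n_\mathrm{med})\,\mathrm dz]$ alternating with
  non-paraxial angular-spectrum propagation, backpropagated to the central
  plane.  It neglects only backscattering and stays valid at arbitrary
  total phase, which makes it the package's exact reference where the
  first-order approximations break down.

## The systematic Rytov correction

Fitting the Rytov model to realistic data underestimates the index
contrast and overestimates the radius in a systematic, contrast-dependent
way.  The package compensates with an affine law in the fitted relative
contrast $x_\mathrm{fit} = n_\mathrm{fit}/n_\mathrm{med} - 1$:

$$x_\mathrm{sc} = c_{n0} + c_{n1}\,x_\mathrm{fit}, \qquad
  r_\mathrm{sc} = r_\mathrm{fit}\,(c_{r0} + c_{r1}\,x_\mathrm{fit}).$$

Identity coefficients $(0, 1, 1, 0)$ reproduce the raw fit.  The default
coefficients are produced by the in-repo harness `calibrate_rytov_sc()`:
beam-propagation reference images over $x \in [0.005, 0.05]$,
$r \in [2, 7]\,\mu m$ are fitted with the Rytov model and the affine law is
regressed with inverse-square weights so the *relative* recovery error is
equalized across the contrast range (the law is multiplicative; unweighted
least squares would sacrifice the weak-contrast end).  With the shipped
coefficients the corrected contrast recovers the truth within about 2.4%
and the radius within 0.7% across the calibration grid.

A first-order Born reference was considered and rejected for this purpose:
at the upper end of the grid the total phase reaches ~16 rad, far outside
Born validity, and the apparent "bias" it produces is dominated by the
reference's own error (strongly radius-dependent, hence not representable
by the affine law at all).  The direct-space Born integral is retained
where it is valid — as the oracle for the scattered-field implementation.
Externally sourced coefficients can be supplied through
`[sphere] sc_coefficients` in the configuration.

## Hologram reconstruction

Off-axis holograms carry the object field on a spatial-frequency carrier.
`detect_sideband()` finds the carrier as the spectral magnitude maximum
over the half-plane $k_y \ge 0$ (excluding a DC disk of radius
$\max(3, N/20)$ bins, requiring at least 5× the median spectral magnitude)
with 3×3 centroid sub-bin refinement.  `reconstruct_hologram()` isolates
the sideband with a configurable filter, shifts it to DC and inverse
transforms.  Because a centroid estimate is only accurate to a fraction of
a bin and any residual carrier error appears as a phase ramp of up to a few
radians across the field, the demodulation is refined: the
amplitude-weighted mean phase slope of the interior (the outer 12% is
excluded, where spectral leakage from the non-periodic fringes
concentrates) re-estimates the residual carrier over up to three passes.
Object-phase gradients average out over a compact object, and any genuine
background tilt this absorbs is degenerate with the carrier anyway and is
handled by the background stage in either case.

Filter types: hard `disk`, `smooth disk` (disk convolved with a Gaussian
of $\sigma = R/10$; the default, ringing-free and spectrally unbiased),
`gauss` (half-weight at $R$) and `square`.  The size is specified relative
to the carrier distance (default 1/3, the largest radius that cannot
overlap DC).  The phase sign convention makes optically denser objects
positive; `[holo] invert_phase` flips it for the opposite sideband choice.

Phase unwrapping follows the reliability-sorting approach (second-
difference reliability, region merging along a non-continuous path),
implemented in C++; the result is congruent to the input modulo $2\pi$ at
every pixel and offset-normalized so the border median lies in
$(-\pi, \pi]$.

## Background correction, detection, fitting

Smooth phase backgrounds (offset, tilt, or full second-order polynomial)
are least-squares fitted over a mask — a border frame, a phase threshold,
or their intersection — and subtracted; amplitude uses the same machinery
with division.  Polynomial design matrices use per-axis $[-1, 1]$
coordinates for conditioning at megapixel sizes; fits on model-form
surfaces are exact to $10^{-9}$.  The correction is applied twice: once
per sensor image, once per extracted ROI (default: `poly2o` over a border
of 10% of the ROI size; the published nuclei recipe widens this to 35 px).

Detection binarizes the corrected phase above a threshold — Otsu, a fixed
value, or the trimmed-maximum rule
$t = \mathrm{mean} + 0.2\,(P_{99} - \mathrm{mean})$ designed for nuclei
whose bright nucleoli defeat bimodal thresholds ($P_{99}$ is the maximum
after discarding the top 1% of values; the count-based reading reproduces
the defining example $99{\times}0 + 1{\times}10 \rightarrow t = 0.08$,
whereas an interpolated percentile would not).  Components are labeled
with 4-connectivity, holes filled before measuring, filtered by equivalent
diameter against the configured specimen size (inclusive bounds), and
returned as padded bounding boxes ordered by top-left corner so that ROI
identifiers `dataset_image.roi` are stable across reruns — the property
the `ignore data` exclusion workflow depends on.

The sphere fit minimizes the sum of squared phase residuals over
$(n, r, c_x, c_y, \varphi_0)$ with bounded Levenberg–Marquardt
(finite differences), bounds $n \in [n_\mathrm{med} - 0.05,
n_\mathrm{med} + 0.30]$, $r \in [0.3, 3]\,r_\mathrm{init}$, center inside
the ROI, offset free; termination at relative cost improvement
$< 10^{-9}$ or 250 evaluations per parameter.  Model images are rendered
on a 2× supersampled grid and bin-averaged, since sub-pixel rim coverage
otherwise biases the radius.  The initializer (`edge_estimate()`) smooths
the phase ($\sigma = 2$ px), thresholds the gradient magnitude at Otsu,
takes the rim radius as the sub-bin argmax of the radial gradient profile
(compensating the known $\approx 0.65\sigma$ inward shift the smoothing
induces), and converts the mean interior phase to an index through the
projection disk average.  The phase offset is fitted rather than pinned at
zero because residual offsets after polynomial correction are common in
real data.

Dry mass comes from the Barer relation $n = n_\mathrm{med} + \alpha c$
either integrated over the fitted sphere,
$m = \tfrac{4}{3}\pi r^3 (n - n_\mathrm{med})/\alpha$, or directly from
the phase integral, $m = \lambda\,\mathrm{px}^2 \sum\varphi/(2\pi\alpha)$;
the two agree within 1% on exact phantoms.  The refraction increment
defaults to $\alpha = 0.18\ \mathrm{mL/g}$, the conventional protein
value, is configurable, and is recorded with every output.

## The synthetic-data generator

`phantom_spec()` / `gen_sphere_qpi()` / `gen_hologram()` / `gen_dataset()`
emulate the target regime: wavelength 550 nm, pixel size 0.107 µm, medium
index 1.335, sphere radii 2.5–6.5 µm and indices 1.34–1.37 (cell-like
contrasts), a quadratic phase background of a few tenths of a radian,
off-axis fringes with 90% contrast and 1% intensity noise.  The carrier
defaults to $(1.6, 1.2)$ rad/px — fringe period ≈3 px, i.e. a carrier near
2/3 of Nyquist, the standard off-axis design that lets the 1/3-size
sideband filter span the maximal usable bandwidth.  At a lower carrier the
filter's band-limitation floor alone exceeds the 0.02 rad round-trip
budget for a 2.5 rad projection sphere, so this is a design constraint of
the instrument being emulated, not a free knob.  Datasets are written with
deterministic timestamps (1 s spacing from a fixed epoch) and a
ground-truth manifest; all randomness derives from the single seed.

What the passing tests show: the reconstruction, detection, correction and
fitting chain recovers known ground truth under realistic noise, sizes and
contrasts, deterministically.  What they do not show: robustness to
aberrations beyond a quadratic background, fixed-pattern or shot noise,
touching or non-spherical objects, defocus, or vendor file-format quirks —
none of which the generator emulates.

## Problem sizes and numerical conventions

The validation studies use 200² px projection phantoms (20 seeds, noise
0.02 rad), 160² px Rytov phantoms (5 seeds, noiseless), a 64³ voxel
direct-space Born comparison, 256² px hologram round trips and a
5-image × 3-sphere end-to-end dataset at 512² px — sizes chosen so the
whole suite exercises every claim at desk scale.  Matrices are indexed
with the first axis as $x$; pixel coordinates are 0-based with half-open
ROI bounds internally, while identifiers use 1-based image and ROI numbers.
Spectra place DC at the array center for all carrier arithmetic.  Stage
outputs are cached on content hashes of the inputs and of exactly the
configuration sections each stage depends on (convert ← meta, holo;
roi ← roi, bg; sphere ← sphere), mirroring the iterative re-run workflow.

One deliberate deviation from a conventional TIF layout: the R `tiff`
writer clamps float samples to $[0, 1]$ and cannot write per-page
description tags, so float32 pages are stored scaled with their
offset/scale and acquisition metadata in a JSON sidecar
(`<file>.meta.json`).  Round-trips preserve phase to better than
$10^{-6}$ rad for typical ranges, which the suite asserts; the files
remain ordinary multi-page TIFs for Fiji and similar tools.

## Known limitations

* The Rytov-SC coefficients are calibrated against beam propagation, not
  an exact electromagnetic solution; backscattering and polarization
  effects are outside the calibration's reach.
* No numerical refocusing: all models assume the in-focus plane passes
  through the sphere center.
* Touching objects are not split; the proprietary SID4Bio TIF dialect is
  detected and rejected, not decoded.
* The interior-slope carrier refinement assumes the object does not
  dominate the field of view; densely filled frames may need a fixed
  `[holo] sideband`.
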