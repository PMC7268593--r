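Package: spherepipe
Title: Quantitative Phase Imaging Pipeline for Spherical Cell-Sized Objects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Batch analysis of quantitative phase microscopy data of sparse,
    spherical, cell-sized objects such as suspended cells, isolated nuclei,
    microgel beads or liquid droplets.  Covers the full chain from raw
    off-axis holograms (or pre-computed phase maps) to per-object refractive
    index, radius and dry mass: automated Fourier-sideband hologram
    reconstruction with configurable filters, two-dimensional phase
    unwrapping, polynomial phase background correction, threshold-based
    region-of-interest detection, and least-squares fits of sphere
    scattering models (optical projection, Rytov approximation, and a
    systematically corrected Rytov variant).  The pipeline is driven by an
    INI-style configuration file, writes multi-page TIF and HDF5 outputs,
    and ships a synthetic phantom and hologram generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    rhdf5,
    tiff,
    jsonlite,
    zip,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
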