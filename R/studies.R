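# Validation studies: self-contained parameter-recovery and consistency
# experiments on synthetic phantoms with known ground truth.  These back the
# package's acceptance checks and give users a one-call way to verify an
# installation.

#' Projection-model parameter recovery study
#'
#' For each seed, draws one sphere (index and radius uniform in the given
#' ranges), renders a noisy projection phantom, initializes with
#' [edge_estimate()] and fits the projection model.
#'
#' @param seeds integer vector of seeds (one phantom per seed).
#' @param n_range,r_range sampling ranges for true index and radius (m).
#' @param noise_sigma phase noise, radians.
#' @param grid imaging grid; default 200 x 200 px at 0.1 um, 550 nm, medium
#'   1.335.
#' @return data.frame with true and fitted parameters per seed.
#' @export
study_projection_recovery <- function(seeds = 1:20,
                                      n_range = c(1.34, 1.38),
                                      r_range = c(3e-6, 7e-6),
                                      noise_sigma = 0.02,
                                      grid = grid_spec(c(200L, 200L), 0.1e-6,
                                                       550e-9, 1.335)) {
  rows <- lapply(seeds, function(s) {
    set.seed(s)
    n_true <- stats::runif(1, n_range[1], n_range[2])
    r_true <- stats::runif(1, r_range[1], r_range[2])
    ctr <- (grid$shape - 1) / 2 + stats::runif(2, -2, 2)
    p <- sphere_params(n_true, r_true, ctr[1], ctr[2])
    spec <- phantom_spec(list(p), grid = grid, noise_sigma = noise_sigma,
                         seed = s)
    qpi <- gen_sphere_qpi(spec, "projection")$qpi
    init <- edge_estimate(qpi)
    fit <- fit_sphere_image(qpi, model = "projection", init = init)
    data.frame(seed = s, n_true = n_true, r_true = r_true,
               n_fit = fit$params$n, r_fit = fit$params$r,
               converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' Rytov-model parameter recovery study
#'
#' Noiseless Rytov phantoms fitted with the Rytov forward model.
#'
#' @param seeds integer vector of seeds.
#' @param n_range,r_range sampling ranges.
#' @param grid imaging grid; default 160 x 160 px at 0.13 um.
#' @return data.frame with true and fitted parameters per seed.
#' @export
study_rytov_recovery <- function(seeds = 1:5,
                                 n_range = c(1.34, 1.365),
                                 r_range = c(3e-6, 6e-6),
                                 grid = grid_spec(c(160L, 160L), 0.13e-6,
                                                  550e-9, 1.335)) {
  rows <- lapply(seeds, function(s) {
    set.seed(s)
    n_true <- stats::runif(1, n_range[1], n_range[2])
    r_true <- stats::runif(1, r_range[1], r_range[2])
    ctr <- (grid$shape - 1) / 2 + stats::runif(2, -1, 1)
    p <- sphere_params(n_true, r_true, ctr[1], ctr[2])
    qpi <- suppressWarnings(rytov_field(p, grid))
    init <- edge_estimate(qpi)
    fit <- fit_sphere_image(qpi, model = "rytov", init = init)
    data.frame(seed = s, n_true = n_true, r_true = r_true,
               n_fit = fit$params$n, r_fit = fit$params$r,
               converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' Weak-scattering limit deviation
#'
#' Deviation between the Rytov and projection phase of the same sphere,
#' normalized to the projection peak phase, for a set of index contrasts.
#' The Rytov model converges to the projection model as the contrast
#' vanishes, up to a contrast-independent diffraction floor localized at
#' the sphere rim (the scattered field is band-limited at the medium
#' wavenumber, the geometric projection is not).  Three metrics are
#' reported: frame-wide RMS, frame-wide pointwise max (dominated by the rim
#' floor), and pointwise max over the inner sphere (`rho <= 0.95 r`).
#'
#' @param dn index contrasts `n - n_med` to probe.
#' @param r sphere radius, meters.
#' @param grid imaging grid.
#' @return data.frame with columns `dn`, `rms_rel`, `max_rel`,
#'   `max_rel_inner`.
#' @export
weak_scatter_deviation <- function(dn = c(0.005, 0.002, 0.001, 0.0005),
                                   r = 4e-6,
                                   grid = grid_spec(c(160L, 160L), 0.13e-6,
                                                    550e-9, 1.335)) {
  ctr <- (grid$shape - 1) / 2
  px <- grid$pixel_size
  co1 <- ((seq_len(grid$shape[1]) - 1) - ctr[1]) * px
  co2 <- ((seq_len(grid$shape[2]) - 1) - ctr[2]) * px
  inner <- outer(co1^2, co2^2, `+`) <= (0.95 * r)^2
  rows <- lapply(dn, function(d) {
    p <- sphere_params(grid$medium_index + d, r, ctr[1], ctr[2])
    proj <- projection_phase(p, grid)
    ryt <- suppressWarnings(rytov_field(p, grid))$phase
    dev <- ryt - proj
    pk <- max(proj)
    data.frame(dn = d, rms_rel = sqrt(mean(dev^2)) / pk,
               max_rel = max(abs(dev)) / pk,
               max_rel_inner = max(abs(dev[inner])) / pk)
  })
  do.call(rbind, rows)
}

#' Born-oracle equivalence check
#'
#' Compares the k-space first-Born scattered field (the engine behind
#' [rytov_field()]) against brute-force direct-space integration of the Born
#' integral over a voxelized sphere, on a line of detector points in a plane
#' beyond the sphere.  Returns the peak-normalized maximum deviation.
#'
#' @param dn index contrast.
#' @param r sphere radius, meters.
#' @param nvox voxels per axis for the direct integration.
#' @param n_det number of detector points along the comparison line.
#' @param grid imaging grid for the k-space field.
#' @return List with `max_rel_dev` (peak-normalized), `model`, `direct`
#'   (complex vectors).
#' @export
born_oracle_check <- function(dn = 0.03, r = 5e-6, nvox = 64L, n_det = 32L,
                              grid = grid_spec(c(128L, 128L), 0.15e-6,
                                               550e-9, 1.335)) {
  ctr <- (grid$shape - 1) / 2
  p <- sphere_params(grid$medium_index + dn, r, ctr[1], ctr[2])
  lD <- r + 2e-6  # detector plane beyond the sphere
  ub <- .born_ub(p, grid, pad = 2L, prop_dist = lD)
  # detector line through the center along the first axis
  idx <- round(seq(ctr[1] - r / grid$pixel_size - 10,
                   ctr[1] + r / grid$pixel_size + 10, length.out = n_det))
  model <- ub[cbind(idx + 1, rep(round(ctr[2]) + 1, n_det))]
  det <- cbind(idx * grid$pixel_size, round(ctr[2]) * grid$pixel_size, lD)
  direct <- born_integral_direct(p, grid, det, nvox = nvox)
  # reference both fields to the incident wave at the detector plane
  direct <- direct * exp(-1i * grid$k_m * lD)
  peak <- max(Mod(direct))
  list(max_rel_dev = max(Mod(model - direct)) / peak,
       model = model, direct = direct)
}

#' Hologram round-trip phase error
#'
#' Renders a projection-sphere phase image, synthesizes an off-axis
#' hologram, reconstructs it, and returns the RMS phase error against the
#' ground truth, excluding a border margin and after removing the mean
#' offset.
#'
#' @param intensity_noise counts noise as a fraction of the fringe
#'   amplitude.
#' @param seed seed for the noise.
#' @param grid imaging grid; default 256 x 256 px.
#' @param margin_frac excluded border fraction.
#' @return RMS phase error in radians.
#' @export
holo_roundtrip_rms <- function(intensity_noise = 0, seed = 1L,
                               grid = grid_spec(c(256L, 256L), 0.107e-6,
                                                550e-9, 1.335),
                               margin_frac = 0.05) {
  ctr <- (grid$shape - 1) / 2
  # peak phase about 2.5 rad
  p <- sphere_params(1.355, 5e-6, ctr[1], ctr[2])
  spec <- phantom_spec(list(p), grid = grid, intensity_noise = intensity_noise,
                       seed = seed)
  qpi <- gen_sphere_qpi(spec, "projection")$qpi
  holo <- gen_hologram(qpi, spec)
  rec <- reconstruct_hologram(holo, meta = list(
    wavelength = grid$wavelength, pixel_size = grid$pixel_size,
    medium_index = grid$medium_index))
  m <- round(margin_frac * grid$shape[1])
  rows <- (m + 1):(grid$shape[1] - m); cols <- (m + 1):(grid$shape[2] - m)
  diffm <- rec$phase[rows, cols] - qpi$phase[rows, cols]
  diffm <- diffm - mean(diffm)
  sqrt(mean(diffm^2))
}

#' End-to-end pipeline determinism study
#'
#' Generates a synthetic hologram dataset, runs the full three-stage
#' pipeline twice from scratch, and compares the statistics TSV bytes.
#'
#' @param seed dataset seed.
#' @param n_images,spheres_per_image dataset size.
#' @param workdir directory to generate into (a fresh tempdir by default).
#' @param overrides configuration overrides applied to both runs.
#' @return List with `n_rows`, `identical` (logical), `records`,
#'   `manifest`.
#' @export
study_pipeline_determinism <- function(seed = 7L, n_images = 5L,
                                       spheres_per_image = 3L,
                                       workdir = tempfile("e2e_"),
                                       overrides = list()) {
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  ds <- file.path(workdir, "synth_ds")
  gen <- gen_dataset(n_images, spheres_per_image, ds, seed = seed)
  # analysis profile matched to the generator: specimen scale 9 um +- 60%;
  # poly2o sensor correction removes the quadratic background exactly, and
  # the 0.15 rad threshold sits above the residual noise floor while the
  # weakest sphere (dn = 0.005, r = 2.5 um, peak 0.285 rad) still binarizes
  # to an equivalent diameter of 4.2 um, inside the size window
  ov <- utils::modifyList(list(
    "meta.wavelength_nm" = 550, "meta.pixel_size_um" = 0.107,
    "meta.medium_index" = 1.335, "roi.size_um" = 9,
    "roi.size_variation" = 0.6, "roi.threshold" = "0.15",
    "bg.sensor_profile" = "poly2o"), overrides)
  run <- function() {
    rd <- .results_dir(ds)
    if (dir.exists(rd)) unlink(rd, recursive = TRUE)
    st <- dm_analyze_sphere(ds, overrides = ov)
    list(tsv = readBin(st$stats_path, "raw",
                       file.info(st$stats_path)$size),
         records = st$records, rois = st$rois)
  }
  a <- run(); b <- run()
  # pair ground-truth spheres with records via ROI box containment
  man <- gen$manifest
  man$identifier <- NA_character_
  for (i in seq_len(nrow(man))) {
    hit <- a$rois$image == man$image[i] &
      a$rois$r0 <= man$cx_px[i] & man$cx_px[i] < a$rois$r1 &
      a$rois$c0 <= man$cy_px[i] & man$cy_px[i] < a$rois$c1
    if (any(hit)) man$identifier[i] <- a$rois$identifier[which(hit)[1]]
  }
  recovery <- merge(man, a$records, by = "identifier")
  recovery$dn_err <- recovery$refractive_index - recovery$n
  recovery$r_err_rel <- recovery$radius_um / recovery$r_um - 1
  list(n_rows = nrow(a$records), identical = identical(a$tsv, b$tsv),
       records = a$records, manifest = gen$manifest, recovery = recovery)
}
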