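# Synthetic fixtures with known ground truth for every pipeline stage:
# spherical phase objects (projection or Rytov profiles), a quadratic phase
# background, off-axis carrier fringes and additive Gaussian noise.
#
# Defaults emulate the regime of suspended-cell / isolated-nucleus
# holographic microscopy: wavelength 550 nm, pixel size 0.107 um, medium
# index 1.335 (cell culture medium), sphere radii of a few micrometers.
# All randomness flows from the single seed in the spec.

#' Phantom specification
#'
#' @param spheres list of [sphere_params()]; pairwise non-overlapping
#'   (center distance > r_i + r_j + 5 px).
#' @param grid a [grid_spec()].
#' @param bg_poly 6 coefficients (a..f) of the quadratic phase background
#'   `a + b u + c v + d u^2 + e v^2 + f u v` over per-axis [-1, 1]
#'   coordinates, radians.
#' @param noise_sigma additive Gaussian phase noise, radians.
#' @param carrier off-axis carrier `c(kx, ky)` in rad/px.
#' @param fringe_contrast modulation depth of the carrier fringes, 0..1.
#' @param intensity_noise hologram counts noise as a fraction of the fringe
#'   amplitude.
#' @param seed integer seed; the same spec and seed give identical output.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(spheres,
                         grid = grid_spec(c(512L, 512L), 0.107e-6, 550e-9, 1.335),
                         bg_poly = c(0, 0, 0, 0, 0, 0),
                         noise_sigma = 0,
                         carrier = c(kx = 1.6, ky = 1.2),
                         fringe_contrast = 0.9,
                         intensity_noise = 0,
                         seed = 1L) {
  stopifnot(length(bg_poly) == 6, fringe_contrast >= 0, fringe_contrast <= 1)
  if (inherits(spheres, "sphere_params")) spheres <- list(spheres)
  px <- grid$pixel_size
  if (length(spheres) > 1) {
    for (i in seq_along(spheres)[-1]) for (j in seq_len(i - 1)) {
      a <- spheres[[i]]; b <- spheres[[j]]
      dpx <- sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2)
      if (dpx <= (a$r + b$r) / px + 5)
        stop("spheres overlap: ", i, " and ", j)
    }
  }
  structure(list(spheres = spheres, grid = grid, bg_poly = bg_poly,
                 noise_sigma = noise_sigma,
                 carrier = list(kx = unname(carrier[1]), ky = unname(carrier[2]),
                                mode = "fixed"),
                 fringe_contrast = fringe_contrast,
                 intensity_noise = intensity_noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

.bg_poly_surface <- function(shape, coefs) {
  nr <- shape[1]; nc <- shape[2]
  u <- if (nr > 1) 2 * (seq_len(nr) - 1) / (nr - 1) - 1 else rep(0, nr)
  v <- if (nc > 1) 2 * (seq_len(nc) - 1) / (nc - 1) - 1 else rep(0, nc)
  U <- matrix(u, nr, nc); V <- matrix(v, nr, nc, byrow = TRUE)
  coefs[1] + coefs[2] * U + coefs[3] * V + coefs[4] * U^2 + coefs[5] * V^2 +
    coefs[6] * U * V
}

#' Generate a phantom phase image with ground truth
#'
#' Sums the model phase of every sphere, adds the quadratic background and
#' Gaussian noise.  Amplitude is all-one for the projection model and the
#' product of per-sphere Rytov amplitudes otherwise.
#'
#' @param spec a [phantom_spec()].
#' @param model `"projection"` or `"rytov"`.
#' @return List with `qpi` (a [qpimage()]) and `truth` (data.frame with one
#'   row per sphere: n, r, cx, cy).
#' @export
gen_sphere_qpi <- function(spec, model = "projection") {
  g <- spec$grid
  ph <- matrix(0, g$shape[1], g$shape[2])
  am <- matrix(1, g$shape[1], g$shape[2])
  for (p in spec$spheres) {
    if (model == "projection") {
      ph <- ph + projection_phase(p, g)
    } else {
      f <- suppressWarnings(rytov_field(p, g))
      ph <- ph + f$phase
      am <- am * f$amplitude
    }
  }
  ph <- ph + .bg_poly_surface(g$shape, spec$bg_poly)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    ph <- ph + matrix(stats::rnorm(length(ph), 0, spec$noise_sigma),
                      nrow(ph), ncol(ph))
  }
  truth <- do.call(rbind, lapply(spec$spheres, function(p)
    data.frame(n = p$n, r = p$r, cx = p$cx, cy = p$cy)))
  list(qpi = qpimage(ph, am, g$wavelength, g$pixel_size, g$medium_index),
       truth = truth)
}

#' Synthesize an off-axis hologram from a phase image
#'
#' `I(x, y) = 1 + a^2 + 2 a c cos(kx x + ky y - phi(x, y))` with amplitude
#' `a`, fringe contrast `c` and the spec's carrier, plus Gaussian counts
#' noise scaled to the fringe amplitude; the result is shifted to be
#' non-negative if noise pushes it below zero.
#'
#' @param qpi a [qpimage()].
#' @param spec a [phantom_spec()] providing carrier, contrast and noise.
#' @return Raw image list (`pixels`, `source_name`, `time`, `index`).
#' @export
gen_hologram <- function(qpi, spec) {
  kx <- spec$carrier$kx; ky <- spec$carrier$ky
  if (sqrt(kx^2 + ky^2) >= pi) stop("carrier at or above Nyquist")
  nr <- nrow(qpi$phase); nc <- ncol(qpi$phase)
  theta <- outer(kx * (seq_len(nr) - 1), ky * (seq_len(nc) - 1), `+`)
  a <- qpi$amplitude
  I <- 1 + a^2 + 2 * a * spec$fringe_contrast * cos(theta - qpi$phase)
  if (spec$intensity_noise > 0) {
    set.seed(spec$seed + 1L)
    famp <- 2 * spec$fringe_contrast * mean(a)
    I <- I + matrix(stats::rnorm(length(I), 0, spec$intensity_noise * famp),
                    nr, nc)
    if (min(I) < 0) I <- I - min(I)
  }
  list(pixels = I, source_name = "synthetic", time = qpi$time, index = 1L)
}

# deterministic sphere layout: k cells of a g x g grid, jittered centers
.layout_spheres <- function(k, grid, r_px) {
  gcells <- ceiling(sqrt(k))
  H <- grid$shape[1]; W <- grid$shape[2]
  ch <- H / gcells; cw <- W / gcells
  cells <- sample(gcells^2, k)
  lapply(seq_len(k), function(i) {
    ci <- (cells[i] - 1) %/% gcells
    cj <- (cells[i] - 1) %% gcells
    jit <- pmax(4, ch / 2 - r_px[i] - 12)
    c(cx = ci * ch + ch / 2 + stats::runif(1, -jit, jit) * 0.5,
      cy = cj * cw + cw / 2 + stats::runif(1, -jit, jit) * 0.5)
  })
}

#' Generate a synthetic hologram dataset on disk
#'
#' Writes `n_images` single-page hologram TIFs (folder or zip archive) with
#' deterministic acquisition timestamps at 1 s spacing, plus a tab-separated
#' ground-truth manifest (per-sphere n, r, centers) for end-to-end
#' assertions.  Sphere indices and radii are sampled from `n_range` /
#' `r_range`; all randomness derives from `seed`.
#'
#' @param n_images number of frames (>= 1).
#' @param spheres_per_image spheres per frame.
#' @param out_path output folder or `.zip` path.
#' @param seed integer seed.
#' @param grid imaging grid; default 512 x 512 px at 0.107 um, 550 nm,
#'   medium 1.335.
#' @param n_range,r_range sampling ranges for sphere index and radius (m).
#' @param bg_poly,noise_sigma,intensity_noise,fringe_contrast,carrier
#'   passed to [phantom_spec()]; defaults give a gently curved background
#'   and 1% fringe noise.
#' @return Invisibly, a list with `path`, `manifest` (data.frame) and
#'   `manifest_path`.
#' @export
gen_dataset <- function(n_images, spheres_per_image, out_path, seed = 1L,
                        grid = grid_spec(c(512L, 512L), 0.107e-6, 550e-9, 1.335),
                        n_range = c(1.34, 1.37),
                        r_range = c(2.5e-6, 6.5e-6),
                        bg_poly = c(0.2, 0.15, -0.1, 0.08, -0.05, 0.03),
                        noise_sigma = 0,
                        intensity_noise = 0.01,
                        fringe_contrast = 0.9,
                        carrier = c(kx = 1.6, ky = 1.2)) {
  stopifnot(n_images >= 1, spheres_per_image >= 1)
  as_zip <- grepl("\\.zip$", out_path, ignore.case = TRUE)
  dir_out <- if (as_zip) tempfile("synthds_") else out_path
  if (!dir.exists(dir_out)) dir.create(dir_out, recursive = TRUE)
  t0 <- 946684800  # fixed epoch so reruns are byte-identical
  manifest <- list()
  for (i in seq_len(n_images)) {
    set.seed(seed * 1000L + i)
    k <- spheres_per_image
    ns <- stats::runif(k, n_range[1], n_range[2])
    rs <- stats::runif(k, r_range[1], r_range[2])
    centers <- .layout_spheres(k, grid, rs / grid$pixel_size)
    spheres <- lapply(seq_len(k), function(s)
      sphere_params(ns[s], rs[s], centers[[s]]["cx"], centers[[s]]["cy"]))
    spec <- phantom_spec(spheres, grid = grid, bg_poly = bg_poly,
                         noise_sigma = noise_sigma, carrier = carrier,
                         fringe_contrast = fringe_contrast,
                         intensity_noise = intensity_noise,
                         seed = seed * 1000L + i)
    gs <- gen_sphere_qpi(spec, model = "projection")
    gs$qpi$time <- t0 + (i - 1)
    holo <- gen_hologram(gs$qpi, spec)
    f <- file.path(dir_out, sprintf("holo_%03d.tif", i))
    .write_tif_scaled(list(holo$pixels), f,
                      page_meta = list(list(kind = "hologram",
                                            time = t0 + (i - 1))))
    Sys.setFileTime(f, as.POSIXct(t0 + (i - 1), origin = "1970-01-01",
                                  tz = "UTC"))
    manifest[[i]] <- data.frame(image = i, sphere = seq_len(k), n = ns,
                                r_um = rs * 1e6,
                                cx_px = vapply(centers, `[[`, 0, "cx"),
                                cy_px = vapply(centers, `[[`, 0, "cy"),
                                time_s = t0 + (i - 1))
  }
  manifest <- do.call(rbind, manifest)
  mpath <- file.path(dir_out, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (as_zip) {
    if (file.exists(out_path)) unlink(out_path)
    zpath <- suppressWarnings(normalizePath(out_path, mustWork = FALSE))
    zip::zip(zpath, files = list.files(dir_out), root = dir_out,
             mode = "mirror")
    mpath <- out_path
  }
  invisible(list(path = out_path, manifest = manifest,
                 manifest_path = mpath))
}
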