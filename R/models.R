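# Forward models for the phase of a homogeneous sphere.
#
# Two regimes are covered: the optical projection approximation (straight-ray
# optical path length, phase proportional to the chord length) and the Rytov
# approximation (first-order scattering of the complex log-field, evaluated
# via the Fourier diffraction theorem and backpropagated to the in-focus
# plane through the sphere center).  The systematic bias of the Rytov fit is
# compensated by an affine correction of the fitted index contrast and
# radius ("rytov-sc").

# pixel-center coordinate grids in meters, relative to array origin (0,0)
.coord_grids <- function(g) {
  x <- (seq_len(g$shape[1]) - 1) * g$pixel_size
  y <- (seq_len(g$shape[2]) - 1) * g$pixel_size
  list(x = x, y = y)
}

#' Projection-approximation phase of a homogeneous sphere
#'
#' Straight-ray model: the phase is proportional to the chord length of the
#' sphere along the optical axis,
#' `phi(x, y) = (2 pi / lambda) (n - n_med) * 2 sqrt(r^2 - rho^2)` inside the
#' sphere outline and equal to `phase_offset` outside.  Pixels are evaluated
#' at their centers; anti-aliasing of the rim is left to the fitting layer.
#'
#' @param p [sphere_params()].
#' @param g [grid_spec()].
#' @return Phase matrix in radians with the shape of `g`.
#' @export
projection_phase <- function(p, g) {
  co <- .coord_grids(g)
  dx2 <- (co$x - p$cx * g$pixel_size)^2
  dy2 <- (co$y - p$cy * g$pixel_size)^2
  rho2 <- outer(dx2, dy2, `+`)
  chord2 <- p$r^2 - rho2
  chord2[chord2 < 0] <- 0
  (2 * pi / g$wavelength) * (p$n - g$medium_index) * 2 * sqrt(chord2) +
    p$phase_offset
}

# 3-D Fourier transform of the sphere scattering potential
# f(r) = k_m^2 * chi inside the sphere, chi = (n/n_med)^2 - 1:
# F(q) = k_m^2 chi 4 pi (sin(qR) - qR cos(qR)) / q^3, F(0) = k_m^2 chi V
.sphere_potential_ft <- function(q, R, km2chi) {
  qR <- q * R
  out <- numeric(length(q))
  small <- qR < 1e-4
  out[!small] <- 4 * pi * (sin(qR[!small]) - qR[!small] * cos(qR[!small])) /
    q[!small]^3
  out[small] <- (4 / 3) * pi * R^3  # qR -> 0 limit
  km2chi * out
}

# First Born scattered field u_B on the in-focus plane through the sphere
# center, by the Fourier diffraction theorem:
#   u_B_hat(kx, ky) = i / (2 kz) * F(kx, ky, kz - k_m),  kz = sqrt(k_m^2-k⊥^2)
# computed on a zero-padded grid (factor `pad`) to suppress periodic
# wrap-around, then cropped back.  Evanescent components are zeroed.
# `prop_dist`: optional extra propagation distance in meters (field referenced
# to the plane z = prop_dist instead of the in-focus plane), used by the
# direct-space oracle comparison.
.born_ub <- function(p, g, pad = 2L, prop_dist = 0) {
  H <- g$shape[1]; W <- g$shape[2]; px <- g$pixel_size
  Hp <- pad * H; Wp <- pad * W
  offr <- floor((Hp - H) / 2); offc <- floor((Wp - W) / 2)
  km <- g$k_m
  kx <- fft_kvals(Hp, px); ky <- fft_kvals(Wp, px)
  KX2 <- matrix(kx^2, Hp, Wp)
  KY2 <- matrix(ky^2, Hp, Wp, byrow = TRUE)
  kz2 <- km^2 - KX2 - KY2
  prop <- kz2 > (1e-3 * km)^2
  kz <- sqrt(pmax(kz2, 0))
  qz <- kz - km
  q <- sqrt(KX2 + KY2 + qz^2)
  chi <- (p$n / g$medium_index)^2 - 1
  Fq <- matrix(0, Hp, Wp)
  Fq[prop] <- .sphere_potential_ft(q[prop], p$r, km^2 * chi)
  # phase ramp placing the sphere center at (cx, cy) of the unpadded grid
  x0 <- (p$cx + offr) * px; y0 <- (p$cy + offc) * px
  ramp <- outer(kx * x0, ky * y0, `+`)
  ub_hat <- matrix(0 + 0i, Hp, Wp)
  ub_hat[prop] <- (1i / (2 * kz[prop])) * Fq[prop] *
    exp(-1i * ramp[prop]) *
    exp(1i * (kz[prop] - km) * prop_dist)
  ub <- stats::fft(ub_hat, inverse = TRUE) / (Hp * px * Wp * px)
  ub[offr + seq_len(H), offc + seq_len(W)]
}

#' Rytov-approximation field of a homogeneous sphere
#'
#' Computes the complex Rytov exponent `psi = u_B / u_0` from the first Born
#' scattered field backpropagated to the in-focus plane through the sphere
#' center; phase is `Im(psi) + phase_offset` (no wrapping occurs since the
#' exponent is computed directly) and amplitude is `exp(Re(psi))`, normalized
#' so that the background amplitude is 1.
#'
#' @inheritParams projection_phase
#' @param pad zero-padding factor for the internal FFT (wrap-around guard).
#' @return A [qpimage()] with phase and amplitude.
#' @export
rytov_field <- function(p, g, pad = 2L) {
  if (p$r / g$pixel_size < 5)
    warning("sphere under-resolved: r/pixel_size < 5")
  ub <- .born_ub(p, g, pad = pad)
  qpimage(phase = Im(ub) + p$phase_offset,
          amplitude = exp(Re(ub)),
          wavelength = g$wavelength, pixel_size = g$pixel_size,
          medium_index = g$medium_index)
}

#' First-Born field image of a homogeneous sphere
#'
#' Total field `u = 1 + u_B` on the in-focus plane; phase is the unwrapped
#' argument, amplitude the modulus.  Serves as the reference forward model
#' for the Rytov-SC calibration harness (the Born field linearizes the
#' scattered field itself rather than the log-field).
#'
#' @inheritParams rytov_field
#' @return A [qpimage()].
#' @export
born_field <- function(p, g, pad = 2L) {
  ub <- .born_ub(p, g, pad = pad)
  u <- 1 + ub
  qpimage(phase = unwrap_phase(atan2(Im(u), Re(u))) + p$phase_offset,
          amplitude = Mod(u),
          wavelength = g$wavelength, pixel_size = g$pixel_size,
          medium_index = g$medium_index)
}

# Brute-force direct-space Born integral: u_s(rd) = sum_voxels f * u0 * G,
# G = exp(ik|r|)/(4 pi |r|), over an nvox^3 voxelization of the sphere's
# bounding box, evaluated at detector points `det` (matrix with columns
# x, y, z in meters).  The self/near-voxel singularity is handled by an
# equal-volume-sphere analytic correction.  Independent oracle; O(ndet*nvox^3).
born_integral_direct <- function(p, g, det, nvox = 64L) {
  km <- g$k_m
  chi <- (p$n / g$medium_index)^2 - 1
  f <- km^2 * chi
  half <- p$r * 1.02
  xs <- seq(-half, half, length.out = nvox + 1L)
  xs <- (xs[-1] + xs[-length(xs)]) / 2  # voxel centers
  h <- xs[2] - xs[1]
  gr <- expand.grid(x = xs, y = xs, z = xs)
  inside <- gr$x^2 + gr$y^2 + gr$z^2 <= p$r^2
  gr <- gr[inside, ]
  x0 <- p$cx * g$pixel_size; y0 <- p$cy * g$pixel_size
  sx <- gr$x + x0; sy <- gr$y + y0; sz <- gr$z
  u0 <- exp(1i * km * sz)
  vol <- h^3
  a_eq <- (3 * vol / (4 * pi))^(1 / 3)  # equal-volume sphere radius
  # analytic integral of G over a small sphere of radius a around the origin
  self_int <- (exp(1i * km * a_eq) * (a_eq / (1i * km) + 1 / km^2) - 1 / km^2)
  out <- complex(nrow(det))
  for (i in seq_len(nrow(det))) {
    dx <- det[i, 1] - sx; dy <- det[i, 2] - sy; dz <- det[i, 3] - sz
    rr <- sqrt(dx^2 + dy^2 + dz^2)
    gval <- exp(1i * km * rr) / (4 * pi * rr) * vol
    near <- rr < a_eq
    if (any(near)) gval[near] <- self_int
    out[i] <- f * sum(u0 * gval)
  }
  out
}

#' Multislice beam-propagation field of a homogeneous sphere
#'
#' Splits the sphere volume into thin slices; each slice applies its phase
#' screen `exp(i k0 (n - n_med) dz)` and the field is propagated between
#' slices with the (non-paraxial) angular-spectrum kernel in the medium.
#' The exit field is backpropagated to the in-focus plane through the
#' sphere center.  Valid at arbitrary total phase in the forward-scattering
#' regime (backscattering neglected), which makes it the package's
#' exact-reference forward model where the first-order approximations break
#' down.
#'
#' @inheritParams rytov_field
#' @param dz slice thickness in meters (default `lambda / 4`).
#' @return A [qpimage()] with phase and amplitude.
#' @export
bpm_field <- function(p, g, pad = 2L, dz = NULL) {
  H <- g$shape[1]; W <- g$shape[2]; px <- g$pixel_size
  Hp <- pad * H; Wp <- pad * W
  offr <- floor((Hp - H) / 2); offc <- floor((Wp - W) / 2)
  km <- g$k_m
  k0 <- 2 * pi / g$wavelength
  if (is.null(dz)) dz <- g$wavelength / 4
  kx <- fft_kvals(Hp, px); ky <- fft_kvals(Wp, px)
  kz2 <- km^2 - outer(kx^2, ky^2, `+`)
  kz <- sqrt(pmax(kz2, 0))
  evan <- kz2 <= 0
  # propagation in the co-moving frame of the plane wave: exp(i (kz - km) z)
  prop_dz <- exp(1i * (kz - km) * dz); prop_dz[evan] <- 0
  x <- (seq_len(Hp) - 1 - offr) * px - p$cx * px
  y <- (seq_len(Wp) - 1 - offc) * px - p$cy * px
  rho2 <- outer(x^2, y^2, `+`)
  zh <- p$r + 2 * dz
  nz <- ceiling(2 * zh / dz)
  zs <- seq(-zh + dz / 2, by = dz, length.out = nz)
  u <- matrix(1 + 0i, Hp, Wp)
  for (z in zs) {
    c2 <- p$r^2 - z^2
    if (c2 > 0) {
      screen <- rho2 <= c2
      if (any(screen)) {
        u[screen] <- u[screen] * exp(1i * k0 * (p$n - g$medium_index) * dz)
      }
    }
    u <- stats::fft(stats::fft(u) * prop_dz, inverse = TRUE) / length(u)
  }
  # backpropagate from the exit plane to the center plane
  z_end <- -zh + nz * dz
  back <- exp(-1i * (kz - km) * z_end); back[evan] <- 0
  u <- stats::fft(stats::fft(u) * back, inverse = TRUE) / length(u)
  u <- u[offr + seq_len(H), offc + seq_len(W)]
  qpimage(phase = unwrap_phase(atan2(Im(u), Re(u))) + p$phase_offset,
          amplitude = Mod(u),
          wavelength = g$wavelength, pixel_size = g$pixel_size,
          medium_index = g$medium_index)
}

#' Edge-detection initial estimate of sphere parameters
#'
#' Smooths the phase (Gaussian, sigma = 2 px), binarizes the gradient
#' magnitude at its Otsu threshold, fits an algebraic circle to the edge
#' pixels, and converts the mean interior phase into a refractive index via
#' the projection disk average `<phi> = (2 pi / lambda)(n - n_med)(4 r / 3)`,
#' i.e. `n = n_med + 3 lambda <phi> / (8 pi r)`.
#'
#' @param qpi a [qpimage()] holding one dominant object.
#' @return A [sphere_params()] estimate.
#' @export
edge_estimate <- function(qpi) {
  g <- grid_of(qpi)
  ph <- EBImage::gblur(qpi$phase, sigma = 2)
  gx <- ph; gy <- ph
  gx[] <- 0; gy[] <- 0
  nr <- nrow(ph); nc <- ncol(ph)
  gx[2:(nr - 1), ] <- (ph[3:nr, ] - ph[1:(nr - 2), ]) / 2
  gy[, 2:(nc - 1)] <- (ph[, 3:nc] - ph[, 1:(nc - 2)]) / 2
  em <- sqrt(gx^2 + gy^2)
  thr <- EBImage::otsu(em, range = range(em), levels = 256L)
  edge <- which(em > thr, arr.ind = TRUE)
  if (nrow(edge) < 20) stop("no object edge found")
  sigma <- 2
  w <- em[edge]
  # gradient-weighted centroid, then the rim radius as the (sub-bin) argmax
  # of the radial gradient profile; the Gaussian pre-smoothing shifts the
  # gradient peak inward by about 0.65 sigma, which is compensated
  cx <- sum((edge[, 1] - 1) * w) / sum(w)
  cy <- sum((edge[, 2] - 1) * w) / sum(w)
  d <- sqrt((edge[, 1] - 1 - cx)^2 + (edge[, 2] - 1 - cy)^2)
  prof <- tapply(w, round(d), mean)
  rb <- as.numeric(names(prof))
  i <- which.max(prof)
  r_px <- rb[i]
  if (i > 1 && i < length(prof)) {
    y1 <- prof[i - 1]; y2 <- prof[i]; y3 <- prof[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) r_px <- r_px + 0.5 * (y1 - y3) / denom
  }
  r_px <- as.numeric(r_px) + 0.65 * sigma
  co <- .coord_grids(g)
  rho2 <- outer((co$x - cx * g$pixel_size)^2, (co$y - cy * g$pixel_size)^2, `+`)
  inside <- rho2 <= (r_px * g$pixel_size)^2
  if (!any(inside) || all(inside)) stop("no object edge found")
  offset <- mean(qpi$phase[rho2 > (1.2 * r_px * g$pixel_size)^2])
  if (!is.finite(offset)) offset <- 0
  phi_bar <- mean(qpi$phase[inside]) - offset
  r <- r_px * g$pixel_size
  n <- g$medium_index + 3 * g$wavelength * phi_bar / (8 * pi * r)
  sphere_params(n = n, r = r, cx = cx, cy = cy, phase_offset = offset)
}

#' Systematic correction of a Rytov sphere fit
#'
#' Affine correction of the fitted relative index contrast
#' `x_fit = n_fit / n_med - 1` and radius compensating the systematic bias of
#' the Rytov approximation: `x_sc = c_n0 + c_n1 x_fit`,
#' `r_sc = r_fit (c_r0 + c_r1 x_fit)`.  Identity coefficients
#' `(0, 1, 1, 0)` return the fit unchanged.
#'
#' @param n_fit,r_fit fitted index and radius.
#' @param n_med medium refractive index.
#' @param coeffs named numeric vector `c(c_n0, c_n1, c_r0, c_r1)`; defaults to
#'   the package's calibration-derived constants.
#' @return List with elements `n_sc` and `r_sc`.
#' @export
rytov_sc_correct <- function(n_fit, r_fit, n_med,
                             coeffs = rytov_sc_default_coeffs()) {
  stopifnot(all(c("c_n0", "c_n1", "c_r0", "c_r1") %in% names(coeffs)))
  x_fit <- n_fit / n_med - 1
  x_sc <- coeffs[["c_n0"]] + coeffs[["c_n1"]] * x_fit
  list(n_sc = n_med * (1 + x_sc),
       r_sc = r_fit * (coeffs[["c_r0"]] + coeffs[["c_r1"]] * x_fit))
}
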