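# Off-axis hologram reconstruction by Fourier sideband isolation.
#
# The off-axis reference tilt shifts the object spectrum to a carrier
# frequency; isolating that sideband, moving it to DC and inverse
# transforming recovers the complex field b(x, y) whose argument is the
# (wrapped) phase and whose modulus the amplitude.  Spectra are indexed with
# DC at the array center for all carrier math; the sideband is searched in
# the half-plane ky >= 0.

#' Unwrap a two-dimensional phase map
#'
#' Removes 2-pi ambiguities by reliability sorting (second-difference
#' reliability, region merging along a non-continuous path).  The output is
#' congruent to the input modulo 2 pi at every pixel and is offset-normalized
#' so that the median over a 5-px border frame lies in (-pi, pi].
#'
#' @param wrapped matrix of wrapped phases in radians, values in (-pi, pi].
#' @return Matrix of unwrapped phases, radians.
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot(is.matrix(wrapped), all(is.finite(wrapped)))
  out <- .unwrap2d_cpp(wrapped)
  b <- min(5L, floor(min(dim(out)) / 2))
  nr <- nrow(out); nc <- ncol(out)
  border <- out[c(seq_len(b), (nr - b + 1):nr), ]
  if (nr - b >= b + 1)
    border <- c(border, out[(b + 1):(nr - b), c(seq_len(b), (nc - b + 1):nc)])
  med <- stats::median(border)
  k <- ceiling(med / (2 * pi) - 0.5)  # med - 2 pi k in (-pi, pi]
  out - 2 * pi * k
}

#' Detect the off-axis carrier frequency
#'
#' Finds the sideband as the magnitude maximum of the hologram's Fourier
#' transform over the half-plane `ky >= 0`, excluding a DC disk of radius
#' `max(3, N/20)` frequency bins, with sub-bin refinement by the local 3x3
#' centroid of the magnitude.
#'
#' @param hologram a raw image (list with element `pixels`) or a matrix.
#' @return A list of class `carrier_spec` with `kx`, `ky` in rad/px.
#' @export
detect_sideband <- function(hologram) {
  m <- if (is.list(hologram)) hologram$pixels else hologram
  stopifnot(is.matrix(m), all(is.finite(m)))
  nr <- nrow(m); nc <- ncol(m)
  S <- fftshift2(Mod(fft2(m - mean(m))))
  bx <- shifted_bins(nr); by <- shifted_bins(nc)
  rdc <- max(3, min(nr, nc) / 20)
  dc <- outer(bx^2, by^2, `+`) <= rdc^2
  half <- matrix(by >= 0, nr, nc, byrow = TRUE)
  cand <- half & !dc
  medmag <- stats::median(S[!dc])
  peak <- which(cand & S == max(S[cand]), arr.ind = TRUE)[1, , drop = TRUE]
  if (S[peak[1], peak[2]] <= 5 * medmag) stop("no sideband detected")
  # 3x3 local centroid (sub-bin refinement)
  ri <- peak[1] + (-1:1); ci <- peak[2] + (-1:1)
  ri <- ri[ri >= 1 & ri <= nr]; ci <- ci[ci >= 1 & ci <= nc]
  w <- S[ri, ci, drop = FALSE]
  cb_x <- sum(bx[ri] * rowSums(w)) / sum(w)
  cb_y <- sum(by[ci] * colSums(w)) / sum(w)
  structure(list(kx = 2 * pi * cb_x / nr, ky = 2 * pi * cb_y / nc,
                 mode = "auto"),
            class = "carrier_spec")
}

#' Build a sideband filter weight matrix
#'
#' Weights on the (fftshift-centered) frequency grid, centered on the carrier
#' position.  Filter radius is `R = size_rel * |k_carrier|` in frequency
#' bins.  Types: `disk` (indicator), `smooth disk` (disk convolved with a
#' Gaussian of sigma = R/10), `gauss` (weight 0.5 at distance R), `square`
#' (Chebyshev-distance indicator).
#'
#' @param shape `c(H, W)` of the hologram.
#' @param carrier a `carrier_spec` (rad/px).
#' @param name filter type; one of `"disk"`, `"smooth disk"`, `"gauss"`,
#'   `"square"`.
#' @param size_rel filter size as a fraction of the carrier distance.
#' @return Weight matrix in `[0, 1]`, fftshift layout (DC at center).
#' @export
make_filter <- function(shape, carrier, name = "smooth disk",
                        size_rel = 1 / 3) {
  stopifnot(size_rel > 0, size_rel <= 1)
  nr <- shape[1]; nc <- shape[2]
  kbins_x <- carrier$kx * nr / (2 * pi)
  kbins_y <- carrier$ky * nc / (2 * pi)
  R <- size_rel * sqrt(kbins_x^2 + kbins_y^2)
  if (R < 2) stop("filter too small")
  dx <- shifted_bins(nr) - kbins_x
  dy <- shifted_bins(nc) - kbins_y
  w <- switch(name,
    "disk" = {
      (outer(dx^2, dy^2, `+`) <= R^2) * 1
    },
    "smooth disk" = {
      disk <- (outer(dx^2, dy^2, `+`) <= R^2) * 1
      sm <- EBImage::gblur(disk, sigma = R / 10)
      sm[sm < 0] <- 0; sm[sm > 1] <- 1
      sm
    },
    "gauss" = {
      sg2 <- R^2 / (2 * log(2))  # weight 0.5 at distance R
      exp(-outer(dx^2, dy^2, `+`) / (2 * sg2))
    },
    "square" = {
      (outer(abs(dx), abs(dy), pmax) <= R) * 1
    },
    stop("unknown filter name: ", name)
  )
  w
}

#' Reconstruct a quantitative phase image from an off-axis hologram
#'
#' FFT, multiplication by the sideband filter, shift of the carrier to DC
#' (integer-bin roll plus sub-bin demodulation in real space), inverse FFT,
#' then phase unwrapping of the argument.  The sign convention makes an
#' optically denser object (n > n_med) yield positive phase;
#' `invert_phase = TRUE` selects the opposite convention.
#'
#' @param hologram raw image (list with `pixels`) or matrix.
#' @param carrier a `carrier_spec`, or `NULL` to auto-detect.
#' @param filter_name,size_rel see [make_filter()].
#' @param meta named list with `wavelength`, `pixel_size`, `medium_index`,
#'   and optionally `time`, `identifier`.
#' @param invert_phase flip the phase sign convention.
#' @return A [qpimage()].
#' @export
reconstruct_hologram <- function(hologram, carrier = NULL,
                                 filter_name = "smooth disk",
                                 size_rel = 1 / 3, meta,
                                 invert_phase = FALSE) {
  m <- if (is.list(hologram)) hologram$pixels else hologram
  if (is.null(carrier)) carrier <- detect_sideband(m)
  nr <- nrow(m); nc <- ncol(m)
  W <- make_filter(c(nr, nc), carrier, filter_name, size_rel)
  S <- fftshift2(fft2(m)) * W
  # integer part of the carrier -> roll to DC; remainder -> real-space ramp
  bx <- round(carrier$kx * nr / (2 * pi))
  by <- round(carrier$ky * nc / (2 * pi))
  S <- roll2(S, -bx, -by)
  b <- ifft2(ifftshift2(S))
  dkx <- carrier$kx - 2 * pi * bx / nr
  dky <- carrier$ky - 2 * pi * by / nc
  # apply the sub-bin demodulation, then refine the carrier estimate from
  # the amplitude-weighted mean phase slope of the interior (auto mode only;
  # FFT-leakage-contaminated edges excluded, object gradients average out)
  n_refine <- if (carrier$mode == "auto") 3L else 0L
  mr <- max(2L, round(0.12 * nr)); mc <- max(2L, round(0.12 * nc))
  ir <- (mr + 1):(nr - mr); ic <- (mc + 1):(nc - mc)
  for (pass in seq_len(n_refine + 1L)) {
    if (dkx != 0 || dky != 0) {
      ramp <- outer(dkx * (seq_len(nr) - 1), dky * (seq_len(nc) - 1), `+`)
      b <- b * exp(-1i * ramp)
    }
    if (pass > n_refine) break
    bi <- b[ir, ic]
    dkx <- Arg(sum(bi[-1, ] * Conj(bi[-nrow(bi), ])))
    dky <- Arg(sum(bi[, -1] * Conj(bi[, -ncol(bi)])))
    if (!is.finite(dkx) || !is.finite(dky)) break
    if (abs(dkx) < 1e-12 && abs(dky) < 1e-12) break
  }
  b <- Conj(b)  # the ky >= 0 sideband carries exp(-i phi)
  ph <- unwrap_phase(atan2(Im(b), Re(b)))
  if (invert_phase) ph <- -ph
  qpimage(phase = ph, amplitude = Mod(b),
          wavelength = meta$wavelength, pixel_size = meta$pixel_size,
          medium_index = meta$medium_index,
          time = meta$time %||% 0, identifier = meta$identifier %||% "")
}
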