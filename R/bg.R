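# Phase (and amplitude) background estimation and removal.
#
# Background pixels are selected either as a frame border around the image,
# by a phase threshold, or both (intersection); a constant, planar or
# second-order polynomial surface is least-squares fitted over that mask and
# subtracted from the phase (divided out of the amplitude).  Polynomial fits
# use coordinates centered and scaled to [-1, 1] per axis for conditioning;
# the surface is returned in pixel space.

#' Background specification
#'
#' @param profile one of `"offset"`, `"tilt"`, `"poly2o"`, `"image"`.
#' @param border_px width of the border frame used as background, pixels.
#' @param binary_threshold optional; pixels with phase strictly below this
#'   value count as background.
#' @param offset_mode `"mean"` or `"median"` (offset profile only).
#' @param reference optional reference phase/amplitude image for
#'   `profile = "image"`.
#' @return List of class `bg_spec`.
#' @export
bg_spec <- function(profile = "poly2o", border_px = 0L,
                    binary_threshold = NULL, offset_mode = "mean",
                    reference = NULL) {
  stopifnot(profile %in% c("offset", "tilt", "poly2o", "image"),
            offset_mode %in% c("mean", "median"), border_px >= 0)
  if (border_px == 0 && is.null(binary_threshold) && profile != "image")
    stop("background spec needs border_px > 0, a binary_threshold, or profile 'image'")
  structure(list(profile = profile, border_px = as.integer(border_px),
                 binary_threshold = binary_threshold,
                 offset_mode = offset_mode, reference = reference),
            class = "bg_spec")
}

#' Build a background mask
#'
#' Border mode marks exactly the frame of width `border_px`; threshold mode
#' marks pixels with phase below `binary_threshold`; if both are set the
#' intersection is used.
#'
#' @param shape `c(H, W)`.
#' @param spec a [bg_spec()].
#' @param phase phase matrix (needed for threshold mode).
#' @return Logical matrix.
#' @export
make_background_mask <- function(shape, spec, phase = NULL) {
  nr <- shape[1]; nc <- shape[2]
  mask <- matrix(TRUE, nr, nc)
  if (spec$border_px > 0) {
    if (spec$border_px >= min(nr, nc) / 2) stop("no background pixels")
    b <- spec$border_px
    inner <- matrix(FALSE, nr, nc)
    inner[(b + 1):(nr - b), (b + 1):(nc - b)] <- TRUE
    mask <- mask & !inner
  }
  if (!is.null(spec$binary_threshold)) {
    stopifnot(!is.null(phase))
    mask <- mask & (phase < spec$binary_threshold)
  }
  if (!any(mask)) stop("no background pixels")
  mask
}

# design matrix on centered, [-1, 1]-scaled coordinates
.bg_design <- function(nr, nc, profile) {
  u <- if (nr > 1) (2 * (seq_len(nr) - 1) / (nr - 1)) - 1 else rep(0, nr)
  v <- if (nc > 1) (2 * (seq_len(nc) - 1) / (nc - 1)) - 1 else rep(0, nc)
  U <- matrix(u, nr, nc); V <- matrix(v, nr, nc, byrow = TRUE)
  switch(profile,
    offset = cbind(rep(1, nr * nc)),
    tilt   = cbind(1, c(U), c(V)),
    poly2o = cbind(1, c(U), c(V), c(U)^2, c(V)^2, c(U) * c(V)),
    stop("unknown background profile: ", profile))
}

#' Fit a smooth background surface
#'
#' Least-squares fit of the requested profile over the masked pixels:
#' `offset` (mean or median constant), `tilt` (plane) or `poly2o` (full
#' second-order polynomial).  The fit is exact to numerical precision when
#' the masked phase is exactly of the model form.
#'
#' @param phase phase matrix, radians.
#' @param mask logical matrix of background pixels.
#' @param profile `"offset"`, `"tilt"` or `"poly2o"`.
#' @param offset_mode `"mean"` or `"median"` for the offset profile.
#' @return Background surface matrix with the shape of `phase`.
#' @export
fit_background <- function(phase, mask, profile = "poly2o",
                           offset_mode = "mean") {
  stopifnot(identical(dim(phase), dim(mask)), any(mask))
  nr <- nrow(phase); nc <- ncol(phase)
  if (profile == "offset") {
    val <- if (offset_mode == "median") stats::median(phase[mask]) else
      mean(phase[mask])
    return(matrix(val, nr, nc))
  }
  X <- .bg_design(nr, nc, profile)
  Xm <- X[c(mask), , drop = FALSE]
  need <- ncol(Xm)
  qr_d <- qr(Xm)
  if (qr_d$rank < need) stop("degenerate background mask")
  beta <- qr.coef(qr_d, phase[mask])
  matrix(X %*% beta, nr, nc)
}

#' Apply background correction to a phase image
#'
#' The fitted surface is subtracted from the phase; for the amplitude the
#' same machinery is applied with division (`amplitude / surface`).  Profile
#' `"image"` subtracts a reference phase / divides by a reference amplitude
#' without registration.
#'
#' @param qpi a [qpimage()].
#' @param spec a [bg_spec()].
#' @param what `"phase"`, `"amplitude"` or `"both"`.
#' @param amplitude_profile profile used for the amplitude surface
#'   (default `"offset"`).
#' @return Corrected [qpimage()].
#' @export
correct_background <- function(qpi, spec, what = "both",
                               amplitude_profile = "offset") {
  if (spec$profile == "image") {
    if (is.null(spec$reference)) stop("background profile 'image' needs a reference")
    if (what %in% c("phase", "both"))
      qpi$phase <- qpi$phase - spec$reference
    return(qpi)
  }
  if (what %in% c("phase", "both")) {
    mask <- make_background_mask(dim(qpi$phase), spec, qpi$phase)
    surf <- fit_background(qpi$phase, mask, spec$profile, spec$offset_mode)
    qpi$phase <- qpi$phase - surf
  }
  if (what %in% c("amplitude", "both")) {
    amask <- make_background_mask(dim(qpi$amplitude), spec, qpi$phase)
    asurf <- fit_background(qpi$amplitude, amask, amplitude_profile,
                            spec$offset_mode)
    if (all(asurf > 0)) qpi$amplitude <- qpi$amplitude / asurf
  }
  qpi
}
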