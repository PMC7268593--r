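#' Quantitative phase image
#'
#' Container pairing an unwrapped phase map (radians) with a normalized
#' amplitude map (1.0 = background) and the acquisition metadata needed for
#' quantitative analysis: imaging wavelength, pixel size, refractive index of
#' the surrounding medium, acquisition time and an identifier.
#'
#' @param phase 2-D numeric matrix, unwrapped phase in radians.
#' @param amplitude 2-D numeric matrix of the same shape, non-negative;
#'   defaults to all-ones.
#' @param wavelength imaging wavelength in meters.
#' @param pixel_size lateral pixel size in meters per pixel.
#' @param medium_index refractive index of the immersion medium.
#' @param time acquisition time in seconds.
#' @param identifier text identifier of the image.
#' @return An object of class `qpimage`.
#' @export
qpimage <- function(phase, amplitude = NULL, wavelength, pixel_size,
                    medium_index, time = 0, identifier = "") {
  phase <- as.matrix(phase)
  if (is.null(amplitude)) amplitude <- matrix(1, nrow(phase), ncol(phase))
  amplitude <- as.matrix(amplitude)
  stopifnot(all(is.finite(phase)), all(is.finite(amplitude)),
            all(amplitude >= 0), identical(dim(phase), dim(amplitude)),
            wavelength > 0, pixel_size > 0, medium_index >= 1)
  structure(list(phase = phase, amplitude = amplitude,
                 wavelength = wavelength, pixel_size = pixel_size,
                 medium_index = medium_index, time = time,
                 identifier = identifier),
            class = "qpimage")
}

#' @export
print.qpimage <- function(x, ...) {
  cat(sprintf(
    "qpimage '%s': %d x %d px, wavelength %.1f nm, pixel %.4f um, n_med %.4f\n",
    x$identifier, nrow(x$phase), ncol(x$phase), x$wavelength * 1e9,
    x$pixel_size * 1e6, x$medium_index))
  cat(sprintf("  phase range [%.3f, %.3f] rad, time %.3f s\n",
              min(x$phase), max(x$phase), x$time))
  invisible(x)
}

#' Sphere model parameters
#'
#' Parameters of a homogeneous dielectric sphere as seen by the forward
#' models: refractive index, radius and in-plane center position (sub-pixel
#' allowed; 0-based pixel coordinates, first array index = x).
#'
#' @param n refractive index of the sphere.
#' @param r radius in meters.
#' @param cx,cy center in pixels (0-based, `cx` along the first array axis).
#' @param phase_offset constant phase offset in radians.
#' @return An object of class `sphere_params`.
#' @export
sphere_params <- function(n, r, cx, cy, phase_offset = 0) {
  stopifnot(n > 0, r > 0, is.finite(cx), is.finite(cy))
  structure(list(n = n, r = r, cx = cx, cy = cy, phase_offset = phase_offset),
            class = "sphere_params")
}

#' Imaging grid specification
#'
#' Describes the detector grid: array shape, pixel size, wavelength and the
#' refractive index of the medium.  The wavenumber in the medium is
#' `k_m = 2 pi n_med / lambda`.
#'
#' @param shape integer vector `c(H, W)` in pixels.
#' @param pixel_size meters per pixel.
#' @param wavelength imaging wavelength in meters.
#' @param medium_index refractive index of the medium.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, pixel_size, wavelength, medium_index) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape >= 4), pixel_size > 0,
            wavelength > 0, medium_index >= 1)
  structure(list(shape = shape, pixel_size = pixel_size,
                 wavelength = wavelength, medium_index = medium_index,
                 k_m = 2 * pi * medium_index / wavelength),
            class = "grid_spec")
}

grid_of <- function(qpi) {
  grid_spec(dim(qpi$phase), qpi$pixel_size, qpi$wavelength, qpi$medium_index)
}
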