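# Versioned numeric constants.

# Default affine coefficients of the systematic Rytov correction, produced
# by calibrate_rytov_sc() at its default grid (beam-propagation references,
# x_true in 0.005..0.05, r_true in 2..7 um, 160^2 px at 0.13 um, 550 nm,
# n_med 1.335).  Regenerate with tools/calibrate.R after model changes.
.RYTOV_SC_COEFFS <- c(c_n0 = -0.00025475711, c_n1 = 1.0545875,
                      c_r0 = 1.0010101, c_r1 = -0.68474444)

#' Default Rytov-SC correction coefficients
#'
#' Affine coefficients `(c_n0, c_n1, c_r0, c_r1)` mapping a fitted Rytov
#' contrast/radius to corrected values; see [rytov_sc_correct()] and
#' [calibrate_rytov_sc()].
#'
#' @return Named numeric vector.
#' @export
rytov_sc_default_coeffs <- function() .RYTOV_SC_COEFFS
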