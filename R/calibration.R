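# Calibration harness for the systematic Rytov correction.
#
# Reference phase images are generated with the multislice beam-propagation
# model (bpm_field), which remains valid at arbitrary total phase in the
# forward-scattering regime and serves as the Mie-free independent
# reference; each image is fitted with the Rytov model, and the relation
# between true and fitted parameters is summarized by an affine law in the
# fitted contrast x_fit = n_fit/n_med - 1:
#   x_true  ~ c_n0 + c_n1 * x_fit
#   r_true / r_fit ~ c_r0 + c_r1 * x_fit
# The package's default coefficients (R/constants.R) were produced by this
# harness at its default grid.

#' Calibrate the Rytov systematic-correction coefficients
#'
#' Runs Rytov-model fits against beam-propagation reference images over a
#' grid of true contrasts and radii and regresses the affine correction
#' law.
#'
#' @param x_true relative index contrasts `n/n_med - 1` to simulate.
#' @param r_true radii to simulate, meters.
#' @param grid imaging grid used for the reference images.
#' @param supersample supersampling factor for the fits.
#' @return List with `coeffs` (named vector c_n0, c_n1, c_r0, c_r1) and
#'   `table` (per-case true/fitted values).
#' @export
calibrate_rytov_sc <- function(x_true = c(0.005, 0.02, 0.035, 0.05),
                               r_true = c(2e-6, 3.5e-6, 5e-6, 7e-6),
                               grid = grid_spec(c(160L, 160L), 0.13e-6,
                                                550e-9, 1.335),
                               supersample = 2L) {
  cases <- expand.grid(x = x_true, r = r_true)
  rows <- vector("list", nrow(cases))
  nmed <- grid$medium_index
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; r <- cases$r[i]
    p <- sphere_params(nmed * (1 + x), r,
                       (grid$shape[1] - 1) / 2, (grid$shape[2] - 1) / 2)
    ref <- bpm_field(p, grid)
    init <- edge_estimate(ref)
    fit <- fit_sphere_image(ref, model = "rytov", init = init,
                            supersample = supersample)
    rows[[i]] <- data.frame(x_true = x, r_true = r,
                            x_fit = fit$params$n / nmed - 1,
                            r_fit = fit$params$r,
                            converged = fit$converged)
  }
  tab <- do.call(rbind, rows)
  ok <- tab$converged
  # inverse-square weights equalize the *relative* recovery error across
  # the contrast range (the law is multiplicative)
  w <- 1 / tab$x_true[ok]^2
  fit_n <- stats::lm(x_true ~ x_fit, data = tab[ok, ], weights = w)
  fit_r <- stats::lm(I(r_true / r_fit) ~ x_fit, data = tab[ok, ], weights = w)
  coeffs <- c(c_n0 = unname(coef(fit_n)[1]), c_n1 = unname(coef(fit_n)[2]),
              c_r0 = unname(coef(fit_r)[1]), c_r1 = unname(coef(fit_r)[2]))
  list(coeffs = coeffs, table = tab)
}
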