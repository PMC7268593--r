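# Least-squares sphere-model fits to ROI phase data, dry-mass computation
# and per-ROI result assembly.
#
# The fit minimizes the sum of squared phase residuals over
# (n, r, cx, cy, phase_offset) with box bounds, using bounded
# Levenberg-Marquardt with finite differences.  Model images are evaluated
# on a supersampled grid and bin-averaged so that sub-pixel rim coverage
# does not bias the radius.

# evaluate a sphere model phase image with ss-fold supersampling
model_phase_image <- function(p, g, model = "projection", supersample = 2L) {
  ss <- as.integer(supersample)
  if (ss <= 1L) {
    return(switch(model,
      projection = projection_phase(p, g),
      rytov = ,
      "rytov-sc" = rytov_field(p, g)$phase,
      stop("unknown sphere model: ", model)))
  }
  gf <- grid_spec(g$shape * ss, g$pixel_size / ss, g$wavelength,
                  g$medium_index)
  pf <- sphere_params(p$n, p$r, p$cx * ss + (ss - 1) / 2,
                      p$cy * ss + (ss - 1) / 2, p$phase_offset)
  fine <- switch(model,
    projection = projection_phase(pf, gf),
    rytov = ,
    "rytov-sc" = suppressWarnings(rytov_field(pf, gf)$phase),
    stop("unknown sphere model: ", model))
  # bin-average ss x ss blocks (vectorized two-pass block mean)
  H <- g$shape[1]; W <- g$shape[2]
  a <- matrix(colMeans(matrix(fine, nrow = ss)), H, ss * W)
  t(matrix(colMeans(matrix(t(a), nrow = ss)), W, H))
}

#' Fit a sphere model to an ROI phase image
#'
#' Minimizes the pixelwise squared phase residual over
#' `(n, r, cx, cy, phase_offset)` with bounds
#' `n` in `[n_med - 0.05, n_med + 0.30]`, `r` in `[0.3, 3] * r_init`, center
#' inside the ROI, offset free.  Termination: relative cost improvement
#' below `tol` or `max_evals` model evaluations per parameter.  For model
#' `"rytov-sc"` the forward model is the Rytov field and the systematic
#' correction fills `params_corrected`.
#'
#' @param roi_qpi background-corrected [qpimage()] of one object.
#' @param model `"projection"`, `"rytov"` or `"rytov-sc"`.
#' @param init initial [sphere_params()], e.g. from [edge_estimate()].
#' @param tol relative cost-improvement tolerance.
#' @param max_evals model evaluations allowed per parameter.
#' @param supersample supersampling factor for model evaluation.
#' @param sc_coeffs Rytov-SC coefficients (`"rytov-sc"` only); default from
#'   the package calibration constants.
#' @return A `sphere_fit` object: `params`, `params_corrected` (or `NULL`),
#'   `model`, `cost`, `n_iterations`, `converged`, `residual_image`.
#' @export
fit_sphere_image <- function(roi_qpi, model = "projection", init = NULL,
                             tol = 1e-9, max_evals = 250L, supersample = 2L,
                             sc_coeffs = rytov_sc_default_coeffs()) {
  if (is.null(init)) stop("init missing: supply initial sphere parameters")
  g <- grid_of(roi_qpi)
  fwd_model <- if (model == "rytov-sc") "rytov" else model
  data <- roi_qpi$phase
  lower <- c(n = g$medium_index - 0.05, r = 0.3 * init$r, cx = 0, cy = 0,
             off = -Inf)
  upper <- c(n = g$medium_index + 0.30, r = 3 * init$r,
             cx = g$shape[1] - 1, cy = g$shape[2] - 1, off = Inf)
  par0 <- c(n = init$n, r = init$r, cx = init$cx, cy = init$cy,
            off = init$phase_offset)
  par0 <- pmin(pmax(par0, lower), upper)
  n_eval <- 0L
  resid_fn <- function(par) {
    n_eval <<- n_eval + 1L
    p <- sphere_params(par[1], par[2], par[3], par[4], par[5])
    mdl <- model_phase_image(p, g, fwd_model, supersample)
    r <- c(mdl - data)
    if (!all(is.finite(r))) r <- rep(1e6, length(r))
    r
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = tol, ptol = tol,
                                     maxfev = max_evals * length(par0),
                                     maxiter = 1024L)
  res <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn, control = ctrl)
  par <- res$par
  params <- sphere_params(par[["n"]], par[["r"]], par[["cx"]], par[["cy"]],
                          par[["off"]])
  mdl <- model_phase_image(params, g, fwd_model, supersample)
  resid <- data - mdl
  cost <- sum(resid^2)
  converged <- res$info %in% 1:4 && all(is.finite(resid))
  corrected <- NULL
  if (model == "rytov-sc")
    corrected <- rytov_sc_correct(params$n, params$r, g$medium_index,
                                  sc_coeffs)
  structure(list(params = params, params_corrected = corrected,
                 model = model, cost = cost,
                 n_iterations = res$niter, n_evals = n_eval,
                 converged = converged, residual_image = resid,
                 message = res$message),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("sphere_fit [%s]: n = %.5f, r = %.4f um, cost = %.3g rad^2, %s\n",
              x$model, x$params$n, x$params$r * 1e6, x$cost,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$params_corrected))
    cat(sprintf("  corrected: n_sc = %.5f, r_sc = %.4f um\n",
                x$params_corrected$n_sc, x$params_corrected$r_sc * 1e6))
  invisible(x)
}

#' Dry mass of a homogeneous sphere
#'
#' Barer relation `n = n_med + alpha c` integrated over the sphere volume:
#' `m = (4/3) pi r^3 (n - n_med) / alpha`.
#'
#' @param n,r fitted refractive index and radius (m).
#' @param n_med medium refractive index.
#' @param alpha refraction increment in mL/g (1 mL/g = 1e-6 m^3/g).
#' @return Mass in grams (negative if `n < n_med`).
#' @export
dry_mass_sphere <- function(n, r, n_med, alpha = 0.18) {
  stopifnot(alpha > 0)
  (4 / 3) * pi * r^3 * (n - n_med) / (alpha * 1e-6)
}

#' Dry mass from integrated phase
#'
#' `m = lambda px^2 sum(phi) / (2 pi alpha)`; equals [dry_mass_sphere()]
#' within discretization error for an exact projection-model sphere.
#'
#' @param roi_qpi background-corrected [qpimage()].
#' @param alpha refraction increment in mL/g.
#' @return Mass in grams.
#' @export
dry_mass_phase <- function(roi_qpi, alpha = 0.18) {
  stopifnot(alpha > 0)
  roi_qpi$wavelength * roi_qpi$pixel_size^2 * sum(roi_qpi$phase) /
    (2 * pi * alpha * 1e-6)
}

#' Summarize sphere fits into analysis records
#'
#' One row per ROI with identifier, acquisition time, radius, refractive
#' index, dry mass, medium index, model, method and convergence flag.
#' When a systematic correction is present its `(n_sc, r_sc)` are reported
#' instead of the raw fit.  Non-converged fits are retained (exclusion is
#' the user's call via the ignore list).
#'
#' @param fits list of `sphere_fit` objects.
#' @param qpis list of the fitted [qpimage()] ROIs (same order).
#' @param alpha refraction increment, mL/g.
#' @param method analysis method label (`"image"` or `"edge"`).
#' @return `data.frame` with one record per fit.
#' @export
summarize_fits <- function(fits, qpis, alpha = 0.18, method = "image") {
  stopifnot(length(fits) == length(qpis))
  if (!length(fits)) {
    return(data.frame(identifier = character(), time_s = numeric(),
                      radius_um = numeric(), refractive_index = numeric(),
                      dry_mass_pg = numeric(), medium_index = numeric(),
                      model = character(), method = character(),
                      converged = logical(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]; q <- qpis[[i]]
    if (!is.null(f$params_corrected)) {
      n <- f$params_corrected$n_sc; r <- f$params_corrected$r_sc
    } else {
      n <- f$params$n; r <- f$params$r
    }
    data.frame(identifier = q$identifier, time_s = q$time,
               radius_um = r * 1e6, refractive_index = n,
               dry_mass_pg = dry_mass_sphere(n, r, q$medium_index, alpha) * 1e12,
               medium_index = q$medium_index, model = f$model,
               method = method, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format analysis records as TSV text
#'
#' Fixed column order, tab delimiter, `.` decimal separator, deterministic
#' fixed-digit number formatting (so identical analyses produce
#' byte-identical files).
#'
#' @param records data.frame from [summarize_fits()].
#' @return Single TSV string including the header line.
#' @export
records_tsv <- function(records) {
  cols <- c("identifier", "time_s", "radius_um", "refractive_index",
            "dry_mass_pg", "medium_index", "model", "method", "converged")
  header <- paste(cols, collapse = "\t")
  if (!nrow(records)) return(paste0(header, "\n"))
  fmt <- function(x, d) formatC(x, digits = d, format = "f")
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                   records$identifier, fmt(records$time_s, 3),
                   fmt(records$radius_um, 4), fmt(records$refractive_index, 6),
                   fmt(records$dry_mass_pg, 3), fmt(records$medium_index, 5),
                   records$model, records$method,
                   ifelse(records$converged, "true", "false"))
  paste0(paste(c(header, lines), collapse = "\n"), "\n")
}
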