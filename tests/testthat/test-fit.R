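# sphere fitting, dry mass, result assembly

test_that("a noisy projection phantom is recovered within tight bounds", {
  g <- grid_spec(c(200L, 200L), 0.1e-6, 550e-9, 1.335)
  p <- centered_sphere(g, 1.360, 5e-6)
  spec <- phantom_spec(list(p), grid = g, noise_sigma = 0.01, seed = 42L)
  qpi <- gen_sphere_qpi(spec, "projection")$qpi
  fit <- fit_sphere_image(qpi, "projection", init = edge_estimate(qpi))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$n - 1.360), 0.001)
  expect_lt(abs(fit$params$r / 5e-6 - 1), 0.01)
})

test_that("initializing at the truth is a fixed point", {
  g <- grid_spec(c(128L, 128L), 0.1e-6, 550e-9, 1.335)
  p <- centered_sphere(g, 1.355, 4e-6)
  qpi <- qpimage(projection_phase(p, g), NULL, g$wavelength, g$pixel_size,
                 g$medium_index)
  fit <- fit_sphere_image(qpi, "projection", init = p, supersample = 1L)
  expect_true(fit$converged)
  expect_lt(fit$cost, 1e-12)
  expect_lte(fit$n_iterations, 3)
})

test_that("a Rytov phantom is recovered by the Rytov model", {
  g <- grid_small()
  p <- centered_sphere(g, 1.352, 4.5e-6)
  qpi <- suppressWarnings(rytov_field(p, g))
  fit <- fit_sphere_image(qpi, "rytov", init = edge_estimate(qpi))
  expect_lt(abs(fit$params$n - 1.352), 0.002)
  expect_lt(abs(fit$params$r / 4.5e-6 - 1), 0.02)
})

test_that("the optimum never costs more than the initial guess", {
  g <- grid_spec(c(128L, 128L), 0.1e-6, 550e-9, 1.335)
  p <- centered_sphere(g, 1.355, 4e-6)
  spec <- phantom_spec(list(p), grid = g, noise_sigma = 0.05, seed = 8L)
  qpi <- gen_sphere_qpi(spec, "projection")$qpi
  init <- sphere_params(1.345, 5e-6, 60, 66)
  cost0 <- sum((model_phase_image(init, grid_of(qpi), "projection") -
                  qpi$phase)^2)
  fit <- fit_sphere_image(qpi, "projection", init = init)
  expect_lte(fit$cost, cost0)
})

test_that("fits are invariant under integer-pixel translation", {
  g <- grid_spec(c(160L, 160L), 0.1e-6, 550e-9, 1.335)
  mk <- function(cx, cy) {
    p <- sphere_params(1.356, 4e-6, cx, cy)
    spec <- phantom_spec(list(p), grid = g, noise_sigma = 0.02, seed = 12L)
    qpi <- gen_sphere_qpi(spec, "projection")$qpi
    fit_sphere_image(qpi, "projection", init = edge_estimate(qpi))
  }
  f1 <- mk(79.5, 79.5); f2 <- mk(72.5, 85.5)
  expect_lt(abs(f1$params$n - f2$params$n), 5e-4)
  expect_lt(abs(f1$params$r / f2$params$r - 1), 0.005)
})

test_that("a missing init is an error and model blow-up is flagged", {
  g <- grid_small(32)
  qpi <- qpimage(matrix(0, 32, 32), NULL, g$wavelength, g$pixel_size,
                 g$medium_index)
  expect_error(fit_sphere_image(qpi, "projection"), "init")
})

test_that("sphere dry mass follows the Barer relation", {
  m <- dry_mass_sphere(1.355, 5e-6, 1.335, alpha = 0.18)
  expect_equal(m * 1e12, 58.2, tolerance = 0.001)  # pg
  expect_equal(dry_mass_sphere(1.335, 5e-6, 1.335), 0)
  expect_equal(dry_mass_sphere(1.355, 10e-6, 1.335) /
                 dry_mass_sphere(1.355, 5e-6, 1.335), 8, tolerance = 1e-12)
})

test_that("phase-integral and sphere dry mass agree on exact phantoms", {
  g <- grid_spec(c(400L, 400L), 0.05e-6, 550e-9, 1.335)
  p <- centered_sphere(g, 1.355, 5e-6)
  qpi <- qpimage(projection_phase(p, g), NULL, g$wavelength, g$pixel_size,
                 g$medium_index)
  mp <- dry_mass_phase(qpi)
  ms <- dry_mass_sphere(1.355, 5e-6, 1.335)
  expect_lt(abs(mp / ms - 1), 0.01)
  # zero phase -> zero mass; constant offset adds exactly its integral
  z <- qpimage(matrix(0, 50, 50), NULL, g$wavelength, g$pixel_size,
               g$medium_index)
  expect_equal(dry_mass_phase(z), 0)
  zc <- qpimage(matrix(0.2, 50, 50), NULL, g$wavelength, g$pixel_size,
                g$medium_index)
  expect_equal(dry_mass_phase(zc),
               g$wavelength * g$pixel_size^2 * 2500 * 0.2 /
                 (2 * pi * 0.18e-6), tolerance = 1e-12)
})

test_that("summaries report one row per ROI with corrected values", {
  g <- grid_small(64)
  qpis <- lapply(1:3, function(i)
    qpimage(matrix(0.1, 64, 64), NULL, g$wavelength, g$pixel_size,
            g$medium_index, time = i, identifier = sprintf("abcde_1.%d", i)))
  mkfit <- function(n, r, corrected = NULL, converged = TRUE) structure(
    list(params = sphere_params(n, r, 31.5, 31.5),
         params_corrected = corrected, model = "rytov-sc", cost = 0.1,
         n_iterations = 5L, converged = converged,
         residual_image = matrix(0, 2, 2)),
    class = "sphere_fit")
  fits <- list(mkfit(1.35, 4e-6),
               mkfit(1.35, 4e-6, list(n_sc = 1.36, r_sc = 4.2e-6)),
               mkfit(1.34, 3e-6, converged = FALSE))
  rec <- summarize_fits(fits, qpis)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$refractive_index[2], 1.36)   # corrected value reported
  expect_equal(rec$radius_um[2], 4.2)
  expect_false(rec$converged[3])                 # retained, flagged
  tsv <- records_tsv(rec)
  lines <- strsplit(tsv, "\n")[[1]]
  expect_length(lines, 4)  # header + 3 rows
  expect_match(lines[1], "^identifier\ttime_s\tradius_um")
  expect_identical(records_tsv(rec), tsv)  # deterministic formatting
})
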