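# background mask construction and surface fitting

test_that("border masks mark exactly the frame", {
  m <- make_background_mask(c(10L, 10L), bg_spec("offset", border_px = 2L))
  expect_equal(sum(m), 64)  # 100 - 36 interior
  expect_false(any(m[3:8, 3:8]))
})

test_that("threshold-only masks select sub-threshold phase", {
  ph <- matrix(seq(0, 1, length.out = 100), 10)
  spec <- bg_spec("offset", border_px = 0L, binary_threshold = Inf)
  expect_true(all(make_background_mask(c(10L, 10L), spec, ph)))
  spec2 <- bg_spec("offset", border_px = 0L, binary_threshold = 0.5)
  m <- make_background_mask(c(10L, 10L), spec2, ph)
  expect_identical(m, ph < 0.5)
})

test_that("an oversized border yields no background pixels", {
  expect_error(
    make_background_mask(c(60L, 60L), bg_spec("poly2o", border_px = 35L)),
    "no background pixels")
})

test_that("polynomial fits are exact on model-form surfaces", {
  nr <- 32; nc <- 32
  x <- matrix(0:(nr - 1), nr, nc); y <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  ph <- 2 + 0.5 * x + 1.0 * y - 0.1 * x * y + 0.2 * x^2
  mask <- matrix(TRUE, nr, nc)
  surf <- fit_background(ph, mask, "poly2o")
  expect_lt(max(abs(surf - ph)), 1e-9)

  const <- matrix(3.3, 16, 16)
  expect_equal(fit_background(const, matrix(TRUE, 16, 16), "offset"),
               const, tolerance = 1e-12)
})

test_that("a border mask recovers the plane under a central bump", {
  g <- grid_spec(c(96L, 96L), 0.1e-6, 550e-9, 1.335)
  bump <- projection_phase(centered_sphere(g, 1.35, 3e-6), g)
  x <- matrix(0:95, 96, 96); y <- t(x)
  plane <- 0.4 + 0.01 * x - 0.02 * y
  ph <- plane + bump
  mask <- make_background_mask(c(96L, 96L), bg_spec("tilt", border_px = 5L))
  surf <- fit_background(ph, mask, "tilt")
  expect_lt(max(abs(surf - plane)), 1e-6)
  corrected <- ph - surf
  expect_lt(max(abs(corrected - bump)), 1e-6)
})

test_that("offset mode median resists outliers in the mask", {
  ph <- matrix(1, 10, 10); ph[1, 1] <- 100
  m <- matrix(TRUE, 10, 10)
  expect_equal(fit_background(ph, m, "offset", "median")[1], 1)
  expect_gt(fit_background(ph, m, "offset", "mean")[1], 1.5)
})

test_that("background correction is idempotent", {
  set.seed(4)
  g <- grid_spec(c(64L, 64L), 0.1e-6, 550e-9, 1.335)
  ph <- projection_phase(centered_sphere(g, 1.35, 2e-6), g) +
    spherepipe:::.bg_poly_surface(c(64L, 64L), c(0.3, 0.2, -0.1, 0.05, 0.02, -0.04))
  qpi <- qpimage(ph, NULL, g$wavelength, g$pixel_size, g$medium_index)
  spec <- bg_spec("poly2o", border_px = 8L)
  once <- correct_background(qpi, spec, what = "phase")
  twice <- correct_background(once, spec, what = "phase")
  expect_lt(max(abs(twice$phase - once$phase)), 1e-9)
})

test_that("least-squares model nesting orders residuals on random masks", {
  set.seed(21)
  for (k in 1:5) {
    ph <- matrix(rnorm(30 * 30), 30)
    mask <- matrix(runif(900) < 0.4, 30)
    if (sum(mask) < 12) next
    res <- vapply(c("offset", "tilt", "poly2o"), function(pr) {
      s <- fit_background(ph, mask, pr)
      sum((ph - s)[mask]^2)
    }, 0)
    expect_lte(res[["poly2o"]], res[["tilt"]] + 1e-9)
    expect_lte(res[["tilt"]], res[["offset"]] + 1e-9)
    # corrected mean over the mask vanishes for the linear models
    s <- fit_background(ph, mask, "tilt")
    expect_lt(abs(mean((ph - s)[mask])), 1e-9)
  }
})

test_that("degenerate masks are rejected for polynomial profiles", {
  ph <- matrix(rnorm(400), 20)
  mask <- matrix(FALSE, 20, 20); mask[10, ] <- TRUE  # one line
  expect_error(fit_background(ph, mask, "poly2o"), "degenerate background mask")
})

test_that("amplitude background is corrected by division", {
  g <- grid_spec(c(40L, 40L), 0.1e-6, 550e-9, 1.335)
  amp <- matrix(1.7, 40, 40)
  qpi <- qpimage(matrix(0, 40, 40), amp, g$wavelength, g$pixel_size,
                 g$medium_index)
  out <- correct_background(qpi, bg_spec("offset", border_px = 4L),
                            what = "amplitude")
  expect_equal(out$amplitude, matrix(1, 40, 40), tolerance = 1e-9)
})
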