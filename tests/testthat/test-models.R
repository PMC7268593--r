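# sphere forward models: projection, Rytov, beam propagation, edge
# estimator, systematic correction

test_that("projection phase matches its closed forms", {
  g <- grid_spec(c(400L, 400L), 0.05e-6, 500e-9, 1.335)
  p <- centered_sphere(g, 1.355, 5e-6)
  ph <- projection_phase(p, g)
  # peak: (4 pi / lambda) dn r
  expect_equal(max(ph), 4 * pi / 500e-9 * 0.02 * 5e-6, tolerance = 1e-4)
  # volume integral: sum(phi) px^2 = (2 pi / lambda) dn (4/3) pi r^3
  lhs <- sum(ph) * g$pixel_size^2
  rhs <- (2 * pi / 500e-9) * 0.02 * (4 / 3) * pi * (5e-6)^3
  expect_equal(lhs, rhs, tolerance = 0.005)
  # zero contrast
  p0 <- centered_sphere(g, g$medium_index, 5e-6)
  p0$phase_offset <- 0.3
  expect_equal(projection_phase(p0, g), matrix(0.3, 400, 400))
})

test_that("projection phase is linear in the index contrast", {
  g <- grid_small(64)
  p1 <- centered_sphere(g, g$medium_index + 0.01, 3e-6)
  p2 <- centered_sphere(g, g$medium_index + 0.03, 3e-6)
  expect_equal(3 * projection_phase(p1, g), projection_phase(p2, g),
               tolerance = 1e-12)
})

test_that("forward models are translation-equivariant", {
  g <- grid_small(96)
  p <- sphere_params(1.35, 3e-6, 40, 44)
  ps <- sphere_params(1.35, 3e-6, 45, 49)
  for (fwd in list(function(p) projection_phase(p, g),
                   function(p) suppressWarnings(rytov_field(p, g))$phase)) {
    a <- fwd(p); b <- fwd(ps)
    expect_equal(a[11:80, 11:80], b[16:85, 16:85], tolerance = 1e-6)
  }
})

test_that("zero contrast gives a trivial Rytov field", {
  g <- grid_small(64)
  p <- centered_sphere(g, g$medium_index, 3e-6)
  p$phase_offset <- 0.1
  f <- rytov_field(p, g)
  expect_equal(f$phase, matrix(0.1, 64, 64), tolerance = 1e-12)
  expect_equal(f$amplitude, matrix(1, 64, 64), tolerance = 1e-12)
})

test_that("the Rytov field approaches the projection in the weak limit", {
  dev <- weak_scatter_deviation()
  expect_lt(dev$rms_rel[dev$dn == 5e-4], 0.02)
  expect_lt(dev$max_rel_inner[dev$dn == 5e-4], 0.02)
  expect_true(all(diff(dev$rms_rel) < 0))  # decreasing with dn
})

test_that("an under-resolved sphere triggers a sampling warning", {
  g <- grid_small(64, px = 0.5e-6)
  expect_warning(rytov_field(centered_sphere(g, 1.35, 2e-6), g),
                 "under-resolved")
})

test_that("the k-space Born field matches direct-space integration", {
  res <- born_oracle_check(nvox = 48L)
  expect_lt(res$max_rel_dev, 0.03)
})

test_that("the beam-propagation field agrees with Rytov at weak contrast", {
  g <- grid_small()
  p <- centered_sphere(g, g$medium_index * 1.005, 4e-6)
  b <- bpm_field(p, g)
  r <- suppressWarnings(rytov_field(p, g))
  expect_lt(sqrt(mean((b$phase - r$phase)^2)) / max(r$phase), 0.01)
})

test_that("edge estimation recovers noiseless phantom parameters", {
  g <- grid_spec(c(200L, 200L), 0.1e-6, 550e-9, 1.335)
  p <- centered_sphere(g, 1.355, 5e-6)
  qpi <- qpimage(projection_phase(p, g), NULL, g$wavelength, g$pixel_size,
                 g$medium_index)
  est <- edge_estimate(qpi)
  expect_lt(abs(est$r / 5e-6 - 1), 0.02)
  expect_lt(abs(est$n - 1.355), 0.002)
  expect_lt(abs(est$cx - p$cx), 1)
  expect_error(edge_estimate(qpimage(matrix(0, 64, 64), NULL, 550e-9,
                                     0.1e-6, 1.335)),
               "no object edge found")
})

test_that("the projection disk average identity holds", {
  g <- grid_spec(c(400L, 400L), 0.05e-6, 550e-9, 1.335)
  r <- 5e-6; dn <- 0.02
  p <- centered_sphere(g, g$medium_index + dn, r)
  ph <- projection_phase(p, g)
  co <- ((0:399) - 199.5) * g$pixel_size
  inside <- outer(co^2, co^2, `+`) <= r^2
  expect_equal(mean(ph[inside]), (2 * pi / g$wavelength) * dn * 4 * r / 3,
               tolerance = 0.005)
})

test_that("identity coefficients leave a Rytov fit uncorrected", {
  idc <- c(c_n0 = 0, c_n1 = 1, c_r0 = 1, c_r1 = 0)
  out <- rytov_sc_correct(1.36, 5e-6, 1.335, idc)
  expect_equal(out$n_sc, 1.36)
  expect_equal(out$r_sc, 5e-6)
  # pure offset term at zero fitted contrast
  co <- c(c_n0 = 0.01, c_n1 = 1, c_r0 = 1, c_r1 = 0)
  expect_equal(rytov_sc_correct(1.335, 5e-6, 1.335, co)$n_sc,
               1.335 * 1.01)
})

test_that("default correction recovers true contrast from Rytov fits", {
  # spot checks against beam-propagation references
  g <- grid_small()
  nmed <- g$medium_index
  for (case in list(c(x = 0.02, r = 3.5e-6), c(x = 0.045, r = 5e-6))) {
    p <- sphere_params(nmed * (1 + case[["x"]]), case[["r"]],
                       (g$shape[1] - 1) / 2, (g$shape[2] - 1) / 2)
    ref <- bpm_field(p, g)
    fit <- fit_sphere_image(ref, model = "rytov-sc",
                            init = edge_estimate(ref))
    x_sc <- fit$params_corrected$n_sc / nmed - 1
    expect_lt(abs(x_sc / case[["x"]] - 1), 0.05)
    expect_lt(abs(fit$params_corrected$r_sc / case[["r"]] - 1), 0.02)
  }
})
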