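# Fourier sideband detection, filters, reconstruction, unwrapping

make_holo <- function(carrier, g = grid_hl60(), n = 1.355, r = 5e-6, ...) {
  p <- centered_sphere(g, n, r)
  spec <- phantom_spec(list(p), grid = g, carrier = carrier, ...)
  qpi <- gen_sphere_qpi(spec, "projection")$qpi
  list(holo = gen_hologram(qpi, spec), qpi = qpi, spec = spec)
}

test_that("sideband detection recovers the carrier within one frequency bin", {
  h <- make_holo(c(0.8, 0.6))
  cs <- detect_sideband(h$holo)
  expect_lt(abs(cs$kx - 0.8), 2 * pi / 256)
  expect_lt(abs(cs$ky - 0.6), 2 * pi / 256)
})

test_that("a flat-field image has no sideband", {
  expect_error(detect_sideband(matrix(5, 128, 128)), "no sideband detected")
})

test_that("a carrier with ky < 0 is detected as its conjugate in ky >= 0", {
  h <- make_holo(c(0.8, -0.6))
  cs <- detect_sideband(h$holo)
  expect_gte(cs$ky, 0)
  expect_lt(abs(cs$kx + 0.8), 2 * pi / 256)
  expect_lt(abs(cs$ky - 0.6), 2 * pi / 256)
})

test_that("carrier detection is shift-equivariant over integer bins", {
  g <- grid_hl60()
  h1 <- make_holo(c(0.8, 0.6), g)
  dk <- 2 * pi * 4 / 256  # four bins
  h2 <- make_holo(c(0.8 + dk, 0.6), g)
  c1 <- detect_sideband(h1$holo); c2 <- detect_sideband(h2$holo)
  expect_equal(c2$kx - c1$kx, dk, tolerance = 0.1 * dk)
  expect_equal(c2$ky, c1$ky, tolerance = 2 * pi / 512)
})

test_that("filter shapes obey their defining properties", {
  cs <- structure(list(kx = 0.8, ky = 0.6, mode = "fixed"),
                  class = "carrier_spec")
  sh <- c(256L, 256L)
  R <- (1 / 3) * sqrt(0.8^2 + 0.6^2) * 256 / (2 * pi)
  kb <- c(0.8, 0.6) * 256 / (2 * pi)
  ctr_idx <- floor(256 / 2) + 1 + round(kb)  # nearest bin to the carrier

  disk <- make_filter(sh, cs, "disk")
  expect_equal(disk[ctr_idx[1], ctr_idx[2]], 1)
  bx <- spherepipe:::shifted_bins(256)
  dist <- sqrt(outer((bx - kb[1])^2, (bx - kb[2])^2, `+`))
  expect_true(all(disk[dist > 1.01 * R] == 0))
  expect_true(all(disk %in% c(0, 1)))

  gauss <- make_filter(sh, cs, "gauss")
  expect_equal(max(abs(gauss[abs(dist - R) < 0.02] - 0.5)), 0, tolerance = 0.01)
  expect_true(all(gauss >= 0 & gauss <= 1))

  sq <- make_filter(sh, cs, "square")
  cheb <- outer(abs(bx - kb[1]), abs(bx - kb[2]), pmax)
  expect_true(all(sq[cheb > 1.01 * R] == 0))

  sm <- make_filter(sh, cs, "smooth disk")
  expect_true(all(sm >= 0 & sm <= 1))
  expect_gt(sm[ctr_idx[1], ctr_idx[2]], 0.999)
  # monotone non-increasing along a ray from the carrier
  ray <- vapply(0:60, function(k) {
    i <- ctr_idx[1] + k
    if (i <= 256) sm[i, ctr_idx[2]] else NA_real_
  }, 0)
  ray <- ray[!is.na(ray)]
  expect_true(all(diff(ray) <= 1e-9))
  # essentially no support beyond the disk radius + 3 sigma (the smoothing
  # kernel is finitely truncated, so allow a tiny numerical tail)
  expect_true(all(sm[dist > R + 3 * (R / 10) + 1.5] < 1e-3))
})

test_that("undersized filters are rejected", {
  cs <- structure(list(kx = 0.05, ky = 0, mode = "fixed"),
                  class = "carrier_spec")
  expect_error(make_filter(c(64L, 64L), cs, "disk"), "filter too small")
})

test_that("unwrapping recovers ramps and steep sphere phases", {
  # plane 0.4 x + 0.2 y on 64^2
  x <- outer(0.4 * (0:63), 0.2 * (0:63), `+`)
  w <- (x + pi) %% (2 * pi) - pi
  u <- unwrap_phase(w)
  off <- u - x
  expect_equal(off, matrix(off[1], 64, 64), tolerance = 1e-9)
  expect_equal(off[1] %% (2 * pi), 0, tolerance = 1e-9)

  # already-smooth input with range < pi: identity up to a 2 pi offset
  sm <- outer(seq(0, 1, length.out = 32), seq(0, 1.5, length.out = 32))
  u2 <- unwrap_phase(sm)
  expect_equal(max(abs((u2 - sm) - round(mean(u2 - sm) / (2 * pi)) * 2 * pi)),
               0, tolerance = 1e-9)

  # projection sphere with 7 rad peak
  g <- grid_spec(c(128L, 128L), 0.1e-6, 550e-9, 1.335)
  r <- 5e-6
  dn <- 7 * g$wavelength / (4 * pi * r)
  phi <- projection_phase(centered_sphere(g, g$medium_index + dn, r), g)
  expect_equal(max(phi), 7, tolerance = 1e-3)
  u3 <- unwrap_phase((phi + pi) %% (2 * pi) - pi)
  expect_lt(max(abs(u3 - phi - round((u3 - phi)[1] / (2 * pi)) * 2 * pi)), 1e-6)
})

test_that("unwrap output is congruent to its input modulo 2 pi", {
  set.seed(11)
  w <- matrix(runif(32 * 32, -pi, pi), 32)
  u <- unwrap_phase(w)
  expect_lt(max(abs((u - w) / (2 * pi) - round((u - w) / (2 * pi)))), 1e-9)
})

test_that("reconstruction of a zero-phase object is flat", {
  g <- grid_hl60()
  # integer-bin carrier: the hologram is exactly periodic, so no spectral
  # leakage obscures the flatness check
  spec <- phantom_spec(list(sphere_params(g$medium_index, 5e-6, 127.5, 127.5)),
                       grid = g,
                       carrier = 2 * pi * c(64, 48) / 256)
  qpi <- gen_sphere_qpi(spec, "projection")$qpi
  holo <- gen_hologram(qpi, spec)
  rec <- reconstruct_hologram(holo, meta = default_meta(g))
  inner <- rec$phase[26:230, 26:230]
  expect_lt(max(abs(inner - mean(inner))), 1e-3)
})

test_that("hologram round trip recovers the phase", {
  expect_lt(holo_roundtrip_rms(0), 0.02)
  expect_lt(holo_roundtrip_rms(0.01, seed = 5L), 0.05)
})

test_that("scaling the fringe modulation scales amplitude, not phase", {
  g <- grid_hl60()
  p <- centered_sphere(g)
  cs <- structure(list(kx = 1.6, ky = 1.2, mode = "fixed"),
                  class = "carrier_spec")
  mk <- function(contrast) {
    spec <- phantom_spec(list(p), grid = g, fringe_contrast = contrast)
    gen_hologram(gen_sphere_qpi(spec, "projection")$qpi, spec)
  }
  r1 <- reconstruct_hologram(mk(0.8), carrier = cs, meta = default_meta(g))
  r2 <- reconstruct_hologram(mk(0.4), carrier = cs, meta = default_meta(g))
  inner <- 26:230
  expect_equal(r1$phase[inner, inner], r2$phase[inner, inner],
               tolerance = 1e-6)
  expect_equal(r1$amplitude[inner, inner] / r2$amplitude[inner, inner],
               matrix(2, length(inner), length(inner)), tolerance = 1e-3)
})

test_that("invert_phase flips the reconstructed phase sign", {
  g <- grid_hl60()
  h <- make_holo(c(1.6, 1.2), g)
  r1 <- reconstruct_hologram(h$holo, meta = default_meta(g))
  r2 <- reconstruct_hologram(h$holo, meta = default_meta(g),
                             invert_phase = TRUE)
  expect_equal(r1$phase, -r2$phase, tolerance = 1e-9)
})
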