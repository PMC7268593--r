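# threshold computation, object detection, ignore lists, ROI extraction

test_that("dm-nuclei threshold follows the trimmed-maximum formula", {
  ph <- matrix(c(rep(0, 99), 10), 10)  # mean 0.1, trimmed max 0
  expect_equal(compute_threshold(ph, "dm-nuclei"), 0.08, tolerance = 1e-12)
  expect_equal(compute_threshold(matrix(2.5, 8, 8), "dm-nuclei"), 2.5)
  expect_identical(compute_threshold(ph, 0.25), 0.25)
})

test_that("otsu separates a bimodal phase image", {
  set.seed(9)
  ph <- matrix(rnorm(1e4, 0, 0.05), 100)
  ph[30:60, 30:60] <- ph[30:60, 30:60] + 2
  t <- compute_threshold(ph, "otsu")
  expect_gt(t, 0.3); expect_lt(t, 1.8)
})

phantom3 <- function(noise = 0) {
  g <- grid_spec(c(512L, 512L), 0.1e-6, 550e-9, 1.335)
  centers <- list(c(100, 120), c(260, 380), c(400, 150))
  spheres <- lapply(centers, function(ct)
    sphere_params(1.36, 25 * g$pixel_size, ct[1], ct[2]))
  spec <- phantom_spec(spheres, grid = g, noise_sigma = noise, seed = 2)
  list(qpi = gen_sphere_qpi(spec, "projection")$qpi, centers = centers, g = g)
}

test_that("three projection spheres yield three ROIs containing their centers", {
  ph3 <- phantom3()
  rois <- find_rois(ph3$qpi$phase, size_px = 50, variation = 0.5,
                    pad_px = 10L, threshold_method = 0.2)
  expect_length(rois, 3)
  found <- vapply(ph3$centers, function(ct) {
    any(vapply(rois, function(r)
      r$r0 <= ct[1] && ct[1] < r$r1 && r$c0 <= ct[2] && ct[2] < r$c1, TRUE))
  }, TRUE)
  expect_true(all(found))
  # ordered and numbered by top-left corner
  expect_equal(vapply(rois, `[[`, 0L, "roi_index"), 1:3)
  r0s <- vapply(rois, `[[`, 0L, "r0")
  expect_true(all(diff(r0s) >= 0))
})

test_that("a tiny speck is filtered out by the size criterion", {
  ph3 <- phantom3()
  ph <- ph3$qpi$phase
  ph[30:33, 30:33] <- 1  # 4-px-diameter speck
  rois <- find_rois(ph, size_px = 50, variation = 0.5, pad_px = 10L,
                    threshold_method = 0.2)
  expect_length(rois, 3)
})

test_that("blank phase yields an empty ROI list", {
  expect_length(find_rois(matrix(0, 64, 64), size_px = 10, variation = 0.5,
                          pad_px = 2L, threshold_method = 0.5), 0)
})

test_that("size filtering is boundary-inclusive in equivalent diameter", {
  ph <- matrix(0, 64, 64)
  ph[20:29, 20:29] <- 1  # 100 px -> equivalent diameter 11.2838
  d <- 2 * sqrt(100 / pi)
  s <- d / 1.5  # |d - s| = 0.5 s exactly
  expect_length(find_rois(ph, size_px = s, variation = 0.5, pad_px = 0L,
                          threshold_method = 0.5), 1)
  expect_length(find_rois(ph, size_px = s, variation = 0.45, pad_px = 0L,
                          threshold_method = 0.5), 0)
})

test_that("holes are filled before measuring component size", {
  ph <- matrix(0, 64, 64)
  ph[20:40, 20:40] <- 1
  ph[28:32, 28:32] <- -1  # nucleolus-like dip -> hole in the binary mask
  area <- 21^2
  d <- 2 * sqrt(area / pi)
  rois <- find_rois(ph, size_px = d, variation = 0.1, pad_px = 0L,
                    threshold_method = 0.5)
  expect_length(rois, 1)
})

test_that("raising the threshold never grows the binary mask", {
  set.seed(14)
  ph <- matrix(rnorm(1e4), 100)
  expect_gte(sum(ph > 0.2), sum(ph > 0.6))
})

test_that("ignored ROIs are removed without renumbering", {
  mk <- function(img, roi) structure(
    list(image_index = img, roi_index = roi, r0 = 0L, r1 = 4L, c0 = 0L,
         c1 = 4L, identifier = sprintf("abcde_%d.%d", img, roi)),
    class = "roi")
  rois <- list(mk(9, 3), mk(9, 4), mk(10, 1))
  kept <- filter_ignored(rois, list(c(9, 4)))
  expect_equal(vapply(kept, `[[`, "", "identifier"),
               c("abcde_9.3", "abcde_10.1"))
  expect_identical(filter_ignored(rois, list()), rois)
  expect_warning(out <- filter_ignored(rois, list(c(7, 1))),
                 "matched no ROI")
  expect_length(out, 3)
})

test_that("ROI extraction crops exactly and applies the per-ROI correction", {
  g <- grid_spec(c(300L, 300L), 0.1e-6, 550e-9, 1.335)
  bump <- projection_phase(centered_sphere(g, 1.355, 6e-6), g)
  bg <- spherepipe:::.bg_poly_surface(c(300L, 300L),
                                      c(0.5, 0.3, -0.2, 0.1, -0.05, 0.08))
  qpi <- qpimage(bump + bg, NULL, g$wavelength, g$pixel_size, g$medium_index)
  roi <- structure(list(image_index = 1L, roi_index = 1L, r0 = 0L, r1 = 300L,
                        c0 = 0L, c1 = 300L, identifier = "abcde_1.1"),
                   class = "roi")
  # crop only
  raw <- extract_roi(qpi, roi, spec = NULL)
  expect_identical(raw$phase, qpi$phase)
  expect_identical(raw$identifier, "abcde_1.1")
  # poly2o with a 35-px border removes the smooth background
  cor <- extract_roi(qpi, roi, bg_spec("poly2o", border_px = 35L))
  border <- cor$phase[c(1:35, 266:300), ]
  expect_lt(max(abs(border)), 1e-3)
  # out-of-bounds ROI errors
  bad <- roi; bad$r1 <- 301L
  expect_error(extract_roi(qpi, bad), "bounds")
})

test_that("detection is deterministic for identical inputs", {
  ph3 <- phantom3(noise = 0.02)
  r1 <- find_rois(ph3$qpi$phase, 50, 0.5, 10L, "otsu", dataset = "aaaaa")
  r2 <- find_rois(ph3$qpi$phase, 50, 0.5, 10L, "otsu", dataset = "aaaaa")
  expect_identical(r1, r2)
})
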