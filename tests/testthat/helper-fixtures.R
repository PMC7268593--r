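# shared fixtures: small grids and quiet pipeline wrappers

grid_small <- function(n = 160L, px = 0.13e-6)
  grid_spec(c(n, n), px, 550e-9, 1.335)

grid_hl60 <- function(n = 256L) grid_spec(c(n, n), 0.107e-6, 550e-9, 1.335)

centered_sphere <- function(g, n = 1.355, r = 5e-6)
  sphere_params(n, r, (g$shape[1] - 1) / 2, (g$shape[2] - 1) / 2)

default_meta <- function(g) {
  list(wavelength = g$wavelength, pixel_size = g$pixel_size,
       medium_index = g$medium_index)
}

# tiny on-disk hologram dataset for pipeline tests (2 images x 2 spheres)
make_tiny_dataset <- function(dir, seed = 3L) {
  g <- grid_spec(c(320L, 320L), 0.107e-6, 550e-9, 1.335)
  gen_dataset(2L, 2L, dir, seed = seed, grid = g,
              r_range = c(3e-6, 5e-6), n_range = c(1.35, 1.365))
}

tiny_overrides <- function(extra = list()) {
  utils::modifyList(list(
    "meta.wavelength_nm" = 550, "meta.pixel_size_um" = 0.107,
    "meta.medium_index" = 1.335, "roi.size_um" = 8,
    "roi.size_variation" = 0.6, "roi.threshold" = "0.15",
    "bg.sensor_profile" = "poly2o"), extra)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
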