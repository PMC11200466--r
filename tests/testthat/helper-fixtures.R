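# Shared fixtures, built once per test run.

default_grid <- kspace_grid(240, 128)

# noiseless default disk phantom and its reference reconstruction
noiseless_disk_spec <- build_disk_phantom(sigma = 0)
noiseless_disk_img <- simulate_phantom(noiseless_disk_spec)

# small grid for cheap noise statistics
small_grid <- kspace_grid(240, 64)

# analytic continuous-disk oracle: magnitude rasterized on a grid `factor`
# times finer than the reconstruction grid (pure indicator, no ringing)
rasterize_disk_dense <- function(radius_mm, fov_mm = 240, n = 128, factor = 16) {
  nn <- n * factor
  cc <- (seq_len(nn) - 0.5 - nn / 2) * fov_mm / nn
  x <- matrix(cc, nn, nn, byrow = TRUE)
  y <- matrix(cc, nn, nn)
  (x^2 + y^2) <= radius_mm^2
}

# wrap a plain magnitude matrix as a phantom_image on a given grid
as_phantom_image <- function(mag, grid, spec = NULL) {
  structure(list(magnitude = mag, complex_image = mag + 0i,
                 pixel_mm = grid$pixel_mm, grid = grid, spec = spec),
            class = "phantom_image")
}
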