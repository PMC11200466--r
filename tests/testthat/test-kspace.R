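test_that("jinc has the analytic DC limit and vanishes at the first Bessel root", {
  expect_equal(jinc(0, 1), pi)
  expect_equal(jinc(0, 95), pi * 95^2)
  # independent oracle: first positive root of J1 from uniroot on besselJ
  z1 <- uniroot(function(z) besselJ(z, 1), c(3, 4.5), tol = 1e-12)$root
  for (R in c(1, 10, 95)) {
    kr <- z1 / (2 * pi * R)
    expect_lt(abs(jinc(kr, R)) / jinc(0, R), 1e-10)
  }
  expect_true(all(is.finite(jinc(seq(0, 5, by = 0.01), 95))))
  expect_error(jinc(0.1, -1), class = "droiq_invalid_parameter")
})

test_that("kspace grid spacing, DC sample and pixel size are exact", {
  g <- default_grid
  expect_identical(g$pixel_mm, 1.875)
  expect_equal(diff(g$kx[1, ]), rep(1 / 240, 127))
  expect_equal(diff(g$ky[, 1]), rep(1 / 240, 127))
  expect_identical(sum(g$kr == 0), 1L)           # DC present exactly once
  expect_identical(g$kr[65, 65], 0)
  expect_error(kspace_grid(240, 127), class = "droiq_invalid_parameter")
})

test_that("centered disk k-space is real with DC value I * pi R^2", {
  ks <- disk_kspace(default_grid, disk_spec(95, 0.5))
  expect_lt(max(abs(Im(ks$values))), 1e-9)
  expect_equal(Re(ks$values[65, 65]), 0.5 * pi * 95^2)
})

test_that("off-centering is a pure phase shift (Fourier shift theorem)", {
  ks0 <- disk_kspace(default_grid, disk_spec(30, 0.5))
  ks1 <- disk_kspace(default_grid, disk_spec(30, 0.5, xc_mm = 10))
  expect_equal(Mod(ks1$values), Mod(ks0$values), tolerance = 1e-10)
  # phase at sample (kx, ky) is -2 pi * 10 * kx
  ph <- Arg(ks1$values / ks0$values)
  expected <- ((-2 * pi * 10 * default_grid$kx + pi) %% (2 * pi)) - pi
  nz <- Mod(ks0$values) > 1e-6
  expect_equal(((ph - expected + pi) %% (2 * pi) - pi)[nz],
               rep(0, sum(nz)), tolerance = 1e-8)
  # property over random disks
  set.seed(42)
  for (i in 1:5) {
    r <- runif(1, 1, 40); off <- runif(2, -30, 30)
    a <- disk_kspace(default_grid, disk_spec(r, 1))
    b <- disk_kspace(default_grid, disk_spec(r, 1, off[1], off[2]))
    expect_equal(Mod(b$values), Mod(a$values), tolerance = 1e-10)
  }
})

test_that("compound k-space is linear in its disks", {
  d <- disk_spec(20, 0.3, 5, -7)
  single <- compound_kspace(default_grid, list(d))
  expect_identical(single$values, disk_kspace(default_grid, d)$values)
  double <- compound_kspace(default_grid, list(d, d))
  expect_equal(double$values, 2 * single$values)
  cancel <- compound_kspace(default_grid, list(d, disk_spec(20, -0.3, 5, -7)))
  expect_equal(max(Mod(cancel$values)), 0)
  expect_error(compound_kspace(default_grid, list()),
               class = "droiq_invalid_parameter")
})

test_that("noise is calibrated to per-channel image std sigma and reproducible", {
  zero_ks <- compound_kspace(small_grid, list(disk_spec(1, 0)))
  sigma <- 0.04
  # pooled per-channel std over 100 realizations; 3 Monte-Carlo SEs
  reals <- vapply(1:100, function(k) {
    img <- ifft_reconstruct(add_complex_noise(zero_ks, sigma, seed = 1000 + k))
    c(sd(Re(img$complex_image)), sd(Im(img$complex_image)))
  }, numeric(2))
  n_samp <- 100 * 64^2
  se <- sigma / sqrt(2 * n_samp)
  pooled <- sqrt(mean(reals^2))       # both channels pooled
  expect_lt(abs(pooled - sigma), 3 * se)
  # sigma = 0 returns the input unchanged; same seed gives identical output
  expect_identical(add_complex_noise(zero_ks, 0, seed = 1), zero_ks)
  a <- add_complex_noise(zero_ks, sigma, seed = 7)
  b <- add_complex_noise(zero_ks, sigma, seed = 7)
  expect_identical(a$values, b$values)
  expect_error(add_complex_noise(zero_ks, -0.1, seed = 1),
               class = "droiq_invalid_parameter")
})

test_that("ifft reconstruction: zeros, symmetry, amplitude and round trip", {
  g <- default_grid
  zeros <- compound_kspace(g, list(disk_spec(1, 0)))
  expect_equal(max(ifft_reconstruct(zeros)$magnitude), 0)
  # centered disk reconstructs symmetric under flips
  img <- noiseless_disk_img
  m <- img$magnitude
  flip_lr <- m[, c(1, ncol(m):2)]   # mirror about the center column (col 65)
  flip_ud <- m[c(1, nrow(m):2), ]
  expect_equal(m[2:128, 2:128], flip_lr[2:128, 2:128], tolerance = 1e-10)
  expect_equal(m[2:128, 2:128], flip_ud[2:128, 2:128], tolerance = 1e-10)
  # amplitude convention: interior mean equals the designed intensity to 1%
  co <- pixel_coords(g)
  expect_equal(mean(m[co$r_mm < 80]), 0.5, tolerance = 0.01)
  # forward FFT round trip at machine precision
  ks <- disk_kspace(g, disk_spec(40, 0.7, 3, -11))
  back <- fft_forward(ifft_reconstruct(ks))
  expect_equal(back$values, ks$values, tolerance = 1e-12)
})

test_that("identical spec and seed give bit-identical k-space and image", {
  spec <- build_disk_phantom(sigma = 0.04, seed = 99L)
  a <- simulate_phantom(spec, realization = 3L)
  b <- simulate_phantom(spec, realization = 3L)
  expect_identical(a$magnitude, b$magnitude)
  expect_identical(a$complex_image, b$complex_image)
  c <- simulate_phantom(spec, realization = 4L)
  expect_false(identical(a$magnitude, c$magnitude))
})
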