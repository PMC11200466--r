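# triangular bump of half-width w (samples) centered at c, height h
add_bump <- function(prof, c, w, h) {
  idx <- max(1, c - w):min(length(prof), c + w)
  prof[idx] <- prof[idx] + h * (1 - abs(idx - c) / w)
  prof
}

test_that("row peak detection: constructed bumps, merging and degenerate input", {
  px <- 1.875
  prof <- rep(0, 60)
  for (c in c(10, 22, 34, 46)) prof <- add_bump(prof, c, 3, 1)
  expect_identical(detect_row_peaks(prof, radius_mm = 2, pixel_mm = px), 4L)
  # constant profile: no local maxima
  expect_identical(detect_row_peaks(rep(1, 30), 1, px), 0L)
  # two bumps closer than two radii merge to one detection:
  # centers 3 samples apart = 5.6 mm < 2 * radius (6 mm)
  prof2 <- add_bump(add_bump(rep(0, 30), 12, 2, 1), 15, 2, 0.9)
  expect_identical(detect_row_peaks(prof2, radius_mm = 3, pixel_mm = px), 1L)
  # same two bumps pass with a permissive radius
  expect_identical(detect_row_peaks(prof2, radius_mm = 2, pixel_mm = px), 2L)
  expect_error(detect_row_peaks(c(1, 2), 1, px), class = "droiq_invalid_input")
})

test_that("otsu threshold separates two-level data and is scale-covariant", {
  set.seed(5)
  v <- c(rnorm(300, 0.1, 0.02), rnorm(100, 0.9, 0.02))
  th <- otsu_threshold(v)
  expect_gt(th, 0.2); expect_lt(th, 0.8)
  # affine covariance => decisions invariant under scaling
  th2 <- otsu_threshold(10 * v + 3)
  expect_equal(th2, 10 * th + 3, tolerance = 0.05)
})

test_that("resolution score: noiseless phantom resolves <= 1.8 mm, scale-invariant", {
  spec <- build_resolution_phantom(sigma = 0)
  img <- simulate_phantom(spec)
  rs <- resolution_score(img, spec)
  expect_lte(rs$achieved_mm_x, 1.8)
  expect_lte(rs$achieved_mm_y, 1.8)
  expect_true(all(rs$per_row_peaks$peaks >= 0 & rs$per_row_peaks$peaks <= 6))
  # achieved resolutions are members of {2r} of the design
  expect_true(rs$achieved_mm_x %in% (2 * spec$layout$radii_mm))
  # global intensity scaling changes nothing (Otsu on the profile's own scale)
  sc <- as_phantom_image(img$magnitude * 11, spec$grid, spec = spec)
  rs2 <- resolution_score(sc, spec)
  expect_identical(rs2$per_row_peaks$peaks, rs$per_row_peaks$peaks)
  expect_error(resolution_score(noiseless_disk_img, noiseless_disk_spec),
               class = "droiq_invalid_phantom")
})

test_that("templates are deterministic, centered and linear in contrast", {
  t1 <- make_template(2.0, contrast = 0.2, grid = default_grid)
  t2 <- make_template(2.0, contrast = 0.2, grid = default_grid)
  expect_identical(t1, t2)
  expect_identical(dim(t1), c(7L, 7L))
  expect_identical(which(t1 == max(t1)), 25L)   # patch center of a 7x7
  # bump above background scales linearly with contrast
  t4 <- make_template(2.0, contrast = 0.4, grid = default_grid)
  bg <- 0.5
  expect_equal((max(t4) - bg) / (max(t1) - bg), 2, tolerance = 0.02)
})

test_that("sliding correlation equals brute-force enumeration and handles edge cases", {
  # self-correlation peaks at 1
  tp <- make_template(2.5, grid = default_grid, template_px = 7L)
  self <- sliding_correlation(tp, tp)
  expect_equal(self$max, 1)
  # anti-correlated equal-size patch
  anti <- sliding_correlation(-tp, tp, shift_range = 0L)
  expect_lte(anti$max, 0)
  # zero-variance patch flags degenerate
  z <- sliding_correlation(matrix(1, 10, 10), matrix(1, 7, 7))
  expect_true(z$degenerate); expect_identical(z$max, 0)
  # brute-force oracle on random patch/template pairs (exact agreement)
  set.seed(99)
  for (i in 1:20) {
    patch <- matrix(rnorm(100), 10, 10)
    templ <- matrix(rnorm(49), 7, 7)
    res <- sliding_correlation(patch, templ)
    brute <- -Inf
    for (r0 in 1:4) for (c0 in 1:4) {
      v <- cor(as.vector(patch[r0:(r0 + 6), c0:(c0 + 6)]), as.vector(templ))
      brute <- max(brute, v)
    }
    expect_identical(res$max, brute)
  }
  # a template cut from an off-center window is recovered exactly at the
  # compensating shift
  patch <- matrix(rnorm(100), 10, 10)
  templ <- patch[2:8, 3:9]
  res <- sliding_correlation(patch, templ)
  expect_equal(res$max, 1)
  expect_identical(which(res$map == res$max, arr.ind = TRUE)[1, ],
                   c(row = 2L, col = 3L))
})

test_that("threshold calibration: noiseless separation and the null case", {
  g <- default_grid
  cal0 <- calibrate_threshold(3.5, sigma = 0, n_per_class = 5L, seed = 2L, grid = g)
  expect_equal(cal0$calibration_accuracy, 1)
  expect_true(cal0$reliable)
  expect_true(all(cal0$scores[cal0$labels == 1] > cal0$threshold))
  # contrast 0: present and absent identically distributed -> chance accuracy
  caln <- calibrate_threshold(3.5, sigma = 0.04, contrast = 0, n_per_class = 25L,
                              seed = 3L, grid = g)
  expect_lt(caln$calibration_accuracy, 0.70)
  expect_false(caln$reliable)
  expect_error(calibrate_threshold(3.5, 0.02, n_per_class = 1L),
               class = "droiq_invalid_parameter")
})

test_that("visible spokes: noiseless perfection and the unreliable short-circuit", {
  spec <- build_lowcontrast_phantom(sigma = 0)
  img <- simulate_phantom(spec)
  mk_th <- function(r, reliable) structure(
    list(disk_radius_mm = r, sigma = 0, contrast = 0.2,
         threshold = 0.5, calibration_accuracy = if (reliable) 1 else 0.5,
         reliable = reliable), class = "detection_threshold")
  all_ok <- lapply(spec$layout$spoke_radii_mm, mk_th, reliable = TRUE)
  sc <- count_visible_spokes(img, spec, all_ok)
  expect_identical(sc$n_visible, 10L)
  expect_true(all(sc$spokes$visible))
  none <- lapply(spec$layout$spoke_radii_mm, mk_th, reliable = FALSE)
  sc0 <- count_visible_spokes(img, spec, none)
  expect_identical(sc0$n_visible, 0L)
  expect_error(count_visible_spokes(img, spec, all_ok[1:3]),
               class = "droiq_configuration_error")
})
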