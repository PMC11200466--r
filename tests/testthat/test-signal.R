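# build an esf object whose central differences equal a chosen derivative
# exactly: y[k+1] = y[k-1] - 2 h g(x[k])
esf_from_derivative <- function(g, x0 = 95, span = 15, h = 0.1875 / 10,
                                y_start = c(1, 1)) {
  x <- seq(x0 - span, x0 + span, by = h)
  n <- length(x)
  y <- numeric(n)
  y[1:2] <- y_start
  for (k in 2:(n - 1)) y[k + 1] <- y[k - 1] - 2 * h * g(x[k])
  structure(list(distance_mm = x, intensity = y, raw_intensity = y,
                 window_mm = range(x), sigmoid_fit = NULL), class = "esf")
}

lorentz <- function(x, A, G, x0, B = 0) A * (1 / pi) * (G / 2) / ((x - x0)^2 + (G / 2)^2) + B

test_that("ESF extraction: grid spacing, half-crossing near the edge", {
  esf <- extract_esf(noiseless_disk_img, radius_mm = 95)
  expect_equal(unique(round(diff(esf$distance_mm), 10)), 1.875 / 10)
  expect_true(all(diff(esf$distance_mm) > 0))
  expect_true(min(esf$distance_mm) < 95 && max(esf$distance_mm) > 95)
  # half-amplitude crossing within 0.5 mm of the designed radius
  y <- esf$intensity
  half <- (max(y) + min(y)) / 2
  xc <- esf$distance_mm[which.min(abs(y - half))]
  expect_lt(abs(xc - 95), 0.5)
  expect_error(extract_esf(noiseless_disk_img, radius_mm = 115, window_mm = 15),
               class = "droiq_invalid_window")
})

test_that("step edges from dense rasterization produce monotone ESFs", {
  # analytic disk indicator (no ringing), averaged to the acquisition grid
  dense <- rasterize_disk_dense(95, factor = 4)
  m <- matrix(0, 128, 128)
  f <- 4
  for (i in 1:128) for (j in 1:128)
    m[i, j] <- mean(dense[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
  img <- as_phantom_image(0.5 * m, default_grid)
  esf <- extract_esf(img, radius_mm = 95, smooth = FALSE)
  y <- esf$intensity
  # smooth the tiny bin-to-bin jitter: strictly decreasing on a 5-bin scale
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys <- ys[!is.na(ys)]
  expect_true(all(diff(ys) <= 1e-9))
})

test_that("Lorentzian fit recovers exact parameters and known widths", {
  esf <- esf_from_derivative(function(x) lorentz(x, A = 1, G = 1, x0 = 95))
  fit <- fit_lorentzian(esf)
  expect_equal(fit$fwhm_mm, 1.0, tolerance = 1e-6)
  expect_equal(fit$center_mm, 95, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$offset, 0, tolerance = 1e-8)
})

test_that("Lorentzian parameter recovery within 5% under 1% noise", {
  h <- 0.1875 / 10
  for (G_true in c(0.5, 1.0, 2.0)) {
    rec <- vapply(1:11, function(rep) {
      set.seed(1000 * G_true + rep)
      esf <- esf_from_derivative(function(x) lorentz(x, A = 1, G = G_true, x0 = 95))
      amp <- max(esf$intensity) - min(esf$intensity)
      esf$intensity <- esf$intensity + rnorm(length(esf$intensity), sd = 0.01 * amp)
      fit_lorentzian(esf)$fwhm_mm
    }, numeric(1))
    expect_lt(abs(median(rec) - G_true) / G_true, 0.05)
  }
})

test_that("sharpness is affine-invariant and grows under blurring", {
  g0 <- sharpness(noiseless_disk_img)
  # affine intensity transform a * I + b, a > 0
  aff <- as_phantom_image(2.4 * noiseless_disk_img$magnitude + 0.07, default_grid)
  expect_equal(sharpness(aff, radius_mm = 95), g0, tolerance = 1e-6)
  # Gaussian blur strictly increases the fitted FWHM
  blurred <- as_phantom_image(
    EBImage::gblur(noiseless_disk_img$magnitude, sigma = 1), default_grid)
  expect_gt(sharpness(blurred, radius_mm = 95), g0)
})

test_that("difference SNR matches the designed I/sigma and its invariances", {
  spec <- build_disk_phantom(sigma = 0.04, seed = 21L)
  ks0 <- phantom_kspace(spec)
  imgs <- lapply(1:6, function(k) simulate_phantom(spec, k, kspace0 = ks0))
  snrs <- vapply(c(1, 3, 5), function(k)
    snr_difference(imgs[[k]], imgs[[k + 1]]), numeric(1))
  # designed SNR oracle: I / sigma = 12.5, Monte-Carlo tolerance
  expect_equal(mean(snrs), 12.5, tolerance = 0.05)
  # symmetry and common-scaling invariance
  s12 <- snr_difference(imgs[[1]], imgs[[2]])
  s21 <- snr_difference(imgs[[2]], imgs[[1]])
  expect_equal(s12, s21, tolerance = 0.02)
  sc <- function(im, a) as_phantom_image(im$magnitude * a, default_grid)
  expect_equal(snr_difference(sc(imgs[[1]], 3), sc(imgs[[2]], 3),
                              ellipse = detect_disk(imgs[[1]])),
               snr_difference(imgs[[1]], imgs[[2]],
                              ellipse = detect_disk(imgs[[1]])),
               tolerance = 1e-10)
  expect_error(snr_difference(imgs[[1]], imgs[[1]]),
               class = "droiq_degenerate_input")
})
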