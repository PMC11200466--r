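#' Extract the radial edge spread function (ESF) of the disk edge
#'
#' Computes each pixel's exact distance to the designed disk center,
#' restricts to a radial window around the designed radius, and bins the
#' intensities onto a uniform distance grid with 1/10-pixel spacing (the
#' fine sampling of the continuous edge afforded by the incommensurate
#' pixel distances). For noisy images (`smooth = TRUE`, the default when
#' the generating spec has `sigma > 0`) the binned ESF is replaced by its
#' four-parameter logistic (sigmoid) fit for robustness against noise.
#'
#' @param image A `phantom_image`.
#' @param center_mm Designed disk center (mm from FOV center), default the
#'   origin.
#' @param radius_mm Designed disk radius (mm); the window is centered here.
#' @param window_mm Half-width of the radial window (default 15 mm, i.e.
#'   8 pixels at the default resolution).
#' @param smooth Replace the binned ESF by its sigmoid fit; `NULL` (default)
#'   means "when the image's generating spec is noisy".
#' @return An object of class `esf`: `distance_mm` (uniform, strictly
#'   increasing, spacing `pixel_mm / 10`), `intensity`, `raw_intensity`,
#'   `window_mm`, `sigmoid_fit` (or NULL).
#' @export
extract_esf <- function(image, center_mm = c(0, 0), radius_mm = 95,
                        window_mm = 15, smooth = NULL) {
  stopifnot(inherits(image, "phantom_image"))
  px <- image$pixel_mm
  co <- pixel_coords(image$grid)
  d <- sqrt((co$x_mm - center_mm[1])^2 + (co$y_mm - center_mm[2])^2)
  lo <- radius_mm - window_mm; hi <- radius_mm + window_mm
  if (hi > min(image$grid$fov_mm / 2, max(d)))
    abort_droiq("ESF window extends outside the image", "droiq_invalid_window")
  sel <- d >= lo & d <= hi
  grid_mm <- seq(lo, hi, by = px / 10)
  bin <- findInterval(d[sel], grid_mm - px / 20)
  esf <- tapply(image$magnitude[sel], factor(bin, levels = seq_along(grid_mm)), mean)
  x <- grid_mm
  y <- as.numeric(esf)
  # rare empty bins (no pixel lands in a 1/10-pixel annulus) are filled by
  # linear interpolation so the grid stays uniform
  if (anyNA(y)) {
    ok <- !is.na(y)
    y <- stats::approx(x[ok], y[ok], xout = x, rule = 2)$y
  }
  if (is.null(smooth))
    smooth <- !is.null(image$spec) && image$spec$noise_sigma > 0
  fit <- NULL
  if (isTRUE(smooth)) {
    fit <- fit_sigmoid(x, y, x0 = radius_mm, s0 = px / 2)
    y_s <- stats::predict(fit, list(x = x))
  } else y_s <- y
  structure(list(distance_mm = x, intensity = y_s, raw_intensity = y,
                 window_mm = c(lo, hi), sigmoid_fit = fit),
            class = "esf")
}

# 4-parameter logistic, decreasing outward: L + (U - L)/(1 + exp((x - x0)/s));
# tails initialize L (outside) and U (inside), x0 at the designed radius,
# slope half a pixel.
#' @noRd
fit_sigmoid <- function(x, y, x0, s0) {
  n <- length(y)
  ntail <- max(3L, n %/% 10L)
  start <- list(L = mean(utils::tail(y, ntail)), U = mean(utils::head(y, ntail)),
                x0 = x0, s = s0)
  minpack.lm::nlsLM(y ~ L + (U - L) / (1 + exp((x - x0) / s)),
                    start = start,
                    lower = c(-Inf, -Inf, min(x), 1e-4),
                    control = minpack.lm::nls.lm.control(maxiter = 200))
}

#' Fit a Lorentzian to the ESF derivative; FWHM is the sharpness
#'
#' Numerically differentiates the (possibly sigmoid-smoothed) ESF with
#' central differences on the uniform grid, negates it (the edge falls
#' outward, so the derivative peak is made positive), and least-squares
#' fits the four-parameter Lorentzian
#' `L(x) = A * (1/pi) * (G/2) / ((x - x0)^2 + (G/2)^2) + B`.
#' The fitted full width at half maximum `G` (mm) is the sharpness
#' metric: it is invariant to affine intensity transforms of the image
#' and grows under blurring.
#'
#' @param esf An [extract_esf()] result with at least 10 samples on each
#'   side of the edge.
#' @return An object of class `lorentzian_fit`: `amplitude`, `offset`,
#'   `fwhm_mm`, `center_mm`, `residual_norm`, and the `nls` `fit` object.
#' @export
fit_lorentzian <- function(esf) {
  stopifnot(inherits(esf, "esf"))
  x <- esf$distance_mm; y <- esf$intensity
  n <- length(x)
  if (n < 21L)
    abort_droiq("ESF must span the edge with >= 10 samples per side",
                "droiq_invalid_input")
  dy <- -(y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  xd <- x[2:(n - 1)]
  pk <- which.max(dy)
  half <- dy[pk] / 2
  above <- which(dy >= half)
  g0 <- max(diff(range(xd[above])), mean(diff(xd)))
  a0 <- sum(dy) * mean(diff(xd))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      dy ~ A * (1 / pi) * (G / 2) / ((xd - x0)^2 + (G / 2)^2) + B,
      start = list(A = a0, B = 0, x0 = xd[pk], G = g0),
      lower = c(-Inf, -Inf, min(xd), 1e-6),
      upper = c(Inf, Inf, max(xd), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) abort_droiq(
      sprintf("Lorentzian fit failed (init A=%.3g, x0=%.3g, G=%.3g): %s",
              a0, xd[pk], g0, conditionMessage(e)),
      "droiq_fit_failure"))
  cf <- stats::coef(fit)
  structure(list(amplitude = cf[["A"]], offset = cf[["B"]],
                 fwhm_mm = cf[["G"]], center_mm = cf[["x0"]],
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 fit = fit),
            class = "lorentzian_fit")
}

#' Edge sharpness of a disk phantom image (convenience wrapper)
#'
#' @param image A `phantom_image` of a disk phantom.
#' @param radius_mm Designed disk radius (defaults to the spec's).
#' @param ... Passed to [extract_esf()].
#' @return Fitted Lorentzian FWHM in mm.
#' @export
sharpness <- function(image, radius_mm = NULL, ...) {
  if (is.null(radius_mm))
    radius_mm <- image$spec$layout$radius_mm %||% 95
  fit_lorentzian(extract_esf(image, radius_mm = radius_mm, ...))$fwhm_mm
}

#' Difference-image SNR (NEMA two-acquisition method)
#'
#' `sqrt(2) * mean(image1 within the disk ROI) / sd(image1 - image2
#' within the ROI)` for two same-protocol acquisitions differing only in
#' their noise realization. The sqrt(2) accounts for the doubled noise
#' variance of the difference. Symmetric ROI: the detected disk of
#' `image1` eroded by 5 pixels.
#'
#' @param image1,image2 Two `phantom_image`s of the same spec.
#' @param ellipse Optional precomputed [detect_disk()] result for `image1`.
#' @return SNR estimate (dimensionless).
#' @export
snr_difference <- function(image1, image2, ellipse = NULL) {
  stopifnot(inherits(image1, "phantom_image"), inherits(image2, "phantom_image"))
  if (is.null(ellipse)) ellipse <- detect_disk(image1)
  roi <- eroded_roi(ellipse)
  dif <- image1$magnitude[roi] - image2$magnitude[roi]
  s <- stats::sd(dif)
  if (s == 0)
    abort_droiq("difference image has zero variance (identical inputs?)",
                "droiq_degenerate_input")
  sqrt(2) * mean(image1$magnitude[roi]) / s
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  cat(sprintf("<lorentzian_fit> FWHM %.4g mm at %.4g mm (A %.3g, B %.3g, resid %.3g)\n",
              x$fwhm_mm, x$center_mm, x$amplitude, x$offset, x$residual_norm))
  invisible(x)
}
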