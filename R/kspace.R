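#' Jinc function: radial Fourier transform of a uniform disk
#'
#' `jinc(kr, R) = 2 pi R^2 J1(2 pi R kr) / (2 pi R kr)`, where J1 is the
#' first-order Bessel function of the first kind. This is the 2-D Fourier
#' transform of a unit-intensity disk of radius `R`; its value at `kr = 0`
#' is the disk area `pi R^2` (the analytic limit `J1(z)/z -> 1/2`).
#'
#' @param kr Radial spatial frequency (cycles/mm), any non-negative numeric.
#' @param R Disk radius in mm, positive scalar.
#' @return Numeric of the same shape as `kr`.
#' @examples
#' jinc(0, 1)    # pi
#' jinc(0, 95)   # pi * 95^2
#' @export
jinc <- function(kr, R) {
  if (!is_scalar_number(R) || R <= 0)
    abort_droiq("R must be a positive scalar", "droiq_invalid_parameter")
  if (any(kr < 0)) abort_droiq("kr must be non-negative", "droiq_invalid_parameter")
  z <- 2 * pi * R * kr
  out <- rep(pi * R^2, length(z))
  nz <- z != 0
  out[nz] <- 2 * pi * R^2 * besselJ(z[nz], 1) / z[nz]
  dim(out) <- dim(kr)
  out
}

#' @noRd
new_kspace_data <- function(values, grid, is_noisy = FALSE, seed = NULL) {
  structure(list(values = values, grid = grid, is_noisy = is_noisy, seed = seed),
            class = "kspace_data")
}

#' Analytic k-space of a single disk
#'
#' Samples the continuous Fourier transform of a uniform disk of radius
#' `radius_mm`, intensity `intensity` and center `(xc_mm, yc_mm)` on the
#' grid: `jinc(kr | R) * I * exp(-2 pi i (xc kx + yc ky))`. Off-centering
#' is a pure phase shift, so the modulus is independent of the center.
#'
#' @param grid A [kspace_grid()].
#' @param disk A [disk_spec()].
#' @return A `kspace_data` object (complex N x N values, DC-centered).
#' @export
disk_kspace <- function(grid, disk) {
  stopifnot(inherits(grid, "kspace_grid"))
  disk <- as_disk_spec(disk)
  vals <- jinc(grid$kr, disk$radius_mm) * disk$intensity *
    exp(-2i * pi * (disk$xc_mm * grid$kx + disk$yc_mm * grid$ky))
  new_kspace_data(vals, grid)
}

#' Compound phantom k-space: superposition of disks
#'
#' The k-space of a compound phantom is the elementwise sum of the k-space
#' of its component disks (linearity of the Fourier transform).
#'
#' @param grid A [kspace_grid()].
#' @param disks Non-empty list of [disk_spec()] objects.
#' @return A `kspace_data` object.
#' @export
compound_kspace <- function(grid, disks) {
  stopifnot(inherits(grid, "kspace_grid"))
  if (!is.list(disks) || length(disks) == 0L)
    abort_droiq("disks must be a non-empty list of disk_spec", "droiq_invalid_parameter")
  n <- grid$matrix_size
  acc <- matrix(0 + 0i, n, n)
  for (d in disks) acc <- acc + disk_kspace(grid, d)$values
  new_kspace_data(acc, grid)
}

#' Add complex Gaussian acquisition noise to k-space
#'
#' Adds independent zero-mean complex Gaussian noise to every k-space
#' sample, calibrated so that each channel (real and imaginary) of the
#' reconstructed complex image has per-pixel standard deviation `sigma`.
#' With disk intensity I this realizes the designed SNR `I / sigma`
#' measurable by the NEMA difference method ([snr_difference()]). The
#' required k-space per-channel standard deviation is
#' `sigma * fov_mm^2 / N` under the `1/fov^2`-scaled unnormalized inverse
#' DFT used by [ifft_reconstruct()]. Noise is not Hermitian-symmetrized;
#' magnitude backgrounds are therefore Rician.
#'
#' @param kspace A `kspace_data` object.
#' @param sigma Image-domain per-channel noise standard deviation (>= 0).
#' @param seed Integer RNG seed; identical seed and input give identical
#'   output.
#' @return A new `kspace_data` with `is_noisy = TRUE` (unless `sigma = 0`,
#'   which returns the input values unchanged).
#' @export
add_complex_noise <- function(kspace, sigma, seed) {
  stopifnot(inherits(kspace, "kspace_data"))
  if (!is_scalar_number(sigma) || sigma < 0)
    abort_droiq("sigma must be a non-negative number", "droiq_invalid_parameter")
  if (sigma == 0) return(kspace)
  g <- kspace$grid
  n <- g$matrix_size
  sk <- sigma * g$fov_mm^2 / n
  set.seed(seed)
  noise <- matrix(stats::rnorm(n * n, sd = sk), n, n) +
    1i * matrix(stats::rnorm(n * n, sd = sk), n, n)
  new_kspace_data(kspace$values + noise, g, is_noisy = TRUE, seed = seed)
}

#' Reference reconstruction: inverse FFT of DC-centered k-space
#'
#' Applies the DC-shift convention, the unnormalized 2-D inverse FFT and
#' the fixed continuous-to-discrete amplitude scaling `dk^2 = 1/fov_mm^2`,
#' so a noiseless disk of intensity I reconstructs with interior intensity
#' I. Returns the complex image and its magnitude.
#'
#' @param kspace A `kspace_data` object (square, even-sized, DC-centered).
#' @param spec Optional generating [phantom_spec()] to attach to the image.
#' @return A `phantom_image`: list with `magnitude` (non-negative N x N),
#'   `complex_image`, `pixel_mm`, `grid` and `spec`.
#' @export
ifft_reconstruct <- function(kspace, spec = NULL) {
  stopifnot(inherits(kspace, "kspace_data"))
  v <- kspace$values
  if (is.null(dim(v)) || nrow(v) != ncol(v) || nrow(v) == 0)
    abort_droiq("k-space values must be a non-empty square matrix", "droiq_invalid_input")
  g <- kspace$grid
  cimg <- fftshift2(stats::fft(fftshift2(v), inverse = TRUE)) / g$fov_mm^2
  structure(
    list(magnitude = Mod(cimg), complex_image = cimg,
         pixel_mm = g$pixel_mm, grid = g, spec = spec),
    class = "phantom_image"
  )
}

#' Forward FFT of a reconstructed complex image
#'
#' Inverse of [ifft_reconstruct()]: returns DC-centered k-space samples
#' that round-trip to the input image at machine precision.
#'
#' @param image A `phantom_image` (its `complex_image` is transformed).
#' @return A `kspace_data` object.
#' @export
fft_forward <- function(image) {
  stopifnot(inherits(image, "phantom_image"))
  g <- image$grid
  vals <- fftshift2(stats::fft(fftshift2(image$complex_image))) *
    g$fov_mm^2 / g$matrix_size^2
  new_kspace_data(vals, g, is_noisy = FALSE)
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf("<kspace_data> %d x %d complex samples, %s\n",
              nrow(x$values), ncol(x$values),
              if (isTRUE(x$is_noisy)) sprintf("noisy (seed %s)", format(x$seed))
              else "noiseless"))
  invisible(x)
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("<phantom_image> %d x %d magnitude, pixel %g mm%s\n",
              nrow(x$magnitude), ncol(x$magnitude), x$pixel_mm,
              if (!is.null(x$spec)) sprintf(", kind '%s'", x$spec$kind) else ""))
  invisible(x)
}
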