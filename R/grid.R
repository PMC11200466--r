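#' DC-centered k-space sampling grid
#'
#' Builds the discrete spatial-frequency grid on which the analytic phantom
#' transforms are sampled. Samples are spaced `1/fov_mm` cycles/mm in each
#' axis (the Fourier conjugate of a field of view of `fov_mm`), with the DC
#' (zero-frequency) sample at matrix position `(N/2 + 1, N/2 + 1)`. Image
#' coordinates are pixel centers, `x = (col - 1 - N/2) * fov_mm / N`, so the
#' image origin coincides with the FOV center.
#'
#' @param fov_mm Field of view in mm (one side of the square FOV).
#' @param matrix_size Even integer N; the grid is N x N.
#' @return An object of class `kspace_grid`: a list with `fov_mm`,
#'   `matrix_size`, `pixel_mm`, the N x N frequency coordinate matrices
#'   `kx`, `ky` (cycles/mm; `kx` varies along columns) and the radial
#'   frequency `kr = sqrt(kx^2 + ky^2)`.
#' @examples
#' g <- kspace_grid(240, 128)
#' g$pixel_mm                      # 1.875
#' g$kx[65, 66] - g$kx[65, 65]     # 1/240
#' @export
kspace_grid <- function(fov_mm = 240, matrix_size = 128L) {
  if (!is_scalar_number(fov_mm) || fov_mm <= 0)
    abort_droiq("fov_mm must be a positive number", "droiq_invalid_parameter")
  if (!is_scalar_number(matrix_size) || matrix_size < 4 ||
      matrix_size != as.integer(matrix_size) || matrix_size %% 2L != 0L)
    abort_droiq("matrix_size must be an even integer >= 4", "droiq_invalid_parameter")
  n <- as.integer(matrix_size)
  kc <- (seq_len(n) - 1L - n / 2L) / fov_mm
  kx <- matrix(kc, n, n, byrow = TRUE)
  ky <- matrix(kc, n, n)
  structure(
    list(fov_mm = fov_mm, matrix_size = n, pixel_mm = fov_mm / n,
         kx = kx, ky = ky, kr = sqrt(kx^2 + ky^2)),
    class = "kspace_grid"
  )
}

#' Image-domain pixel-center coordinates of a grid
#'
#' @param grid A [kspace_grid()].
#' @return List with N x N matrices `x_mm`, `y_mm` (mm from FOV center;
#'   x along columns, y along rows) and `r_mm`, the distance to center.
#' @export
pixel_coords <- function(grid) {
  stopifnot(inherits(grid, "kspace_grid"))
  n <- grid$matrix_size
  c1 <- (seq_len(n) - 1L - n / 2L) * grid$pixel_mm
  x <- matrix(c1, n, n, byrow = TRUE)
  y <- matrix(c1, n, n)
  list(x_mm = x, y_mm = y, r_mm = sqrt(x^2 + y^2))
}

# mm offset from FOV center -> nearest 1-based pixel index along one axis
#' @noRd
mm_to_pixel <- function(grid, v_mm) {
  as.integer(round(v_mm / grid$pixel_mm) + grid$matrix_size / 2 + 1)
}

#' @export
print.kspace_grid <- function(x, ...) {
  cat(sprintf("<kspace_grid> %d x %d, FOV %g mm, pixel %g mm, dk %g cycles/mm\n",
              x$matrix_size, x$matrix_size, x$fov_mm, x$pixel_mm, 1 / x$fov_mm))
  invisible(x)
}
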