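#' Detect the phantom disk as an ellipse
#'
#' Region growing from the image-center seed: the foreground level is
#' estimated robustly as the median of a small central patch, the growth
#' threshold is half that level (the standard half-maximum edge
#' criterion), and the detected region is the connected component of the
#' thresholded image containing the seed. The equivalent ellipse is
#' estimated from the region's second central moments (sub-pixel,
#' deterministic): semi-axes are `2 * sqrt(eigenvalues)` of the coordinate
#' covariance, which recovers the radius exactly for a continuous uniform
#' disk.
#'
#' @param image A `phantom_image` containing one dominant bright disk at
#'   the FOV center.
#' @param patch_px Half-width of the central patch used for the robust
#'   foreground level (default 5, i.e. an 11 x 11 patch).
#' @return An object of class `detected_ellipse`: `center_px` (sub-pixel
#'   centroid, col/row), `center_mm`, `r_major_mm`, `r_minor_mm`, `mask`
#'   (logical matrix) and `threshold`.
#' @export
detect_disk <- function(image, patch_px = 5L) {
  stopifnot(inherits(image, "phantom_image"))
  mag <- image$magnitude
  n <- nrow(mag)
  ctr <- as.integer(n / 2 + 1)
  idx <- (ctr - patch_px):(ctr + patch_px)
  thr <- 0.5 * stats::median(mag[idx, idx])
  if (!(mag[ctr, ctr] >= thr) || thr <= 0)
    abort_droiq("no disk found at the image center (seed below threshold)",
                "droiq_detection_failure")
  bw <- mag >= thr
  lab <- EBImage::bwlabel(bw)
  mask <- lab == lab[ctr, ctr]
  px <- image$pixel_mm
  co <- pixel_coords(image$grid)
  xs <- co$x_mm[mask]; ys <- co$y_mm[mask]
  cx <- mean(xs); cy <- mean(ys)
  cov <- matrix(c(mean((xs - cx)^2), mean((xs - cx) * (ys - cy)),
                  mean((xs - cx) * (ys - cy)), mean((ys - cy)^2)), 2, 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  structure(
    list(center_mm = c(x = cx, y = cy),
         center_px = c(col = cx / px + n / 2 + 1, row = cy / px + n / 2 + 1),
         r_major_mm = 2 * sqrt(max(ev)), r_minor_mm = 2 * sqrt(min(ev)),
         mask = mask, threshold = thr),
    class = "detected_ellipse"
  )
}

#' Geometric accuracy: maximum percentage radius error
#'
#' `100 * max(|R_major - R_gt|, |R_minor - R_gt|) / R_gt` for a detected
#' ellipse against the designed ground-truth radius.
#'
#' @param ellipse A [detect_disk()] result.
#' @param r_ground_truth_mm Designed disk radius, mm (> 0).
#' @return Non-negative percentage.
#' @export
geometric_accuracy <- function(ellipse, r_ground_truth_mm) {
  stopifnot(inherits(ellipse, "detected_ellipse"))
  if (!is_scalar_number(r_ground_truth_mm) || r_ground_truth_mm <= 0)
    abort_droiq("ground-truth radius must be positive", "droiq_invalid_parameter")
  100 * max(abs(ellipse$r_major_mm - r_ground_truth_mm),
            abs(ellipse$r_minor_mm - r_ground_truth_mm)) / r_ground_truth_mm
}

# disk ROI shared by uniformity / ghosting / SNR: detected mask eroded by
# a disk-shaped structuring element of the given pixel radius
#' @noRd
eroded_roi <- function(ellipse, erosion_px = 5L) {
  er <- EBImage::erode(ellipse$mask + 0,
                       EBImage::makeBrush(2L * erosion_px + 1L, shape = "disc")) > 0
  if (!any(er))
    abort_droiq("eroded disk ROI is empty", "droiq_roi_too_small")
  er
}

#' Percent intensity uniformity (PIU)
#'
#' NEMA-style uniformity: the detected disk mask is eroded by
#' `erosion_px` pixels (disk-shaped element) to exclude edges, the image
#' is low-pass filtered with the uniform 3 x 3 kernel to suppress noise,
#' and `PIU = 100 * (1 - (Imax - Imin) / (Imax + Imin))` is computed from
#' the filtered extrema inside the eroded ROI. Always in [0, 100].
#'
#' @param image A `phantom_image`.
#' @param ellipse The [detect_disk()] result for that image.
#' @param erosion_px Erosion radius in pixels (default 5).
#' @return Percentage in [0, 100].
#' @export
intensity_uniformity <- function(image, ellipse, erosion_px = 5L) {
  stopifnot(inherits(image, "phantom_image"), inherits(ellipse, "detected_ellipse"))
  roi <- eroded_roi(ellipse, erosion_px)
  f <- EBImage::filter2(image$magnitude, matrix(1 / 9, 3, 3))
  imax <- max(f[roi]); imin <- min(f[roi])
  100 * (1 - (imax - imin) / (imax + imin))
}

#' Background rectangles and disk ROI for the ghosting ratio
#'
#' Four rectangles (long edge N/2, short edge N/16) centered 7N/16 pixels
#' from the designed disk center (the image center), top/bottom along the
#' vertical axis and left/right along the horizontal axis, plus the
#' eroded disk interior. ROIs are defined in the phantom's frame, not the
#' detected centroid, so the ghosting measurement is decoupled from the
#' geometry measurement.
#'
#' @param image A `phantom_image`.
#' @param ellipse The [detect_disk()] result (for the disk ROI).
#' @param erosion_px Erosion used for the disk ROI (default 5).
#' @return An object of class `ghosting_rois`: logical masks `top`,
#'   `bottom`, `left`, `right`, `disk_roi`.
#' @export
ghosting_rois <- function(image, ellipse, erosion_px = 5L) {
  stopifnot(inherits(image, "phantom_image"))
  n <- nrow(image$magnitude)
  if (n %% 16L != 0L)
    abort_droiq("ghosting ROI geometry requires matrix size divisible by 16",
                "droiq_invalid_roi")
  ctr <- n / 2L + 1L
  off <- 7L * n / 16L
  short <- n / 16L; long <- n / 2L
  span_short <- function(c0) (c0 - short / 2 + 1L):(c0 + short / 2)
  span_long <- (ctr - long / 2 + 1L):(ctr + long / 2)
  if (ctr - off - short / 2 + 1L < 1L || ctr + off + short / 2 > n)
    abort_droiq("ghosting ROIs fall outside the image", "droiq_invalid_roi")
  mk <- function(rows, cols) {
    m <- matrix(FALSE, n, n); m[rows, cols] <- TRUE; m
  }
  rois <- structure(
    list(top = mk(span_short(ctr - off), span_long),
         bottom = mk(span_short(ctr + off), span_long),
         left = mk(span_long, span_short(ctr - off)),
         right = mk(span_long, span_short(ctr + off)),
         disk_roi = eroded_roi(ellipse, erosion_px)),
    class = "ghosting_rois"
  )
  for (nm in c("top", "bottom", "left", "right"))
    if (any(rois[[nm]] & ellipse$mask))
      abort_droiq(sprintf("%s ghosting ROI intersects the detected disk", nm),
                  "droiq_invalid_roi")
  rois
}

#' Ghosting ratio
#'
#' `|(mean_top + mean_bottom) - (mean_left + mean_right)| / (2 * mean_disk)`:
#' the normalized asymmetry between the phase-encode-axis and
#' frequency-encode-axis background regions, sensitive to Cartesian
#' aliasing replicas. The absolute value follows the ACR formulation.
#'
#' @param image A `phantom_image`.
#' @param rois A [ghosting_rois()] object (built from the image if omitted,
#'   using `ellipse`).
#' @param ellipse A [detect_disk()] result; required when `rois` is NULL.
#' @return Non-negative ratio.
#' @export
ghosting_ratio <- function(image, rois = NULL, ellipse = NULL) {
  stopifnot(inherits(image, "phantom_image"))
  if (is.null(rois)) {
    if (is.null(ellipse)) ellipse <- detect_disk(image)
    rois <- ghosting_rois(image, ellipse)
  }
  mag <- image$magnitude
  m <- vapply(rois[c("top", "bottom", "left", "right", "disk_roi")],
              function(r) mean(mag[r]), numeric(1))
  if (m[["disk_roi"]] <= 0)
    abort_droiq("mean disk intensity must be positive", "droiq_invalid_roi")
  abs((m[["top"]] + m[["bottom"]]) - (m[["left"]] + m[["right"]])) /
    (2 * m[["disk_roi"]])
}

#' @export
print.detected_ellipse <- function(x, ...) {
  cat(sprintf("<detected_ellipse> center (%.2f, %.2f) mm, semi-axes %.2f / %.2f mm, %d px\n",
              x$center_mm[["x"]], x$center_mm[["y"]],
              x$r_major_mm, x$r_minor_mm, sum(x$mask)))
  invisible(x)
}
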