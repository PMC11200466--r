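#' Otsu threshold of a 1-D intensity sample
#'
#' Histogram threshold maximizing between-class variance, computed on the
#' sample's own range (so any decision based on it is invariant under
#' affine intensity scaling).
#'
#' @param v Numeric vector.
#' @param levels Histogram resolution (default 256).
#' @return Threshold on the scale of `v`.
#' @export
otsu_threshold <- function(v, levels = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(levels, 1L + floor((v - rng[1]) / diff(rng) * levels)), levels)
  p <- h / sum(h)
  om <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mt <- mu[levels]
  sb <- (mt * om - mu)^2 / (om * (1 - om))
  sb[!is.finite(sb)] <- 0
  # the between-class variance is flat across empty gaps; take the middle
  # of the maximizing plateau (standard tie handling)
  k <- mean(which(sb == max(sb)))
  rng[1] + (k / levels) * diff(rng)
}

#' Count resolvable peaks along a row profile
#'
#' Local maxima (strictly greater than both neighbours) whose height
#' exceeds the Otsu threshold of the profile's intensity distribution,
#' pruned greedily (highest first) so surviving peaks are at least two
#' disk radii apart.
#'
#' @param profile 1-D intensity samples along a disk row.
#' @param radius_mm Disk radius of that row, mm.
#' @param pixel_mm Sample spacing of the profile, mm.
#' @return Integer peak count.
#' @export
detect_row_peaks <- function(profile, radius_mm, pixel_mm) {
  n <- length(profile)
  if (n < 3L)
    abort_droiq("profile must have at least 3 samples", "droiq_invalid_input")
  th <- otsu_threshold(profile)
  loc <- which(profile[2:(n - 1)] > profile[1:(n - 2)] &
               profile[2:(n - 1)] > profile[3:n]) + 1L
  loc <- loc[profile[loc] > th]
  if (length(loc) == 0L) return(0L)
  ord <- loc[order(-profile[loc])]
  keep <- integer(0)
  for (p in ord)
    if (length(keep) == 0L || all(abs(keep - p) * pixel_mm >= 2 * radius_mm))
      keep <- c(keep, p)
  length(keep)
}

#' High-contrast resolution score of a resolution phantom image
#'
#' For each designed radius and direction, extracts the intensity profile
#' along each row line (the pixel row/column through the designed disk
#' centers, with a small margin beyond the outer disks) and counts peaks
#' with [detect_row_peaks()]. A resolution `2 r` is achieved in a
#' direction if at least one of the 4 rows of the corresponding block
#' yields 4 distinct peaks. Reports the smallest achieved resolution per
#' direction (or `NA` = not resolved).
#'
#' @param image A `phantom_image`.
#' @param spec The generating `phantom_spec` of kind `"resolution"`
#'   (defaults to the spec attached to the image).
#' @param margin_mm Profile margin beyond the outermost disk centers
#'   (default 6 mm).
#' @return An object of class `resolution_result`: `achieved_mm_x`,
#'   `achieved_mm_y` (smallest resolved `2 r`, `NA` if none) and
#'   `per_row_peaks`, a data.frame of peak counts per row.
#' @export
resolution_score <- function(image, spec = NULL, margin_mm = 6) {
  stopifnot(inherits(image, "phantom_image"))
  spec <- spec %||% image$spec
  if (is.null(spec) || spec$kind != "resolution")
    abort_droiq("resolution_score needs a resolution phantom spec",
                "droiq_invalid_phantom")
  g <- spec$grid
  mag <- image$magnitude
  rows_out <- list()
  achieved <- list(h = NA_real_, v = NA_real_)
  for (b in spec$layout$blocks) {
    r <- b$radius_mm
    counts <- integer(4)
    for (j in seq_along(b$rows)) {
      rw <- b$rows[[j]]
      if (b$direction == "h") {
        rowpix <- mm_to_pixel(g, rw$y_mm[1])
        cols <- mm_to_pixel(g, min(rw$x_mm) - margin_mm):mm_to_pixel(g, max(rw$x_mm) + margin_mm)
        prof <- mag[rowpix, cols]
      } else {
        colpix <- mm_to_pixel(g, rw$x_mm[1])
        rws <- mm_to_pixel(g, min(rw$y_mm) - margin_mm):mm_to_pixel(g, max(rw$y_mm) + margin_mm)
        prof <- mag[rws, colpix]
      }
      counts[j] <- detect_row_peaks(prof, r, g$pixel_mm)
    }
    rows_out[[length(rows_out) + 1L]] <-
      data.frame(radius_mm = r, direction = b$direction,
                 row = seq_along(counts), peaks = counts)
    if (any(counts >= 4L)) {
      cur <- achieved[[b$direction]]
      if (is.na(cur) || 2 * r < cur) achieved[[b$direction]] <- 2 * r
    }
  }
  structure(list(achieved_mm_x = achieved$h, achieved_mm_y = achieved$v,
                 per_row_peaks = do.call(rbind, rows_out)),
            class = "resolution_result")
}

#' Noiseless detection template for a low-contrast disk
#'
#' The template is the noiseless magnitude rendering, through the same
#' k-space pipeline (analytic transform, sampling, inverse FFT), of a
#' disk of the given radius with bump intensity
#' `contrast * background_intensity`, centered on the background disk,
#' cropped to `template_px` pixels. A 7-pixel template inside the
#' 10-pixel patch leaves a 4 x 4 grid of fully-contained correlation
#' positions, covering the sub-pixel placement error of patches cropped
#' at rounded designed centers.
#'
#' @param disk_radius_mm Small-disk radius, mm.
#' @param contrast Bump-to-background intensity ratio.
#' @param template_px Template side length in pixels (default 7).
#' @param grid A [kspace_grid()].
#' @param background_radius_mm,background_intensity Background disk the
#'   template disk sits on (defaults match [build_lowcontrast_phantom()]).
#' @return `template_px` x `template_px` numeric matrix.
#' @export
make_template <- function(disk_radius_mm, contrast = 0.2, template_px = 7L,
                          grid = kspace_grid(),
                          background_radius_mm = 65,
                          background_intensity = 0.5) {
  ks <- compound_kspace(grid, list(
    disk_spec(background_radius_mm, background_intensity),
    disk_spec(disk_radius_mm, contrast * background_intensity)))
  img <- ifft_reconstruct(ks)
  crop_patch(img$magnitude, grid$matrix_size / 2 + 1, grid$matrix_size / 2 + 1,
             template_px)
}

# crop a side x side patch centered at (row, col); even sides take one
# extra pixel below/right of center
#' @noRd
crop_patch <- function(mag, row, col, side) {
  lo <- (side - 1L) %/% 2L
  hi <- side - 1L - lo
  rows <- (row - lo):(row + hi)
  cols <- (col - lo):(col + hi)
  if (min(rows) < 1L || min(cols) < 1L || max(rows) > nrow(mag) || max(cols) > ncol(mag))
    abort_droiq("patch falls outside the image", "droiq_invalid_input")
  mag[rows, cols]
}

#' Sliding-window normalized correlation of a template over a patch
#'
#' Pearson correlation (zero-mean, unit-variance over the window) of the
#' template against the patch at every shift. When the template is
#' smaller than the patch, shifts are all fully-contained placements
#' (the standard template-matching correlation map); when both are the
#' same size, the template is shifted by up to `shift_range` pixels in
#' each axis and correlated over the overlapping region.
#'
#' @param patch Numeric matrix (the cropped image patch).
#' @param template Numeric matrix, sides not larger than the patch.
#' @param shift_range Maximum |shift| per axis for equal-size inputs
#'   (default 3).
#' @return List with `map` (correlation at each shift), `max`, and
#'   `degenerate` (TRUE when every window had zero variance; `max` is 0).
#' @export
sliding_correlation <- function(patch, template, shift_range = 3L) {
  if (nrow(template) > nrow(patch) || ncol(template) > ncol(patch))
    abort_droiq("template must not be larger than the patch", "droiq_invalid_input")
  tp <- nrow(template); pp <- nrow(patch)
  tv <- as.vector(template)
  if (tp < pp) {
    npos <- pp - tp + 1L
    map <- matrix(NA_real_, npos, npos)
    for (i in seq_len(npos)) for (j in seq_len(npos)) {
      a <- as.vector(patch[i:(i + tp - 1L), j:(j + tp - 1L)])
      if (stats::sd(a) == 0 || stats::sd(tv) == 0) next
      map[i, j] <- stats::cor(a, tv)
    }
  } else {
    shifts <- -shift_range:shift_range
    map <- matrix(NA_real_, length(shifts), length(shifts),
                  dimnames = list(shifts, shifts))
    for (di in seq_along(shifts)) for (dj in seq_along(shifts)) {
      dy <- shifts[di]; dx <- shifts[dj]
      tr <- max(1L, 1L + dy):min(tp, tp + dy)
      tc <- max(1L, 1L + dx):min(tp, tp + dx)
      a <- as.vector(patch[tr - dy, tc - dx])
      b <- as.vector(template[tr, tc])
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      map[di, dj] <- stats::cor(a, b)
    }
  }
  if (all(is.na(map)))
    return(list(map = map, max = 0, degenerate = TRUE))
  list(map = map, max = max(map, na.rm = TRUE), degenerate = FALSE)
}

#' Calibrate the detection threshold for one disk size
#'
#' Simulates `n_per_class` disk-present and `n_per_class` disk-absent
#' 10 x 10-pixel patches through the full k-space pipeline with matched
#' matrix size, noise level and contrast (present patches get a uniform
#' sub-pixel center offset, mirroring patches cropped at rounded designed
#' centers in the phantom), records each patch's maximum sliding
#' correlation against the noiseless template, and sweeps the threshold
#' over midpoints of consecutive sorted scores. Returns the
#' accuracy-maximizing threshold (ties broken toward the higher
#' candidate, the operating point with fewer false positives), the best
#' accuracy, and whether it reaches the 0.70 reliability floor. Disks
#' whose calibration is unreliable are deemed undetectable without
#' testing.
#'
#' @param disk_radius_mm Disk radius, mm.
#' @param sigma Noise level (image-domain per-channel std).
#' @param contrast Bump-to-background intensity ratio.
#' @param n_per_class Patches per class (default 100).
#' @param seed RNG master seed for the calibration draws.
#' @param grid A [kspace_grid()].
#' @param patch_px Patch side (default 10).
#' @param template_px Template side (default 7).
#' @param background_radius_mm,background_intensity Background disk.
#' @param accuracy_floor Reliability floor (default 0.70).
#' @return An object of class `detection_threshold`: `disk_radius_mm`,
#'   `sigma`, `contrast`, `threshold`, `calibration_accuracy`, `reliable`,
#'   `scores`, `labels`.
#' @export
calibrate_threshold <- function(disk_radius_mm, sigma, contrast = 0.2,
                                n_per_class = 100L, seed = 1L,
                                grid = kspace_grid(), patch_px = 10L,
                                template_px = 7L,
                                background_radius_mm = 65,
                                background_intensity = 0.5,
                                accuracy_floor = 0.70) {
  if (!is_scalar_number(n_per_class) || n_per_class < 2)
    abort_droiq("n_per_class must be >= 2", "droiq_invalid_parameter")
  n_per_class <- as.integer(n_per_class)
  templ <- make_template(disk_radius_mm, contrast, template_px, grid,
                         background_radius_mm, background_intensity)
  n <- grid$matrix_size
  ctr <- n / 2L + 1L
  px <- grid$pixel_mm
  ks_bg <- disk_kspace(grid, disk_spec(background_radius_mm, background_intensity))
  bump <- contrast * background_intensity
  scores <- numeric(2L * n_per_class)
  labels <- rep(c(1L, 0L), n_per_class)
  for (i in seq_len(n_per_class)) {
    set.seed(derive_seed(seed, 2L, i))
    off <- stats::runif(2, -px / 2, px / 2)
    ks_p <- new_kspace_data(
      ks_bg$values + disk_kspace(grid, disk_spec(disk_radius_mm, bump,
                                                 off[1], off[2]))$values, grid)
    imp <- ifft_reconstruct(add_complex_noise(ks_p, sigma,
                                              seed = derive_seed(seed, 3L, i)))
    ima <- ifft_reconstruct(add_complex_noise(ks_bg, sigma,
                                              seed = derive_seed(seed, 4L, i)))
    scores[2L * i - 1L] <-
      sliding_correlation(crop_patch(imp$magnitude, ctr, ctr, patch_px), templ)$max
    scores[2L * i] <-
      sliding_correlation(crop_patch(ima$magnitude, ctr, ctr, patch_px), templ)$max
  }
  ss <- sort(unique(scores))
  cand <- if (length(ss) > 1L) (utils::head(ss, -1) + utils::tail(ss, -1)) / 2
          else ss
  acc <- vapply(cand, function(th) mean((scores > th) == labels), numeric(1))
  best <- max(acc)
  structure(
    list(disk_radius_mm = disk_radius_mm, sigma = sigma, contrast = contrast,
         threshold = max(cand[acc == best]),
         calibration_accuracy = best,
         reliable = best >= accuracy_floor,
         scores = scores, labels = labels),
    class = "detection_threshold"
  )
}

#' Calibrate thresholds for every spoke of a low-contrast phantom
#'
#' @param spec A `phantom_spec` of kind `"low_contrast"`.
#' @param n_per_class,seed,template_px See [calibrate_threshold()].
#' @return Named list of `detection_threshold`, one per spoke radius.
#' @export
calibrate_spoke_thresholds <- function(spec, n_per_class = 100L, seed = 1L,
                                       template_px = 7L) {
  stopifnot(inherits(spec, "phantom_spec"), spec$kind == "low_contrast")
  lay <- spec$layout
  out <- lapply(seq_along(lay$spoke_radii_mm), function(s)
    calibrate_threshold(lay$spoke_radii_mm[s], spec$noise_sigma, lay$contrast,
                        n_per_class = n_per_class,
                        seed = derive_seed(seed, 5L, s),
                        grid = spec$grid, template_px = template_px,
                        background_radius_mm = lay$background_radius_mm,
                        background_intensity = lay$background_intensity))
  names(out) <- sprintf("spoke%02d", seq_along(out))
  out
}

#' Count visible spokes of a low-contrast phantom image
#'
#' Each small disk is tested by cropping the 10 x 10 patch at its rounded
#' designed center and comparing the maximum sliding correlation against
#' its spoke's calibrated threshold. A spoke is visible when all of its
#' disks are detected; spokes with an unreliable calibration
#' (accuracy < 0.70) are deemed undetectable without testing.
#'
#' @param image A `phantom_image`.
#' @param spec The generating low-contrast `phantom_spec` (defaults to the
#'   one attached to the image).
#' @param thresholds Per-spoke list from [calibrate_spoke_thresholds()].
#' @param patch_px,template_px Patch/template sides (default 10 / 7).
#' @param templates Optional precomputed per-spoke template list (as built
#'   internally via [make_template()]); supply in batch loops to avoid
#'   re-rendering.
#' @return An object of class `spoke_count`: `n_visible`, plus a
#'   data.frame `spokes` with per-spoke detail.
#' @export
count_visible_spokes <- function(image, spec = NULL, thresholds,
                                 patch_px = 10L, template_px = 7L,
                                 templates = NULL) {
  stopifnot(inherits(image, "phantom_image"))
  spec <- spec %||% image$spec
  if (is.null(spec) || spec$kind != "low_contrast")
    abort_droiq("count_visible_spokes needs a low-contrast phantom spec",
                "droiq_invalid_phantom")
  lay <- spec$layout
  if (length(thresholds) != lay$n_spokes)
    abort_droiq("need one calibrated threshold per spoke", "droiq_configuration_error")
  g <- spec$grid
  if (is.null(templates))
    templates <- lapply(lay$spoke_radii_mm, function(r)
      make_template(r, lay$contrast, template_px, g,
                    lay$background_radius_mm, lay$background_intensity))
  res <- lapply(seq_len(lay$n_spokes), function(s) {
    th <- thresholds[[s]]
    rows <- which(lay$centers$spoke == s)
    if (!isTRUE(th$reliable))
      return(data.frame(spoke = s, radius_mm = lay$spoke_radii_mm[s],
                        reliable = FALSE, n_detected = 0L, visible = FALSE))
    det <- vapply(rows, function(i) {
      p <- crop_patch(image$magnitude,
                      mm_to_pixel(g, lay$centers$y_mm[i]),
                      mm_to_pixel(g, lay$centers$x_mm[i]), patch_px)
      sliding_correlation(p, templates[[s]])$max > th$threshold
    }, logical(1))
    data.frame(spoke = s, radius_mm = lay$spoke_radii_mm[s], reliable = TRUE,
               n_detected = sum(det), visible = all(det))
  })
  spokes <- do.call(rbind, res)
  structure(list(n_visible = sum(spokes$visible), spokes = spokes),
            class = "spoke_count")
}

#' @export
print.resolution_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "not resolved" else sprintf("%.1f mm", v)
  cat(sprintf("<resolution_result> achieved: x %s, y %s\n",
              fmt(x$achieved_mm_x), fmt(x$achieved_mm_y)))
  invisible(x)
}

#' @export
print.detection_threshold <- function(x, ...) {
  cat(sprintf(
    "<detection_threshold> r %.2f mm, sigma %g: threshold %.3f, accuracy %.2f (%s)\n",
    x$disk_radius_mm, x$sigma, x$threshold, x$calibration_accuracy,
    if (x$reliable) "reliable" else "unreliable"))
  invisible(x)
}

#' @export
print.spoke_count <- function(x, ...) {
  cat(sprintf("<spoke_count> %d of %d spokes visible\n",
              x$n_visible, nrow(x$spokes)))
  invisible(x)
}
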