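#' Specification of a single analytic disk
#'
#' A disk is the phantom primitive: radius and center in physical units
#' (mm from FOV center), intensity dimensionless.
#'
#' @param radius_mm Disk radius (> 0), mm.
#' @param intensity Signal level of the disk (may be negative: a negative
#'   disk superimposed on a positive one carves a darker region).
#' @param xc_mm,yc_mm Center offsets from the FOV center, mm.
#' @return An object of class `disk_spec`.
#' @export
disk_spec <- function(radius_mm, intensity, xc_mm = 0, yc_mm = 0) {
  if (!is_scalar_number(radius_mm) || radius_mm <= 0)
    abort_droiq("radius_mm must be a positive number", "droiq_invalid_parameter")
  if (!is_scalar_number(intensity))
    abort_droiq("intensity must be a finite number", "droiq_invalid_parameter")
  if (!is_scalar_number(xc_mm) || !is_scalar_number(yc_mm))
    abort_droiq("center coordinates must be finite numbers", "droiq_invalid_parameter")
  structure(list(radius_mm = radius_mm, intensity = intensity,
                 xc_mm = xc_mm, yc_mm = yc_mm),
            class = "disk_spec")
}

#' @noRd
as_disk_spec <- function(x) {
  if (inherits(x, "disk_spec")) return(x)
  if (is.list(x) && all(c("radius_mm", "intensity") %in% names(x)))
    return(disk_spec(x$radius_mm, x$intensity, x$xc_mm %||% 0, x$yc_mm %||% 0))
  abort_droiq("not a disk_spec", "droiq_invalid_parameter")
}

#' @noRd
check_contained <- function(disk, fov_mm) {
  if (abs(disk$xc_mm) + disk$radius_mm > fov_mm / 2 ||
      abs(disk$yc_mm) + disk$radius_mm > fov_mm / 2)
    abort_droiq(sprintf(
      "disk (R = %g mm at %g, %g) is not contained in the %g mm FOV",
      disk$radius_mm, disk$xc_mm, disk$yc_mm, fov_mm), "droiq_containment_error")
  invisible(TRUE)
}

#' @noRd
new_phantom_spec <- function(kind, disks, grid, noise_sigma, seed, layout) {
  if (!is_scalar_number(noise_sigma) || noise_sigma < 0)
    abort_droiq("noise_sigma must be >= 0", "droiq_invalid_parameter")
  structure(list(kind = kind, disks = disks, grid = grid,
                 noise_sigma = noise_sigma, seed = seed, layout = layout),
            class = "phantom_spec")
}

#' Simple disk phantom
#'
#' One large centered disk: the test object for geometric accuracy,
#' intensity uniformity, ghosting ratio, sharpness and SNR. Defaults are
#' the standard study conditions: FOV 240 mm, matrix 128, radius 95 mm,
#' intensity 0.5 (so noise sigma 0.04 / 0.02 give designed SNR 12.5 / 25).
#'
#' @param fov_mm,matrix_size Grid parameters (see [kspace_grid()]).
#' @param radius_mm Disk radius, mm.
#' @param intensity Disk intensity.
#' @param sigma Image-domain per-channel noise standard deviation.
#' @param seed Master RNG seed for noise realizations.
#' @return A `phantom_spec` of kind `"disk"`.
#' @export
build_disk_phantom <- function(fov_mm = 240, matrix_size = 128L, radius_mm = 95,
                               intensity = 0.5, sigma = 0.04, seed = 1L) {
  grid <- kspace_grid(fov_mm, matrix_size)
  d <- disk_spec(radius_mm, intensity)
  check_contained(d, fov_mm)
  new_phantom_spec("disk", list(d), grid, sigma, seed,
                   layout = list(radius_mm = radius_mm, intensity = intensity))
}

#' High-contrast resolution phantom
#'
#' For each radius r and each direction, a block of 4 rows x 4 identical
#' disks. In-row center-to-center spacing is `4 r` (two diameters, so the
#' edge-to-edge gap equals the disk diameter `2 r`, the resolution under
#' test) and successive rows are shifted laterally by `r / 2` so that at
#' least one row lands favourably on the pixel grid (partial-volume
#' sampling). Horizontal blocks probe x-resolution, vertical blocks are
#' the 90-degree-rotated layout probing y-resolution. Blocks are tiled on
#' two FOV rows with > 10 mm margins.
#'
#' @inheritParams build_disk_phantom
#' @param radii_mm Disk radii, mm; resolutions under test are `2 * radii_mm`.
#' @param intensity Disk intensity.
#' @return A `phantom_spec` of kind `"resolution"`; `layout$blocks` maps
#'   each (radius, direction) to its 4 rows of 4 disk centers.
#' @export
build_resolution_phantom <- function(fov_mm = 240, matrix_size = 128L,
                                     radii_mm = c(0.8, 0.9, 1.0, 1.1),
                                     intensity = 0.5, sigma = 0.04, seed = 1L) {
  grid <- kspace_grid(fov_mm, matrix_size)
  if (length(radii_mm) < 1 || any(radii_mm <= 0))
    abort_droiq("radii_mm must be positive", "droiq_invalid_parameter")
  n_r <- length(radii_mm)
  # block centers: one FOV row per direction, columns spread by radius index
  bx <- (seq_len(n_r) - (n_r + 1) / 2) * (2 * fov_mm / (2 * n_r + 1))
  by <- c(h = fov_mm / 6, v = -fov_mm / 6)
  disks <- list()
  blocks <- list()
  for (ri in seq_len(n_r)) {
    r <- radii_mm[ri]
    for (dir in c("h", "v")) {
      x0 <- bx[ri]; y0 <- by[[dir]]
      rows <- vector("list", 4L)
      for (j in 0:3) {
        # 4 disks spaced two diameters apart; row j shifted by j * r/2
        # (block centered so the mean shift cancels)
        along <- (0:3) * 4 * r - 6 * r + (j - 1.5) * r / 2
        if (dir == "h") { xs <- x0 + along; ys <- rep(y0 + (j - 1.5) * 4 * r, 4) }
        else            { ys <- y0 + along; xs <- rep(x0 + (j - 1.5) * 4 * r, 4) }
        for (q in 1:4) {
          d <- disk_spec(r, intensity, xs[q], ys[q])
          check_contained(d, fov_mm)
          disks[[length(disks) + 1L]] <- d
        }
        rows[[j + 1L]] <- list(x_mm = xs, y_mm = ys)
      }
      blocks[[paste0("r", format(r), "_", dir)]] <-
        list(radius_mm = r, direction = dir, rows = rows)
    }
  }
  check_blocks_disjoint(blocks)
  new_phantom_spec("resolution", disks, grid, sigma, seed,
                   layout = list(radii_mm = radii_mm, intensity = intensity,
                                 blocks = blocks))
}

# blocks must not overlap: compare bounding boxes (disk extents included)
#' @noRd
check_blocks_disjoint <- function(blocks) {
  bb <- lapply(blocks, function(b) {
    xs <- unlist(lapply(b$rows, `[[`, "x_mm"))
    ys <- unlist(lapply(b$rows, `[[`, "y_mm"))
    c(min(xs) - b$radius_mm, max(xs) + b$radius_mm,
      min(ys) - b$radius_mm, max(ys) + b$radius_mm)
  })
  nb <- length(bb)
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    a <- bb[[i]]; b <- bb[[j]]
    if (a[1] < b[2] && b[1] < a[2] && a[3] < b[4] && b[3] < a[4])
      abort_droiq(sprintf("resolution blocks %s and %s overlap",
                          names(bb)[i], names(bb)[j]), "droiq_layout_error")
  }
  invisible(TRUE)
}

#' Low-contrast detectability phantom
#'
#' An ACR-like arrangement: one large background disk plus
#' `n_spokes x disks_per_spoke` small disks on radial spokes. All disks
#' on a spoke share one radius; radii are evenly spaced across spokes.
#' Small disks are superimposed with added intensity
#' `contrast * background_intensity` (brighter than background). The
#' default geometry (spokes every 36 degrees, disks at 21/34/47 mm,
#' background radius 65 mm) keeps every neighbouring disk and the
#' background edge outside the 10 x 10-pixel detection patch of any disk
#' at the default 1.875 mm resolution.
#'
#' @inheritParams build_disk_phantom
#' @param n_spokes Number of spokes.
#' @param disks_per_spoke Disks per spoke.
#' @param radii_range_mm Range of per-spoke disk radii (evenly spaced).
#' @param contrast Intensity ratio of the small-disk bump to background.
#' @param ring_mm Radial center distances of the disks on each spoke, mm
#'   (length `disks_per_spoke`).
#' @param background_radius_mm,background_intensity Background disk.
#' @return A `phantom_spec` of kind `"low_contrast"`; `layout$centers` is
#'   a data.frame of all small-disk positions.
#' @export
build_lowcontrast_phantom <- function(fov_mm = 240, matrix_size = 128L,
                                      n_spokes = 10L, disks_per_spoke = 3L,
                                      radii_range_mm = c(0.75, 3.5),
                                      contrast = 0.2,
                                      ring_mm = c(21, 34, 47),
                                      background_radius_mm = 65,
                                      background_intensity = 0.5,
                                      sigma = 0.04, seed = 1L) {
  grid <- kspace_grid(fov_mm, matrix_size)
  if (length(ring_mm) != disks_per_spoke)
    abort_droiq("ring_mm must have one entry per disk on a spoke",
                "droiq_invalid_parameter")
  bg <- disk_spec(background_radius_mm, background_intensity)
  check_contained(bg, fov_mm)
  spoke_radii <- seq(radii_range_mm[1], radii_range_mm[2], length.out = n_spokes)
  bump <- contrast * background_intensity
  disks <- list(bg)
  centers <- do.call(rbind, lapply(seq_len(n_spokes), function(s) {
    a <- 2 * pi * (s - 1) / n_spokes
    data.frame(spoke = s, disk = seq_len(disks_per_spoke),
               radius_mm = spoke_radii[s],
               x_mm = ring_mm * cos(a), y_mm = ring_mm * sin(a))
  }))
  for (i in seq_len(nrow(centers))) {
    d <- disk_spec(centers$radius_mm[i], bump, centers$x_mm[i], centers$y_mm[i])
    if (sqrt(d$xc_mm^2 + d$yc_mm^2) + d$radius_mm > background_radius_mm)
      abort_droiq("small disk extends beyond the background disk",
                  "droiq_layout_error")
    disks[[length(disks) + 1L]] <- d
  }
  new_phantom_spec("low_contrast", disks, grid, sigma, seed,
                   layout = list(n_spokes = n_spokes,
                                 disks_per_spoke = disks_per_spoke,
                                 spoke_radii_mm = spoke_radii,
                                 ring_mm = ring_mm, contrast = contrast,
                                 background_radius_mm = background_radius_mm,
                                 background_intensity = background_intensity,
                                 centers = centers))
}

#' Noiseless k-space of a phantom
#'
#' @param spec A `phantom_spec`.
#' @return A `kspace_data` object (the compound transform of all disks).
#' @export
phantom_kspace <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  compound_kspace(spec$grid, spec$disks)
}

#' Simulate one reconstructed phantom realization
#'
#' Samples the analytic k-space, adds one realization of complex Gaussian
#' noise (substream derived deterministically from the spec's master seed
#' and the realization index) and reconstructs by inverse FFT. With
#' `sigma = 0` the image is the noiseless reference.
#'
#' @param spec A `phantom_spec`.
#' @param realization Realization index (1-based); realization k is
#'   reproducible in isolation.
#' @param kspace0 Optional precomputed noiseless k-space (a `kspace_data`)
#'   to avoid recomputing the analytic transform in batch loops.
#' @return A `phantom_image` with the generating spec attached.
#' @export
simulate_phantom <- function(spec, realization = 1L, kspace0 = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  ks <- kspace0 %||% phantom_kspace(spec)
  if (spec$noise_sigma > 0)
    ks <- add_complex_noise(ks, spec$noise_sigma,
                            seed = derive_seed(spec$seed, 1L, realization))
  ifft_reconstruct(ks, spec = spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> kind '%s', %d disk(s), FOV %g mm, N %d, sigma %g, seed %s\n",
              x$kind, length(x$disks), x$grid$fov_mm, x$grid$matrix_size,
              x$noise_sigma, format(x$seed)))
  invisible(x)
}
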