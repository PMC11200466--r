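#' Serialize a phantom spec to JSON
#'
#' Round-trippable with [phantom_spec_from_json()]: the JSON carries the
#' kind, grid parameters, noise level, seed and the kind-specific layout
#' parameters; disks are re-derived by the builder on read.
#'
#' @param spec A `phantom_spec`.
#' @param path Optional file path; when NULL the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
phantom_spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  lay <- spec$layout
  payload <- list(kind = spec$kind, fov_mm = spec$grid$fov_mm,
                  matrix_size = spec$grid$matrix_size,
                  noise_sigma = spec$noise_sigma, seed = spec$seed)
  payload$layout <- switch(spec$kind,
    disk = lay[c("radius_mm", "intensity")],
    resolution = lay[c("radii_mm", "intensity")],
    low_contrast = lay[c("n_spokes", "disks_per_spoke", "contrast", "ring_mm",
                         "background_radius_mm", "background_intensity")])
  if (spec$kind == "low_contrast")
    payload$layout$radii_range_mm <- range(lay$spoke_radii_mm)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Rebuild a phantom spec from its JSON serialization
#'
#' @param json A file path or JSON string from [phantom_spec_to_json()].
#' @return A `phantom_spec`.
#' @export
phantom_spec_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  lay <- p$layout
  switch(p$kind,
    disk = build_disk_phantom(p$fov_mm, p$matrix_size, lay$radius_mm,
                              lay$intensity, p$noise_sigma, p$seed),
    resolution = build_resolution_phantom(p$fov_mm, p$matrix_size, lay$radii_mm,
                                          lay$intensity, p$noise_sigma, p$seed),
    low_contrast = build_lowcontrast_phantom(
      p$fov_mm, p$matrix_size, lay$n_spokes, lay$disks_per_spoke,
      lay$radii_range_mm, lay$contrast, lay$ring_mm,
      lay$background_radius_mm, lay$background_intensity,
      p$noise_sigma, p$seed),
    abort_droiq(sprintf("unknown phantom kind '%s'", p$kind),
                "droiq_invalid_parameter"))
}

#' Export a magnitude image as NIfTI
#'
#' Writes the magnitude with the pixel spacing in the header. Requires
#' the RNifti package.
#'
#' @param image A `phantom_image`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_phantom_nifti <- function(image, path) {
  stopifnot(inherits(image, "phantom_image"))
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort_droiq("RNifti is required for NIfTI export", "droiq_missing_package")
  arr <- array(image$magnitude, dim = c(dim(image$magnitude), 1L))
  nif <- RNifti::asNifti(arr, pixdim = c(image$pixel_mm, image$pixel_mm, 1))
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Export a magnitude image as a quick-look PNG
#'
#' Linearly rescales the magnitude to [0, 1]. Requires the png package.
#'
#' @param image A `phantom_image`.
#' @param path Output path.
#' @param max_value White level; defaults to the image maximum.
#' @return `path`, invisibly.
#' @export
write_phantom_png <- function(image, path, max_value = NULL) {
  stopifnot(inherits(image, "phantom_image"))
  if (!requireNamespace("png", quietly = TRUE))
    abort_droiq("png is required for PNG export", "droiq_missing_package")
  m <- image$magnitude
  mx <- max_value %||% max(m)
  if (mx <= 0) mx <- 1
  png::writePNG(pmin(pmax(m / mx, 0), 1), path)
  invisible(path)
}

#' Write a metric report to CSV / JSON
#'
#' `rows.csv` and `summary.csv` plus `metadata.json` under `dir`.
#'
#' @param report A `metric_report`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"`, `"json"` or both.
#' @return `dir`, invisibly.
#' @export
write_metric_report <- function(report, dir, format = c("csv", "json")) {
  stopifnot(inherits(report, "metric_report"))
  format <- match.arg(format, c("csv", "json"), several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if ("csv" %in% format) {
    utils::write.csv(report$rows, file.path(dir, "rows.csv"), row.names = FALSE)
    utils::write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  }
  if ("json" %in% format) {
    jsonlite::write_json(list(rows = report$rows, summary = report$summary),
                         file.path(dir, "report.json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  jsonlite::write_json(report$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a metric report written by [write_metric_report()]
#'
#' @param dir Report directory.
#' @return A `metric_report` (rows, summary, metadata).
#' @export
read_metric_report <- function(dir) {
  rows_path <- file.path(dir, "rows.csv")
  if (!file.exists(rows_path))
    abort_droiq(sprintf("no rows.csv under %s", dir), "droiq_invalid_input")
  rows <- utils::read.csv(rows_path, stringsAsFactors = FALSE)
  meta_path <- file.path(dir, "metadata.json")
  metadata <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else list()
  structure(list(rows = rows, summary = summarize_metrics(rows),
                 metadata = metadata),
            class = "metric_report")
}
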