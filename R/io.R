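## File interfaces: YAML solve configs, TIFF images, CSV metric tables.

#' Read a field-solve configuration from YAML
#'
#' Expected blocks: `electrodes` (spacing, diameter, exposure,
#' applied_voltage), `grid` (bounding_box, step), optional `regions` (list
#' of shape/conductivity/label) and `conductivity`.
#'
#' @param path YAML file.
#' @return List with `electrodes` ([electrode_pair()]) and `domain`
#'   ([tissue_domain()]).
#' @export
read_field_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  el <- do.call(electrode_pair, cfg$electrodes)
  dom <- tissue_domain(bounding_box = unlist(cfg$grid$bounding_box),
                       grid_step = cfg$grid$step,
                       conductivity = cfg$conductivity %||% 0.5,
                       regions = cfg$regions %||% list(),
                       electrodes = el)
  list(electrodes = el, domain = dom)
}

#' Write a coverage curve as CSV
#'
#' @param curve data frame from [coverage_curve()].
#' @param path output file.
#' @export
write_coverage_csv <- function(curve, path) {
  write.csv(curve, path, row.names = FALSE)
  invisible(path)
}

#' Read / write calibrated TIFF images
#'
#' Thin wrappers around EBImage: multi-channel arrays are written as
#' multi-frame TIFFs; the pixel size travels in a JSON sidecar
#' (`<path>.json`).
#'
#' @param image a [calibrated_image()].
#' @param path TIFF path.
#' @return `read_calibrated_tiff`: a `calibrated_image`.
#' @export
write_calibrated_tiff <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  EBImage::writeImage(EBImage::Image(image$pixels), path, type = "tiff")
  jsonlite::write_json(list(pixel_size = image$pixel_size,
                            channels = image$channels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibrated_tiff
#' @export
read_calibrated_tiff <- function(path) {
  px <- as.array(EBImage::readImage(path))
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  calibrated_image(px, meta$pixel_size, meta$channels)
}

#' Write region metrics rows as CSV
#'
#' @param metrics list of `region_metrics` (from [count_vessels()]).
#' @param path output file.
#' @param sample,stain identifiers recorded per row.
#' @export
write_region_metrics_csv <- function(metrics, path, sample = "", stain = "") {
  if (inherits(metrics, "region_metrics")) metrics <- list(metrics)
  df <- do.call(rbind, lapply(metrics, function(m)
    data.frame(sample = sample, region = m$label, stain = stain,
               area_percent = m$area_percent, vessel_count = m$vessel_count,
               roi_area_mm2 = m$roi_area_mm2,
               density_per_mm2 = m$vessel_density)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
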