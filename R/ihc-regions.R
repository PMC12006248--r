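## Region-of-interest quantification: area percent and microvessel density.

#' Region of interest polygon
#'
#' @param x,y vertex coordinates in pixels (0-based, x right, y down).
#' @param label one of `"viable_tumor"`, `"peritumoral"`, `"lymph_node"` or
#'   a custom label.
#' @return A `region_of_interest`.
#' @export
roi_polygon <- function(x, y, label = "custom") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (polygon_area(x, y) <= 0)
    stop("ROI polygon must have positive area", call. = FALSE)
  structure(list(x = x, y = y, label = label), class = "region_of_interest")
}

#' Read / write ROI polygons as JSON
#'
#' JSON schema: a list of objects with `label`, `x`, `y` (pixel vertices)
#' and optional `pixel_size`.
#'
#' @param path file path.
#' @param rois list of [roi_polygon()] objects (for writing).
#' @return `read_rois`: list of `region_of_interest`.
#' @export
read_rois <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(raw, function(r) roi_polygon(unlist(r$x), unlist(r$y),
                                      r$label %||% "custom"))
}

#' @rdname read_rois
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(lapply(rois, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

roi_pixel_mask <- function(roi, dim_yx) {
  m <- rasterize_polygon(roi$x, roi$y, dim_yx)
  if (!any(m)) stop("invalid ROI: polygon covers no image pixels", call. = FALSE)
  m
}

#' Positive-area percentage within an ROI
#'
#' @param mask logical matrix of stain-positive pixels (rows = y, cols = x).
#' @param roi a [roi_polygon()] in the same coordinate frame.
#' @return Percent of ROI pixels that are positive.
#' @export
region_area_percent <- function(mask, roi) {
  stopifnot(is.matrix(mask))
  rm_ <- roi_pixel_mask(roi, dim(mask))
  100 * sum(mask & rm_) / sum(rm_)
}

#' Count vessels and compute density within an ROI
#'
#' Connected components of the positive mask are treated as vessel
#' cross-sections; a component belongs to the ROI if its centroid lies
#' inside the polygon (boundary counts as inside), and is kept if its area
#' is at least `min_area_um2`.
#'
#' @param mask logical matrix of stain-positive pixels.
#' @param roi a [roi_polygon()].
#' @param pixel_size micrometres per pixel.
#' @param connectivity 4 or 8 (default 8, matching typical IHC macros).
#' @param min_area_um2 minimum component area, square micrometres; the same
#'   15 um^2 background filter used in the lymph-node pipeline.
#' @return A `region_metrics` list: `label`, `area_percent`, `vessel_count`,
#'   `roi_area_mm2`, `vessel_density` (vessels/mm^2).
#' @export
count_vessels <- function(mask, roi, pixel_size, connectivity = 8L,
                          min_area_um2 = 15) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  roi_area_mm2 <- polygon_area(roi$x, roi$y) * (pixel_size / 1000)^2
  if (roi_area_mm2 <= 0) stop("invalid ROI: zero area", call. = FALSE)
  lab <- .label_components(mask, as.integer(connectivity))
  n <- max(lab)
  count <- 0L
  if (n > 0) {
    idx <- which(lab > 0)
    ids <- lab[idx]
    rows <- (idx - 1L) %% nrow(mask)       # y, 0-based
    cols <- (idx - 1L) %/% nrow(mask)      # x, 0-based
    area_px <- tabulate(ids, nbins = n)
    cx <- tapply(cols, ids, mean)
    cy <- tapply(rows, ids, mean)
    keep <- area_px * pixel_size^2 >= min_area_um2
    inside <- point_in_polygon(cx, cy, roi$x, roi$y)
    count <- sum(keep & inside)
  }
  structure(list(label = roi$label,
                 area_percent = region_area_percent(mask, roi),
                 vessel_count = count,
                 roi_area_mm2 = roi_area_mm2,
                 vessel_density = count / roi_area_mm2),
            class = "region_metrics")
}

#' Picrosirius-red fiber ratio under polarized light
#'
#' Classifies birefringent pixels by hue into red-yellow (thick, collagen
#' I-like) versus green (thin, collagen III-like) fibers and returns their
#' area ratio. Pixels below the saturation or value floors are treated as
#' background.
#'
#' @param rgb y-by-x-by-3 array in `[0, 1]` from a polarized acquisition.
#' @param red_yellow_hue,green_hue hue bands in degrees; `red_yellow_hue`
#'   may wrap around 360.
#' @param sat_floor,val_floor HSV floors below which a pixel is background.
#' @param pixel_size micrometres per pixel (areas returned in um^2 when
#'   given, else pixels).
#' @return List with `ratio`, `red_yellow_area`, `green_area`. A scene with
#'   no green fibers returns `ratio = Inf` with a warning.
#' @export
psr_fiber_ratio <- function(rgb, red_yellow_hue = c(330, 70),
                            green_hue = c(70, 170),
                            sat_floor = 0.2, val_floor = 0.1,
                            pixel_size = NULL) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  hsv <- grDevices::rgb2hsv(r = as.vector(rgb[, , 1]),
                            g = as.vector(rgb[, , 2]),
                            b = as.vector(rgb[, , 3]), maxColorValue = 1)
  hue <- hsv[1, ] * 360
  fg <- hsv[2, ] >= sat_floor & hsv[3, ] >= val_floor
  in_band <- function(h, band) {
    if (band[1] <= band[2]) h >= band[1] & h < band[2]
    else h >= band[1] | h < band[2]   # wrap-around band
  }
  px_area <- if (is.null(pixel_size)) 1 else pixel_size^2
  red <- sum(fg & in_band(hue, red_yellow_hue)) * px_area
  green <- sum(fg & in_band(hue, green_hue)) * px_area
  if (green == 0) {
    warning("no green fiber area: ratio is infinite")
    ratio <- if (red > 0) Inf else NaN
  } else ratio <- red / green
  list(ratio = ratio, red_yellow_area = red, green_area = green)
}

#' Ablation lesion area from a live/dead image pair
#'
#' Thresholds both channels (maximum entropy), extracts the dead-positive,
#' live-negative region, and returns the area of its largest connected
#' component — the lesion — in mm^2.
#'
#' @param live,dead numeric matrices (registered channels).
#' @param pixel_size micrometres per pixel.
#' @return List with `area_mm2`, `n_components` and `empty` flag.
#' @export
ablation_area <- function(live, dead, pixel_size) {
  stopifnot(is.matrix(live), is.matrix(dead), all(dim(live) == dim(dead)),
            pixel_size > 0)
  chan_mask <- function(ch) {
    rng <- range(ch)
    if (rng[1] == rng[2]) return(matrix(FALSE, nrow(ch), ncol(ch)))
    ch > max_entropy_threshold(ch)
  }
  lesion <- chan_mask(dead) & !chan_mask(live)
  if (!any(lesion))
    return(list(area_mm2 = 0, n_components = 0L, empty = TRUE))
  lab <- .label_components(lesion, 8L)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  list(area_mm2 = max(sizes) * (pixel_size / 1000)^2,
       n_components = length(sizes), empty = FALSE)
}
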