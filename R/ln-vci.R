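#' Vascular Complexity Index
#'
#' Morphometric index of a vessel network: the squared sum of all vessel
#' perimeters over 4*pi times the summed vessel areas,
#' \deqn{VCI = (\sum_i P_i)^2 / (4 \pi \sum_i A_i).}
#' A single ideal circle scores exactly 1 (the isoperimetric minimum); a
#' square scores 4/pi; n identical circles score n. The index is invariant
#' under uniform scaling and rigid motion of the network.
#'
#' @param perimeter vessel perimeters (consistent length units), or a
#'   vessel-object data frame with `perimeter_um` and `area_um2` columns.
#' @param area vessel areas (squared length units); ignored when
#'   `perimeter` is a data frame.
#' @return The index (dimensionless); `NA` with a warning for an empty set.
#' @export
#' @examples
#' r <- 3
#' vascular_complexity_index(2 * pi * r, pi * r^2)  # 1
vascular_complexity_index <- function(perimeter, area = NULL) {
  if (is.data.frame(perimeter)) {
    area <- perimeter$area_um2
    perimeter <- perimeter$perimeter_um
  }
  if (!length(perimeter)) {
    warning("VCI undefined for an empty object set")
    return(NA_real_)
  }
  stopifnot(length(perimeter) == length(area), all(area > 0), all(perimeter > 0))
  sum(perimeter)^2 / (4 * pi * sum(area))
}

#' Summarize a lymph node's vascular content
#'
#' Combines classified vessel objects with the node annotation: artifact
#' areas are subtracted from the node area, and per-class area percentage
#' (relative to the net node area), counts, total perimeter and the
#' Vascular Complexity Index are reported.
#'
#' @param objects classified vessel-object data frame (column `class`).
#' @param node_polygon list with `x`, `y` vertices of the node outline, in
#'   micrometres.
#' @param artifact_polygons list of polygons (same format) to subtract.
#' @return A `lymph_node_record`: `net_area_mm2`, and per class
#'   (`lymphatic`, `blood`) a list with `count`, `total_area_um2`,
#'   `total_perimeter_um`, `area_percent`, `vci`. Serializable with
#'   [jsonlite::toJSON()].
#' @export
summarize_node <- function(objects, node_polygon, artifact_polygons = list()) {
  node_area <- polygon_area(node_polygon$x, node_polygon$y)      # um^2
  art_area <- sum(vapply(artifact_polygons,
                         function(p) polygon_area(p$x, p$y), numeric(1)))
  if (art_area >= node_area)
    stop("invalid annotation: artifact area >= node area", call. = FALSE)
  net <- node_area - art_area
  per_class <- lapply(c(lymphatic = "lymphatic", blood = "blood"), function(cl) {
    sub <- objects[objects$class == cl, , drop = FALSE]
    list(count = nrow(sub),
         total_area_um2 = sum(sub$area_um2),
         total_perimeter_um = sum(sub$perimeter_um),
         area_percent = 100 * sum(sub$area_um2) / net,
         vci = if (nrow(sub)) vascular_complexity_index(sub) else NA_real_)
  })
  structure(c(list(net_area_mm2 = net / 1e6, n_objects = nrow(objects)),
              per_class),
            class = "lymph_node_record")
}
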