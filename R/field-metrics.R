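## Ablation coverage prediction and inverse threshold estimation.

## Logical mask of grid cells belonging to a region spec; region may be
## "all", the label of a domain region, or a shape spec list.
region_mask <- function(field, region) {
  axes <- field$axes
  dims <- vapply(axes, length, 1L)
  if (identical(region, "all")) return(array(TRUE, dim = dims))
  if (is.character(region)) {
    labs <- vapply(field$domain$regions, function(r) r$label %||% "", "")
    hit <- which(labs == region)
    if (!length(hit)) stop("no domain region labelled '", region, "'", call. = FALSE)
    region <- field$domain$regions[[hit[1]]]
  }
  d3 <- length(axes) == 3L
  tmp <- array(0L, dim = dims)
  X <- axes[[1]][slice.index(tmp, 1)]
  Y <- axes[[2]][slice.index(tmp, 2)]
  Z <- if (d3) axes[[3]][slice.index(tmp, 3)] else 0
  ctr <- region$center %||% rep(0, length(axes))
  switch(region$shape,
    sphere = (X - ctr[1])^2 + (Y - ctr[2])^2 +
      (if (d3) (Z - ctr[3])^2 else 0) <= region$radius^2,
    cylinder = {
      m <- (X - ctr[1])^2 + (Y - ctr[2])^2 <= region$radius^2
      if (d3 && !is.null(region$height)) m & abs(Z - ctr[3]) <= region$height / 2 else m
    },
    slab = {
      ax <- switch(region$axis %||% "z", x = X, y = Y, z = if (d3) Z else Y)
      ax >= region$from & ax <= region$to
    },
    stop("unknown region shape: ", region$shape, call. = FALSE))
}

#' Spherical tumor region of a given volume
#'
#' Convenience constructor for the coverage analysis: a sphere centred on
#' the electrode midpoint with the prescribed volume.
#'
#' @param volume_mm3 tumor volume, mm^3.
#' @param center sphere center, mm.
#' @return A region spec usable with [ablation_metrics()].
#' @export
tumor_sphere <- function(volume_mm3 = 142, center = c(0, 0, 0)) {
  list(shape = "sphere", center = center,
       radius = (3 * volume_mm3 / (4 * pi))^(1 / 3), label = "tumor")
}

#' Predicted ablation coverage of a region
#'
#' Cells whose field magnitude meets or exceeds the lethal threshold count
#' as ablated; coverage is the ablated fraction of the region, in percent.
#'
#' @param field a `field_solution` from [solve_field()].
#' @param lethal_threshold lethal field threshold, V/cm.
#' @param region `"all"`, a domain-region label, or a shape spec such as
#'   [tumor_sphere()].
#' @return An `ablation_prediction`: `lethal_threshold`, `ablated_volume`
#'   and `region_volume` (mm^3, or mm^2 in 2-D), and `coverage` (%).
#' @export
ablation_metrics <- function(field, lethal_threshold, region = "all") {
  stopifnot(inherits(field, "field_solution"), lethal_threshold >= 0)
  mask <- region_mask(field, region)
  n_region <- sum(mask)
  if (n_region == 0) stop("invalid region: no grid cells inside", call. = FALSE)
  cell <- field$grid_step^length(dim(field$potential))
  n_abl <- sum(field$e_magnitude[mask] >= lethal_threshold)
  structure(list(lethal_threshold = lethal_threshold,
                 ablated_volume = n_abl * cell,
                 region_volume = n_region * cell,
                 coverage = 100 * n_abl / n_region),
            class = "ablation_prediction")
}

#' Coverage versus voltage-to-distance ratio
#'
#' Computes predicted coverage for a set of nominal field strengths. The
#' conduction problem is linear in the applied voltage, so a single solve at
#' a reference voltage is rescaled to every requested ratio.
#'
#' @param domain a [tissue_domain()].
#' @param electrodes an [electrode_pair()]; its `applied_voltage` is ignored
#'   and derived from each ratio as ratio x spacing.
#' @param ratios voltage-to-distance ratios, V/cm.
#' @param lethal_threshold lethal field threshold, V/cm.
#' @param region region spec as in [ablation_metrics()].
#' @param ... passed on to [solve_field()].
#' @return Data frame with `ratio_V_per_cm`, `applied_voltage_V` and
#'   `coverage_percent`; coverage is non-decreasing in the ratio.
#' @export
coverage_curve <- function(domain, electrodes, ratios, lethal_threshold,
                           region = "all", ...) {
  if (any(ratios <= 0)) stop("ratios must be positive", call. = FALSE)
  ratios <- sort(ratios)
  v_ref <- max(electrodes$applied_voltage, 1)
  el <- electrode_pair(electrodes$spacing, electrodes$diameter,
                       electrodes$exposure, v_ref)
  field <- solve_field(domain, el, ...)
  mask <- region_mask(field, region)
  e <- field$e_magnitude[mask]
  n_region <- sum(mask)
  volts <- ratios * el$spacing / 10
  cov <- vapply(volts, function(v) {
    100 * sum(e * (v / v_ref) >= lethal_threshold) / n_region
  }, numeric(1))
  data.frame(ratio_V_per_cm = ratios, applied_voltage_V = volts,
             coverage_percent = cov)
}

#' Invert a measured ablation area to a lethal threshold
#'
#' Given a planar field solution and an ablation area measured on a
#' registered live/dead image, returns the field magnitude t such that the
#' area where |E| >= t equals the measured area. Because area is a step
#' function of t on a grid, the answer is the corresponding order statistic
#' of the |E| values (exact up to one grid quantile).
#'
#' @param field a 2-D `field_solution`, or a 3-D one (its mid-plane z slice
#'   is used).
#' @param measured_area ablation area, mm^2.
#' @return Estimated lethal threshold, V/cm.
#' @export
invert_threshold <- function(field, measured_area) {
  stopifnot(inherits(field, "field_solution"))
  e <- field$e_magnitude
  if (length(dim(e)) == 3L) e <- e[, , ceiling(dim(e)[3] / 2)]
  cell <- field$grid_step^2
  total <- length(e) * cell
  if (measured_area <= 0 || measured_area > total)
    stop(sprintf("measured_area out of range (0, %.4g] mm^2", total), call. = FALSE)
  k <- max(1L, round(measured_area / cell))
  sort(as.vector(e), decreasing = TRUE)[k]
}
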