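## Tumor growth bookkeeping and the ablation-fraction consistency check.

#' Percent change in tumor volume
#'
#' @param v_t volume at the later time point, mm^3.
#' @param v_0 baseline (treatment-day) volume, mm^3; must be positive.
#' @return Percent change, `100 * (v_t - v_0) / v_0`. Scale-invariant.
#' @export
#' @examples
#' percent_change(2.35 * 100, 100)  # 135
percent_change <- function(v_t, v_0) {
  if (any(v_0 <= 0)) stop("invalid baseline: v_0 must be > 0", call. = FALSE)
  100 * (v_t - v_0) / v_0
}

#' Treated-arm growth predicted from an ablation fraction
#'
#' If untreated tumors grow by `control_change` percent and treatment
#' instantaneously removes a fraction `ablation_fraction` of the volume,
#' the expected treated-arm percent change is
#' `100 * ((1 + control_change/100) * (1 - fraction) - 1)`: the surviving
#' fraction grows at the control rate. Strictly decreasing in the fraction
#' and increasing in the control change.
#'
#' @param control_change control-arm percent change (> -100).
#' @param ablation_fraction ablated volume fraction in `[0, 1)`.
#' @return Predicted treated-arm percent change.
#' @export
#' @examples
#' predicted_treated_change(135, 0.2332)  # about 80.2
predicted_treated_change <- function(control_change, ablation_fraction) {
  if (any(control_change <= -100))
    stop("control_change must exceed -100", call. = FALSE)
  if (any(ablation_fraction < 0 | ablation_fraction >= 1))
    stop("invalid fraction: ablation_fraction must lie in [0, 1)", call. = FALSE)
  100 * ((1 + control_change / 100) * (1 - ablation_fraction) - 1)
}

#' Per-animal percent change from a growth table
#'
#' @param growth data frame with columns `animal`, `group`, `day`,
#'   `volume_mm3`.
#' @param from_day baseline day (the treatment day).
#' @param to_day evaluation day.
#' @return Data frame with one row per animal: `animal`, `group`,
#'   `percent_change`.
#' @export
growth_percent_change <- function(growth, from_day = 0, to_day = 1) {
  need <- c("animal", "group", "day", "volume_mm3")
  stopifnot(all(need %in% names(growth)))
  out <- do.call(rbind, lapply(split(growth, growth$animal), function(g) {
    v0 <- g$volume_mm3[g$day == from_day]
    v1 <- g$volume_mm3[g$day == to_day]
    if (!length(v0) || !length(v1)) return(NULL)
    data.frame(animal = g$animal[1], group = g$group[1],
               percent_change = percent_change(v1[1], v0[1]))
  }))
  rownames(out) <- NULL
  out
}
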