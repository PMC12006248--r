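## Synthetic study cohorts: tumor growth series, qPCR / ELISA plates,
## and live/dead lesion images derived from a field solution.

#' Generate a synthetic tumor growth cohort
#'
#' Exponential growth with per-animal lognormal rate variation and
#' lognormal measurement noise. The treated arm loses an instantaneous
#' ablation fraction of its volume at the treatment day. Defaults mirror
#' the study conditions: about seven animals per arm, a control day-1
#' volume increase of 135%, and an ablated fraction of 0.2332.
#'
#' @param seed RNG seed.
#' @param n_per_group animals per arm.
#' @param days measurement days.
#' @param treatment_day day of treatment (volume on this day is
#'   pre-ablation; later days carry the deficit).
#' @param v0_mm3 mean baseline volume, mm^3.
#' @param v0_sdlog lognormal spread of baseline volumes.
#' @param daily_growth mean per-day fractional growth of controls (1.35
#'   doubles-and-a-bit per day: a 135% day-1 increase).
#' @param rate_sdlog lognormal spread of per-animal growth rates.
#' @param ablation_fraction volume fraction removed at treatment.
#' @param noise_sdlog lognormal measurement noise per observation.
#' @return Data frame `animal`, `group` (`control`/`treated`), `day`,
#'   `volume_mm3`, with the generating parameters in attribute `truth`.
#' @export
gen_growth_cohort <- function(seed = 1, n_per_group = 7, days = 0:7,
                              treatment_day = 0, v0_mm3 = 142,
                              v0_sdlog = 0.15, daily_growth = 1.35,
                              rate_sdlog = 0.15,
                              ablation_fraction = 0.2332,
                              noise_sdlog = 0.05) {
  stopifnot(ablation_fraction >= 0, ablation_fraction < 1,
            treatment_day %in% days)
  g0 <- log(1 + daily_growth)
  with_seed(seed, {
    rows <- list()
    for (grp in c("control", "treated")) {
      for (i in seq_len(n_per_group)) {
        v0 <- v0_mm3 * rlnorm(1, 0, v0_sdlog)
        g <- g0 * rlnorm(1, 0, rate_sdlog)
        eps <- if (noise_sdlog > 0) rlnorm(length(days), 0, noise_sdlog) else
          rep(1, length(days))
        v <- v0 * exp(g * (days - treatment_day)) * eps
        if (grp == "treated")
          v[days > treatment_day] <- v[days > treatment_day] * (1 - ablation_fraction)
        rows[[length(rows) + 1L]] <- data.frame(
          animal = sprintf("%s_%02d", grp, i), group = grp,
          day = days, volume_mm3 = v)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(seed = seed, daily_growth = daily_growth,
                               ablation_fraction = ablation_fraction,
                               v0_mm3 = v0_mm3, rate_sdlog = rate_sdlog,
                               noise_sdlog = noise_sdlog)
    out
  })
}

#' Generate qPCR and ELISA fixtures
#'
#' qPCR: Cq values from a log-linear curve at a configured amplification
#' efficiency over the plate's seven-point standard series, plus Gaussian
#' Cq noise. ELISA: absorbances from a configured four-parameter logistic,
#' plus noise. True parameters are returned alongside.
#'
#' @param seed RNG seed.
#' @param standards qPCR standard quantities.
#' @param efficiency amplification efficiency (1 = perfect doubling).
#' @param intercept Cq at unit template quantity.
#' @param cq_noise_sd Gaussian Cq noise, cycles.
#' @param elisa_standards ELISA standard concentrations, pg/ml.
#' @param elisa_params list `a`, `b`, `c`, `d` of the true 4PL.
#' @param abs_noise_sd Gaussian absorbance noise.
#' @return List `qpcr` (data frame `concentration`, `cq`; `truth`) and
#'   `elisa` (data frame `concentration`, `absorbance`; `truth`).
#' @export
gen_assay_fixtures <- function(seed = 1, standards = default_qpcr_standards(),
                               efficiency = 1, intercept = 35,
                               cq_noise_sd = 0.2,
                               elisa_standards = 2000 / 2^(0:7),
                               elisa_params = list(a = 0.08, b = 1.3,
                                                   c = 250, d = 3.2),
                               abs_noise_sd = 0.02) {
  slope <- -1 / log10(1 + efficiency)
  with_seed(seed, {
    cq <- intercept + slope * log10(standards) +
      rnorm(length(standards), 0, cq_noise_sd)
    ab <- fourpl(elisa_standards, elisa_params$a, elisa_params$b,
                 elisa_params$c, elisa_params$d) +
      rnorm(length(elisa_standards), 0, abs_noise_sd)
    list(qpcr = list(standards = data.frame(concentration = standards, cq = cq),
                     truth = list(slope = slope, intercept = intercept,
                                  efficiency = efficiency,
                                  cq_noise_sd = cq_noise_sd)),
         elisa = list(standards = data.frame(concentration = elisa_standards,
                                             absorbance = ab),
                      truth = c(elisa_params, list(abs_noise_sd = abs_noise_sd))))
  })
}

#' Generate a live/dead image pair from a field solution
#'
#' The dead channel is positive where the field magnitude meets the lethal
#' threshold, the live channel on the complement, with optional boundary
#' blur and noise — a synthetic stand-in for calcein/propidium-iodide
#' imaging of a treated construct. For 3-D solutions the mid-plane slice is
#' used.
#'
#' @param field a `field_solution`.
#' @param threshold lethal threshold, V/cm.
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @param blur_sigma Gaussian blur of the channel masks, px.
#' @param noise_sd Gaussian intensity noise.
#' @param level foreground intensity.
#' @return List `live`, `dead` (matrices), `pixel_size_um`, and `truth`
#'   (`threshold`, exact `area_mm2` of the dead region).
#' @export
gen_livedead <- function(field, threshold, seed = 1, blur_sigma = 0,
                         noise_sd = 0, level = 0.9) {
  stopifnot(inherits(field, "field_solution"))
  e <- field$e_magnitude
  if (length(dim(e)) == 3L) e <- e[, , ceiling(dim(e)[3] / 2)]
  dead_mask <- e >= threshold
  area_mm2 <- sum(dead_mask) * field$grid_step^2
  dead <- matrix(ifelse(dead_mask, level, 0), nrow(e), ncol(e))
  live <- matrix(ifelse(dead_mask, 0, level), nrow(e), ncol(e))
  if (blur_sigma > 0) {
    dead <- as.matrix(EBImage::gblur(dead, blur_sigma))
    live <- as.matrix(EBImage::gblur(live, blur_sigma))
  }
  if (noise_sd > 0) {
    with_seed(seed, {
      dead <- dead + rnorm(length(dead), 0, noise_sd)
      live <- live + rnorm(length(live), 0, noise_sd)
    })
    dead[dead < 0] <- 0; live[live < 0] <- 0
  }
  list(live = live, dead = dead,
       pixel_size_um = field$grid_step * 1000,
       truth = list(threshold = threshold, area_mm2 = area_mm2))
}
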