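## qPCR standard-curve quantification with housekeeping normalization.
## Quantities are read off a per-plate log-linear calibration (Cq versus
## log10 template quantity); a fit with R^2 at or below 0.9 is unusable.

#' Fit a qPCR standard curve
#'
#' Least-squares line of Cq against log10 template quantity. Amplification
#' efficiency is derived from the slope as `10^(-1/slope) - 1` (a perfect
#' doubling per cycle gives slope -1/log10(2) = -3.3219 and efficiency 1).
#'
#' @param concentrations standard template quantities, strictly positive.
#' @param cq observed quantification cycles, same length.
#' @param r2_gate minimum usable R-squared (exclusive).
#' @return A `standard_curve_fit`: `slope`, `intercept`, `r_squared`,
#'   `efficiency`, `usable`, and the standards.
#' @export
#' @examples
#' conc <- c(2000, 1000, 500, 250, 125, 61.25, 31.125)
#' fit_standard_curve(conc, 30 - 3.3219 * log10(conc))
fit_standard_curve <- function(concentrations, cq, r2_gate = 0.9) {
  if (length(concentrations) < 3)
    stop("insufficient standards: need at least 3 points", call. = FALSE)
  stopifnot(length(cq) == length(concentrations), all(concentrations > 0))
  lx <- log10(concentrations)
  fit <- lm(cq ~ lx)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  slope <- unname(coef(fit)[2])
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 usable = r2 > r2_gate,
                 concentrations = concentrations, cq = cq),
            class = "standard_curve_fit")
}

#' Quantify a qPCR sample against a standard curve
#'
#' Template abundance is `10^((Cq - intercept)/slope)`; when a reference
#' (housekeeping, e.g. R18S) abundance is supplied, the normalized abundance
#' is their ratio. Samples outside the standard range are flagged. A fit
#' failing the R-squared gate refuses to quantify.
#'
#' @param cq sample quantification cycle(s); `NA` marks undetectable
#'   transcripts, which propagate as `NA` (never zero).
#' @param fit a usable `standard_curve_fit`.
#' @param reference_abundance optional abundance of the housekeeping target
#'   for the same sample(s).
#' @return A `sample_quant` data frame: `cq`, `abundance`,
#'   `normalized_abundance` (if a reference was given), `out_of_range` flag.
#' @export
quantify_qpcr <- function(cq, fit, reference_abundance = NULL) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  if (!fit$usable)
    stop(sprintf("gated fit: standard curve R^2 = %.3f does not exceed 0.9",
                 fit$r_squared), call. = FALSE)
  ab <- 10^((cq - fit$intercept) / fit$slope)
  out <- data.frame(cq = cq, abundance = ab,
                    out_of_range = !is.na(cq) &
                      (cq < min(fit$cq) | cq > max(fit$cq)))
  if (!is.null(reference_abundance)) {
    if (length(reference_abundance) != 1 && length(reference_abundance) != length(cq))
      stop("normalization error: reference abundance length mismatch", call. = FALSE)
    out$normalized_abundance <- ab / reference_abundance
  }
  class(out) <- c("sample_quant", class(out))
  out
}

#' The plate standard series used throughout
#'
#' Default dilution series for qPCR fixtures and simulations.
#' @return Numeric vector of template quantities.
#' @export
default_qpcr_standards <- function() c(2000, 1000, 500, 250, 125, 61.25, 31.125)
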