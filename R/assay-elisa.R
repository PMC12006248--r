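## ELISA quantification: four-parameter logistic calibration and
## tissue-mass normalization.

fourpl <- function(x, a, b, c, d) d + (a - d) / (1 + (x / c)^b)

#' Fit a four-parameter logistic standard curve
#'
#' `y = d + (a - d) / (1 + (x/c)^b)`: `a` is the response at zero
#' concentration, `d` the saturated response, `c` the inflection
#' concentration (EC50) and `b` the Hill slope. Fitted by nonlinear least
#' squares (Levenberg-Marquardt) from heuristic starting values; optional
#' `1/y^2` weighting.
#'
#' @param concentrations standard concentrations (strictly positive).
#' @param response measured signals (e.g. absorbance).
#' @param weights `"uniform"` (default) or `"1/y2"`.
#' @return A `fourpl_fit`: parameters `a`, `b`, `c`, `d`, `rss`, and the
#'   standards.
#' @export
fit_4pl <- function(concentrations, response, weights = c("uniform", "1/y2")) {
  weights <- match.arg(weights)
  if (length(concentrations) < 5)
    stop("need at least 5 standards spanning the sigmoid", call. = FALSE)
  stopifnot(length(response) == length(concentrations), all(concentrations > 0))
  ord <- order(concentrations)
  xs <- concentrations[ord]; ys <- response[ord]
  increasing <- ys[length(ys)] >= ys[1]
  a0 <- ys[1]; d0 <- ys[length(ys)]
  c0 <- 10^stats::approx(ys, log10(xs), xout = (a0 + d0) / 2, ties = mean)$y
  if (!is.finite(c0)) c0 <- exp(mean(log(range(xs))))
  b0 <- if (increasing) 1 else -1
  w <- if (weights == "1/y2") 1 / pmax(response, 1e-6)^2 else rep(1, length(response))
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ d + (a - d) / (1 + (concentrations / c)^b),
                      start = list(a = a0, b = b0, c = c0, d = d0),
                      weights = w,
                      lower = c(a = -Inf, b = -Inf, c = 1e-12, d = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("4PL fit did not converge: ", conditionMessage(e),
                             call. = FALSE))
  p <- as.list(coef(fit))
  structure(list(a = p$a, b = p$b, c = p$c, d = p$d,
                 rss = sum(resid(fit)^2),
                 concentrations = concentrations, response = response),
            class = "fourpl_fit")
}

#' Invert a 4PL curve: signal to concentration
#'
#' Closed-form inverse `x = c * ((a - d)/(y - d) - 1)^(1/b)`. Signals at or
#' beyond the asymptotes have no finite concentration and are returned as
#' `NA` with `out_of_range = TRUE`.
#'
#' @param signal measured signal(s).
#' @param fit a `fourpl_fit`.
#' @return Data frame with `signal`, `concentration`, `out_of_range`.
#' @export
invert_4pl <- function(signal, fit) {
  stopifnot(inherits(fit, "fourpl_fit"))
  lo <- min(fit$a, fit$d); hi <- max(fit$a, fit$d)
  ok <- is.finite(signal) & signal > lo & signal < hi
  conc <- rep(NA_real_, length(signal))
  ratio <- (fit$a - fit$d) / (signal[ok] - fit$d) - 1
  conc[ok] <- fit$c * ratio^(1 / fit$b)
  data.frame(signal = signal, concentration = conc, out_of_range = !ok)
}

#' Normalize an eluate concentration to tissue mass
#'
#' Converts a measured concentration (pg/ml of eluate) into pg analyte per
#' mg of source tissue: `concentration x volume / mass`.
#'
#' @param concentration_pg_ml concentration in the eluate, pg/ml.
#' @param eluate_volume_ml eluate volume, ml.
#' @param tissue_mass_mg wet tissue mass, mg.
#' @return pg analyte per mg tissue.
#' @export
#' @examples
#' normalize_per_mg(100, 0.1, 1)  # 10 pg/mg
normalize_per_mg <- function(concentration_pg_ml, eluate_volume_ml,
                             tissue_mass_mg) {
  if (any(tissue_mass_mg <= 0))
    stop("normalization error: tissue mass must be > 0", call. = FALSE)
  if (any(eluate_volume_ml <= 0))
    stop("normalization error: eluate volume must be > 0", call. = FALSE)
  concentration_pg_ml * eluate_volume_ml / tissue_mass_mg
}
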