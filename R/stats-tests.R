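## Group comparisons and correlation, mirroring the study's statistical
## workflow: optional log10 transform for lognormal variables, unpaired t
## tests with Welch's correction when variances are unequal, one-way ANOVA
## with Tukey's test for more than two groups, Pearson correlation.

#' Compare measurement groups
#'
#' Two groups: unpaired t test, with Welch's correction when the variance
#' ratio exceeds `welch_ratio` (or always, if `welch = TRUE`). More than
#' two groups: one-way ANOVA followed by Tukey's honest significant
#' differences. Variables declared lognormal are log10-transformed before
#' testing; summaries (mean, SEM, n) are reported on the original scale.
#'
#' @param values numeric measurements.
#' @param groups group labels, same length.
#' @param lognormal log10-transform before testing (requires positive
#'   values).
#' @param welch force Welch's correction; `NA` (default) applies it when the
#'   sample variance ratio exceeds `welch_ratio`.
#' @param welch_ratio variance-ratio trigger for Welch's correction.
#' @return A `group_comparison`: per-group `summary` (mean, sem, n), `test`
#'   name, `statistic`, `p_value`, `transform`, and for ANOVA a `tukey`
#'   table of pairwise adjusted p values.
#' @export
compare_groups <- function(values, groups, lognormal = FALSE, welch = NA,
                           welch_ratio = 4) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  summ <- lapply(split(values, groups), function(v)
    list(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v)))
  y <- values
  if (lognormal) {
    if (any(values <= 0))
      stop("transform error: log10 requires positive values", call. = FALSE)
    y <- log10(values)
  }
  if (nlevels(groups) == 2) {
    sp <- split(y, groups)
    vr <- var(sp[[1]]) / var(sp[[2]])
    use_welch <- if (is.na(welch)) (vr > welch_ratio || vr < 1 / welch_ratio) else welch
    tt <- t.test(sp[[1]], sp[[2]], var.equal = !use_welch)
    res <- list(test = if (use_welch) "Welch t" else "Student t",
                statistic = unname(tt$statistic), p_value = tt$p.value,
                tukey = NULL)
  } else {
    fit <- aov(y ~ groups)
    an <- summary(fit)[[1]]
    res <- list(test = "one-way ANOVA + Tukey",
                statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                tukey = as.data.frame(TukeyHSD(fit)$groups))
  }
  structure(c(list(summary = summ,
                   transform = if (lognormal) "log10" else "none"), res),
            class = "group_comparison")
}

#' Pearson correlation with p value
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return List with `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
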