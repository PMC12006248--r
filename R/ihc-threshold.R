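#' Maximum-entropy (Kapur) threshold
#'
#' Automatic binarization threshold maximizing the sum of the Shannon
#' entropies of the background and foreground parts of the grey-level
#' histogram (Kapur, Sahoo & Wong 1985) — the "Max Entropy" method of
#' FIJI/ImageJ. Depends on the image only through its histogram, and is
#' deterministic for a fixed binning.
#'
#' @param x numeric matrix or vector of intensities.
#' @param n_bins number of histogram bins spanning the observed range.
#' @return The threshold, as the upper edge of the selected background bin:
#'   pixels with value > threshold are foreground.
#' @export
#' @examples
#' img <- c(rnorm(500, 0.2, 0.03), rnorm(100, 0.8, 0.03))
#' max_entropy_threshold(img)
max_entropy_threshold <- function(x, n_bins = 256) {
  v <- as.vector(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (!length(v) || rng[1] == rng[2])
    stop("degenerate histogram: image has fewer than 2 distinct values",
         call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1L),
                          n_bins), nbins = n_bins)
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  cp <- cumsum(p)          # background mass up to bin t
  ce <- cumsum(plogp)
  tot <- ce[n_bins]
  crit <- rep(-Inf, n_bins - 1)
  for (t in seq_len(n_bins - 1)) {
    pb <- cp[t]; pf <- 1 - pb
    if (pb <= 0 || pf <= 0) next
    hb <- log(pb) - ce[t] / pb
    hf <- log(pf) - (tot - ce[t]) / pf
    crit[t] <- hb + hf
  }
  if (!any(is.finite(crit)))
    stop("degenerate histogram: all mass in one bin", call. = FALSE)
  edges[which.max(crit) + 1L]
}
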