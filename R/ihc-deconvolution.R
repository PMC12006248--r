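## Chromogenic stain separation: optical density transform and
## colour deconvolution for H-DAB slides.

#' Calibrated image container
#'
#' Lightweight container tying pixel data to its physical calibration.
#' Intensities are stored in `[0, 1]` (EBImage convention).
#'
#' @param pixels matrix (single channel) or y-by-x-by-channel array.
#' @param pixel_size pixel size, micrometres per pixel.
#' @param channels character vector of channel names, e.g. `c("R","G","B")`
#'   or `c("CD31","LYVE1","DAPI")`.
#' @return A `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size,
                             channels = if (length(dim(pixels)) == 3)
                               paste0("ch", seq_len(dim(pixels)[3])) else "ch1") {
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  nch <- if (length(dim(pixels)) == 3) dim(pixels)[3] else 1L
  if (length(channels) != nch)
    stop("channel count does not match channel semantics", call. = FALSE)
  structure(list(pixels = pixels, pixel_size = pixel_size, channels = channels),
            class = "calibrated_image")
}

#' Standard H-DAB stain vectors
#'
#' The published optical-density direction vectors for hematoxylin and DAB
#' (Ruifrok & Johnston), with the residual direction completed orthogonally.
#' Rows are unit vectors in (R, G, B) optical-density space.
#'
#' @return 3 x 3 matrix with rows `hematoxylin`, `dab`, `residual`.
#' @export
hdab_stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             dab = d / sqrt(sum(d^2)),
             residual = r / sqrt(sum(r^2)))
  colnames(m) <- c("R", "G", "B")
  m
}

#' RGB to optical density
#'
#' Beer-Lambert transform `OD = -log10((I + eps) / I0)` per channel. A pixel
#' at the white level has OD 0; a pixel at a tenth of it has OD 1.
#'
#' @param image a `calibrated_image` with RGB channels, or an RGB array in
#'   `[0, 1]`.
#' @param white per-channel white level `I0`; defaults to 1 (a properly
#'   white-balanced slide). Use `"max"` to take each channel's maximum.
#' @param eps guard added to intensities so black pixels stay finite.
#' @param max_od cap applied to the result; if any pixel saturates the cap a
#'   warning is raised.
#' @return Array of optical densities, same shape as the input.
#' @export
od_transform <- function(image, white = 1, eps = 1 / 512, max_od = 4) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("od_transform expects an RGB image", call. = FALSE)
  if (identical(white, "max")) white <- apply(px, 3, max)
  white <- rep_len(white, 3)
  od <- px
  for (k in 1:3) od[, , k] <- -log10((px[, , k] + eps) / white[k])
  od[od < 0] <- 0
  if (any(od > max_od)) {
    warning("saturated optical density capped at ", max_od)
    od[od > max_od] <- max_od
  }
  od
}

#' Colour deconvolution
#'
#' Unmixes a per-channel optical-density image into per-stain concentration
#' channels by inverting the stain matrix pixel-wise. Negative concentrations
#' (noise outside the stain simplex) are clamped to zero and the clamped
#' fraction recorded.
#'
#' @param od optical-density array (from [od_transform()]).
#' @param vectors stain matrix, rows = unit stain vectors
#'   (default [hdab_stain_vectors()]).
#' @param max_condition reject stain matrices with condition number above
#'   this (near-parallel stain vectors cannot be unmixed).
#' @return y-by-x-by-stain array of concentrations, with attribute
#'   `clamped_fraction`.
#' @export
color_deconvolve <- function(od, vectors = hdab_stain_vectors(),
                             max_condition = 1e6) {
  stopifnot(length(dim(od)) == 3, dim(od)[3] == 3, nrow(vectors) == 3)
  if (kappa(vectors, exact = TRUE) > max_condition)
    stop("degenerate stain vectors: matrix is near-singular", call. = FALSE)
  d <- dim(od)
  flat <- matrix(od, ncol = 3)
  conc <- flat %*% solve(vectors)
  clamped <- mean(conc < -1e-12)
  conc[conc < 0] <- 0
  out <- array(conc, dim = d)
  dimnames(out) <- list(NULL, NULL, rownames(vectors))
  attr(out, "clamped_fraction") <- clamped
  out
}
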