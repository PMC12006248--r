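## Synthetic multichannel lymph-node fields: CD31+LYVE1+ lymphatic and
## CD31+LYVE1- blood vessels inside a node polygon, plus sub-threshold
## debris, with per-object ground truth.

#' Generate a synthetic CD31/LYVE-1/DAPI lymph-node field
#'
#' Vessels are filled circular cross-sections placed inside a circular node
#' polygon: every vessel is CD31-positive, lymphatic vessels additionally
#' LYVE-1-positive. Debris blobs below the 15 um^2 background filter can be
#' spiked in. Channels carry optional Gaussian noise.
#'
#' @param seed RNG seed.
#' @param size image side, pixels.
#' @param pixel_size um/px.
#' @param n_lymphatic,n_blood vessel counts per class.
#' @param n_debris sub-15 um^2 debris blobs (CD31-positive specks).
#' @param area_meanlog,area_sdlog lognormal vessel area distribution, um^2.
#' @param debris_area_um2 range of debris areas, um^2 (kept below 15).
#' @param cd31_level,lyve1_level foreground intensities in `[0, 1]`.
#' @param background background intensity in every channel.
#' @param noise_sd Gaussian channel noise.
#' @param min_separation_px minimum gap between object boundaries.
#' @return List: `channels` (named list of matrices `cd31`, `lyve1`,
#'   `dapi`), `node_polygon` (pixel coords), `node_polygon_um`, `truth`
#'   (data frame: id, class, centroid, radius_px, area_um2, perimeter_um),
#'   `pixel_size`, `params`.
#' @export
gen_if_lymphnode <- function(seed = 1, size = 512, pixel_size = 0.65,
                             n_lymphatic = 8, n_blood = 8, n_debris = 0,
                             area_meanlog = log(300), area_sdlog = 0.4,
                             debris_area_um2 = c(3, 10),
                             cd31_level = 0.8, lyve1_level = 0.8,
                             background = 0.05, noise_sd = 0,
                             min_separation_px = 4) {
  stopifnot(max(debris_area_um2) < 15)
  with_seed(seed, {
    cd31 <- matrix(background, size, size)
    lyve1 <- matrix(background, size, size)
    n_ves <- n_lymphatic + n_blood
    n_all <- n_ves + n_debris
    classes <- c(rep("lymphatic", n_lymphatic), rep("blood", n_blood),
                 rep("debris", n_debris))
    areas <- c(rlnorm(n_ves, area_meanlog, area_sdlog),
               runif(n_debris, debris_area_um2[1], debris_area_um2[2]))
    radii <- sqrt(areas / pi) / pixel_size
    node_r <- 0.45 * size
    ctr <- place_centers(n_all, size, size, radii,
                         margin = 0.08 * size, min_sep = min_separation_px)
    rows <- vector("list", n_all)
    for (i in seq_len(n_all)) {
      idx <- disk_indices(size, size, ctr$y[i], ctr$x[i], radii[i])
      cd31[idx] <- cd31_level
      if (classes[i] == "lymphatic") lyve1[idx] <- lyve1_level
      rows[[i]] <- data.frame(id = i, class = classes[i],
                              centroid_x = ctr$x[i] - 1,
                              centroid_y = ctr$y[i] - 1,
                              radius_px = radii[i],
                              area_px = nrow(idx),
                              area_um2 = nrow(idx) * pixel_size^2,
                              perimeter_um = 2 * pi * radii[i] * pixel_size)
    }
    truth <- if (n_all) do.call(rbind, rows) else
      data.frame(id = integer(0), class = character(0))
    dapi <- matrix(background, size, size)
    if (noise_sd > 0) {
      addn <- function(m) {
        m <- m + rnorm(length(m), 0, noise_sd)
        m[m < 0] <- 0; m[m > 1] <- 1; m
      }
      cd31 <- addn(cd31); lyve1 <- addn(lyve1); dapi <- addn(dapi)
    }
    theta <- seq(0, 2 * pi, length.out = 65)[-65]
    node_poly <- list(x = size / 2 + node_r * cos(theta),
                      y = size / 2 + node_r * sin(theta))
    list(channels = list(cd31 = cd31, lyve1 = lyve1, dapi = dapi),
         node_polygon = node_poly,
         node_polygon_um = list(x = node_poly$x * pixel_size,
                                y = node_poly$y * pixel_size),
         truth = truth, pixel_size = pixel_size,
         params = list(seed = seed, noise_sd = noise_sd,
                       cd31_level = cd31_level, lyve1_level = lyve1_level,
                       background = background))
  })
}
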