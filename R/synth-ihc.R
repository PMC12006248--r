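## Seeded synthetic brightfield IHC scenes: DAB-stained vessel
## cross-sections (elliptical annuli) on a hematoxylin background, rendered
## to RGB through the Beer-Lambert forward model, with a ground-truth
## sidecar. Rerunning with the same spec is bit-identical.

disk_indices <- function(nr, nc, cy, cx, r_out, r_in = 0) {
  ys <- max(1, floor(cy - r_out)):min(nr, ceiling(cy + r_out))
  xs <- max(1, floor(cx - r_out)):min(nc, ceiling(cx + r_out))
  g <- expand.grid(y = ys, x = xs)
  d2 <- (g$y - cy)^2 + (g$x - cx)^2
  hit <- d2 <= r_out^2 & d2 >= r_in^2
  cbind(g$y[hit], g$x[hit])
}

## Rejection-sample non-overlapping vessel centres.
place_centers <- function(n, nr, nc, radii, margin, min_sep, max_tries = 2000) {
  cx <- cy <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      x <- runif(1, margin + radii[i], nc - margin - radii[i])
      y <- runif(1, margin + radii[i], nr - margin - radii[i])
      if (!length(cx) ||
          all(sqrt((cx - x)^2 + (cy - y)^2) >= radii[i] + radii[seq_along(cx)] + min_sep)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place vessels without overlap; reduce n or sizes",
                  call. = FALSE)
    cx <- c(cx, x); cy <- c(cy, y)
  }
  list(x = cx, y = cy)
}

#' Generate a synthetic DAB/hematoxylin IHC scene
#'
#' Vessels are rendered as annular (ring) cross-sections of DAB optical
#' density on a uniform hematoxylin background; RGB intensities follow the
#' Beer-Lambert model `I = 10^-(OD_h v_h + OD_d v_d)` with the standard
#' H-DAB stain vectors, plus optional Gaussian noise. The truth table lists
#' every vessel's centroid and area.
#'
#' @param seed RNG seed (the generator is bit-reproducible).
#' @param width,height image size, pixels.
#' @param pixel_size um/px.
#' @param n_vessels number of vessel cross-sections.
#' @param area_meanlog,area_sdlog lognormal outer cross-section area
#'   distribution, um^2 (median `exp(area_meanlog)`).
#' @param lumen_fraction lumen (unstained inner) radius as a fraction of the
#'   outer radius.
#' @param dab_od,hema_od peak DAB optical density inside vessel walls and
#'   background hematoxylin optical density.
#' @param noise_sd Gaussian intensity noise, in `[0, 1]` units.
#' @param min_separation_px minimum gap between vessel outer boundaries.
#' @return List: `image` (a [calibrated_image()] RGB), `dab_od` (the clean
#'   DAB optical-density matrix), `truth` (data frame: id, centroid, outer
#'   radius, wall area in px and um^2), `params`.
#' @export
gen_ihc_scene <- function(seed = 1, width = 512, height = 512,
                          pixel_size = 0.65, n_vessels = 10,
                          area_meanlog = log(80), area_sdlog = 0.5,
                          lumen_fraction = 0.5, dab_od = 0.8, hema_od = 0.25,
                          noise_sd = 0, min_separation_px = 4) {
  with_seed(seed, {
    od_d <- matrix(0, height, width)
    truth <- NULL
    if (n_vessels > 0) {
      areas <- rlnorm(n_vessels, area_meanlog, area_sdlog)   # um^2
      r_out <- sqrt(areas / pi) / pixel_size                 # px
      ctr <- place_centers(n_vessels, height, width, r_out,
                           margin = 2, min_sep = min_separation_px)
      rows <- vector("list", n_vessels)
      for (i in seq_len(n_vessels)) {
        idx <- disk_indices(height, width, ctr$y[i], ctr$x[i],
                            r_out[i], r_out[i] * lumen_fraction)
        od_d[idx] <- dab_od
        rows[[i]] <- data.frame(id = i, centroid_x = ctr$x[i] - 1,
                                centroid_y = ctr$y[i] - 1,
                                outer_radius_px = r_out[i],
                                wall_area_px = nrow(idx),
                                wall_area_um2 = nrow(idx) * pixel_size^2)
      }
      truth <- do.call(rbind, rows)
    } else {
      truth <- data.frame(id = integer(0), centroid_x = numeric(0),
                          centroid_y = numeric(0), outer_radius_px = numeric(0),
                          wall_area_px = integer(0), wall_area_um2 = numeric(0))
    }
    vec <- hdab_stain_vectors()
    rgb <- array(0, dim = c(height, width, 3))
    for (k in 1:3)
      rgb[, , k] <- 10^-(hema_od * vec["hematoxylin", k] + od_d * vec["dab", k])
    if (noise_sd > 0) {
      rgb <- rgb + rnorm(length(rgb), 0, noise_sd)
      rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
    }
    list(image = calibrated_image(rgb, pixel_size, c("R", "G", "B")),
         dab_od = od_d, truth = truth,
         params = list(seed = seed, pixel_size = pixel_size,
                       dab_od = dab_od, hema_od = hema_od,
                       noise_sd = noise_sd))
  })
}
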