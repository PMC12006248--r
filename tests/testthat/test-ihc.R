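# Chromogenic IHC quantification: optical density, colour deconvolution,
# maximum-entropy thresholding, ROI metrics, PSR ratio, lesion area.

test_that("optical density transform follows the Beer-Lambert decade rule", {
  img <- array(1, dim = c(4, 4, 3))
  expect_equal(od_transform(img, eps = 0), array(0, dim = c(4, 4, 3)))
  img[1, 1, ] <- 0.1
  od <- od_transform(img, eps = 0)
  expect_equal(od[1, 1, ], c(1, 1, 1))
  black <- array(0, dim = c(2, 2, 3))
  expect_warning(od_b <- od_transform(black, max_od = 2), "saturated")
  expect_true(all(od_b <= 2))
})

test_that("colour deconvolution inverts the Beer-Lambert forward model", {
  vec <- hdab_stain_vectors()
  set.seed(42)
  ch <- matrix(runif(25, 0, 1.2), 5, 5)   # hematoxylin concentrations
  cd <- matrix(runif(25, 0, 1.2), 5, 5)   # DAB concentrations
  od <- array(0, dim = c(5, 5, 3))
  for (k in 1:3)
    od[, , k] <- ch * vec["hematoxylin", k] + cd * vec["dab", k]
  conc <- color_deconvolve(od, vec)
  expect_equal(conc[, , "hematoxylin"], ch, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(conc[, , "dab"], cd, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(conc[, , "residual"]), 1e-8)
  # pure white pixels carry no stain
  conc0 <- color_deconvolve(array(0, dim = c(2, 2, 3)), vec)
  expect_true(all(conc0 == 0))
  # near-parallel vectors are rejected
  bad <- rbind(c(1, 0, 0), c(1, 1e-9, 0), c(0, 0, 1))
  expect_error(color_deconvolve(od, bad), "near-singular")
})

test_that("max-entropy threshold equals the exhaustive Kapur argmax", {
  # independent oracle: direct entropy evaluation per candidate boundary
  kapur_brute <- function(v, n_bins = 256) {
    rng <- range(v)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bins <- pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1), n_bins)
    p <- tabulate(bins, n_bins) / length(v)
    best <- -Inf; best_t <- NA
    for (t in 1:(n_bins - 1)) {
      pb <- sum(p[1:t]); pf <- 1 - pb
      if (pb <= 0 || pf <= 0) next
      qb <- p[1:t][p[1:t] > 0] / pb
      qf <- p[(t + 1):n_bins][p[(t + 1):n_bins] > 0] / pf
      h <- -sum(qb * log(qb)) - sum(qf * log(qf))
      if (h > best) { best <- h; best_t <- t }
    }
    edges[best_t + 1]
  }
  set.seed(7)
  for (i in 1:20) {
    v <- c(rnorm(300, 0.25, 0.05 + runif(1, 0, 0.1)),
           rnorm(sample(50:300, 1), 0.7, 0.08))
    expect_equal(max_entropy_threshold(v), kapur_brute(v))
  }
  # histogram-only dependence: a shuffle leaves the threshold unchanged
  v <- c(rnorm(500, 0.2, 0.04), rnorm(120, 0.8, 0.05))
  expect_identical(max_entropy_threshold(v), max_entropy_threshold(sample(v)))
  # two-valued image: threshold strictly between the values
  tv <- max_entropy_threshold(c(rep(0.1, 60), rep(0.9, 40)))
  expect_gt(tv, 0.1); expect_lt(tv, 0.9)
  expect_error(max_entropy_threshold(rep(1, 10)), "degenerate")
})

test_that("area percent and vessel counts recover generator ground truth", {
  sc <- gen_ihc_scene(seed = 11, width = 384, height = 384, n_vessels = 10,
                      noise_sd = 0)
  od <- od_transform(sc$image$pixels)
  dab <- color_deconvolve(od)[, , "dab"]
  mask <- dab > max_entropy_threshold(dab)
  roi <- roi_polygon(c(0, 383, 383, 0), c(0, 0, 383, 383), "viable_tumor")
  # area percent against the clean optical-density ground truth
  truth_pct <- 100 * sum(sc$dab_od > 0) / length(sc$dab_od)
  expect_equal(region_area_percent(mask, roi), truth_pct, tolerance = 0.02)
  m <- count_vessels(mask, roi, pixel_size = sc$image$pixel_size)
  expect_equal(m$vessel_count, 10)
  expect_equal(m$vessel_density, m$vessel_count / m$roi_area_mm2)
  # ROI moved away from every vessel counts none
  far <- roi_polygon(c(0, 4, 4, 0), c(0, 0, 4, 4))
  expect_equal(count_vessels(mask, far, sc$image$pixel_size)$vessel_count, 0)
})

test_that("vessel counting honours connectivity and the centroid rule", {
  m <- matrix(FALSE, 30, 30)
  m[5:9, 5:9] <- TRUE
  m[11:15, 11:15] <- TRUE
  m[10, 10] <- TRUE             # 1-px diagonal bridge
  roi <- roi_polygon(c(0, 29, 29, 0), c(0, 0, 29, 29))
  expect_equal(count_vessels(m, roi, 1, connectivity = 8,
                             min_area_um2 = 0)$vessel_count, 1)
  expect_equal(count_vessels(m, roi, 1, connectivity = 4,
                             min_area_um2 = 0)$vessel_count, 3)
})

test_that("region metrics are invariant under translation and rotation", {
  sc <- gen_ihc_scene(seed = 3, width = 200, height = 260, n_vessels = 6)
  dab <- color_deconvolve(od_transform(sc$image$pixels))[, , "dab"]
  mask <- dab > max_entropy_threshold(dab)
  roi <- roi_polygon(c(10, 150, 150, 10), c(10, 10, 190, 190))
  base <- count_vessels(mask, roi, 1)
  # translation of both mask and ROI by (3, 5)
  shifted <- matrix(FALSE, 260, 200)
  shifted[(1:255) + 5, (1:197) + 3] <- mask[1:255, 1:197]
  roi_s <- roi_polygon(roi$x + 3, roi$y + 5)
  tr <- count_vessels(shifted, roi_s, 1)
  expect_equal(tr$vessel_count, base$vessel_count)
  expect_equal(tr$area_percent, base$area_percent, tolerance = 1e-10)
  # 90 degree rotation: (x, y) -> (y, (ncol-1) - x)
  rot <- t(mask)[ncol(mask):1, , drop = FALSE]
  roi_r <- roi_polygon(roi$y, (ncol(mask) - 1) - roi$x)
  rr <- count_vessels(rot, roi_r, 1)
  expect_equal(rr$vessel_count, base$vessel_count)
  expect_equal(rr$area_percent, base$area_percent, tolerance = 1e-10)
})

test_that("half-covered and empty masks give 50% and 0%", {
  mask <- matrix(FALSE, 20, 20)
  mask[, 1:10] <- TRUE
  roi <- roi_polygon(c(-0.5, 19.5, 19.5, -0.5), c(-0.5, -0.5, 19.5, 19.5))
  expect_equal(region_area_percent(mask, roi), 50)
  expect_equal(region_area_percent(matrix(FALSE, 20, 20), roi), 0)
  outside <- roi_polygon(c(100, 110, 110, 100), c(100, 100, 110, 110))
  expect_error(region_area_percent(mask, outside), "invalid ROI")
})

test_that("PSR fiber ratio classifies hue bands with expected symmetries", {
  mk <- function(n_red, n_green, n = 40) {
    img <- array(0, dim = c(n, n, 3))
    stopifnot(n_red + n_green <= n * n)
    idx <- seq_len(n_red + n_green)
    for (i in idx) {
      r <- (i - 1) %% n + 1; c <- (i - 1) %/% n + 1
      if (i <= n_red) img[r, c, ] <- c(1, 0, 0) else img[r, c, ] <- c(0, 1, 0)
    }
    img
  }
  eq <- psr_fiber_ratio(mk(200, 200))
  expect_equal(eq$ratio, 1)
  two <- psr_fiber_ratio(mk(400, 200))
  expect_equal(two$ratio, 2)
  allg <- psr_fiber_ratio(mk(0, 300))
  expect_equal(allg$ratio, 0)
  expect_warning(nog <- psr_fiber_ratio(mk(300, 0)), "infinite")
  expect_true(is.infinite(nog$ratio))
})

test_that("lesion area recovers a synthetic disk and handles empty scenes", {
  n <- 200; r <- 40
  dead <- matrix(0, n, n); live <- matrix(0.9, n, n)
  d <- disk_mask(n, r)
  dead[d] <- 0.9; live[d] <- 0
  px <- 50  # um/px
  res <- ablation_area(live, dead, pixel_size = px)
  truth <- pi * r^2 * (px / 1000)^2
  expect_equal(res$area_mm2, truth, tolerance = 0.03)
  uni <- ablation_area(matrix(0.9, 20, 20), matrix(0, 20, 20), px)
  expect_equal(uni$area_mm2, 0)
  expect_true(uni$empty)
})
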