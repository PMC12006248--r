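# Lymph-node vessel pipeline: pixel features, classifiers, sub-pixel
# segmentation, the 15 um^2 filter, VCI and node summaries.

test_that("pixel features have the expected closed-form behaviour", {
  const <- matrix(0.4, 64, 64)
  f <- compute_pixel_features(const, scales = c(2, 4))
  inner <- 20:44
  expect_equal(max(abs(f[inner, inner, "hessian_det_s2"])), 0, tolerance = 1e-12)
  expect_equal(f[inner, inner, "gaussian_s2"], const[inner, inner],
               tolerance = 1e-6, ignore_attr = TRUE)
  # isotropic Gaussian blob: equal Hessian eigenvalues at the center
  g <- expand.grid(y = 1:65, x = 1:65)
  blob <- matrix(exp(-((g$x - 33)^2 + (g$y - 33)^2) / (2 * 6^2)), 65, 65)
  fb <- compute_pixel_features(blob, scales = 2)
  expect_equal(fb[33, 33, "hessian_eig_max_s2"], fb[33, 33, "hessian_eig_min_s2"],
               tolerance = 1e-6, ignore_attr = TRUE)
  # quadratic ramp a x^2 + b y^2: Hessian determinant = 4ab (smoothing-invariant)
  a <- 0.003; b <- 0.001
  quad <- matrix(a * (g$x - 33)^2 + b * (g$y - 33)^2, 65, 65)
  fq <- compute_pixel_features(quad, scales = 2)
  expect_equal(fq[33, 33, "hessian_det_s2"], 4 * a * b, tolerance = 0.05,
               ignore_attr = TRUE)
  expect_error(compute_pixel_features(matrix(0, 5, 5), scales = 4), "smaller")
})

test_that("pixel classifier separates synthetic CD31 fields and is seed-deterministic", {
  sc <- gen_if_lymphnode(seed = 21, size = 256, n_lymphatic = 5, n_blood = 5,
                         noise_sd = 0.02)
  feats <- compute_pixel_features(sc$channels$cd31)
  labels <- matrix(NA_real_, 256, 256)
  truth_pos <- sc$channels$cd31 > 0.4   # generator foreground, pre-noise level
  labels[truth_pos] <- 1
  labels[!truth_pos] <- 0
  m1 <- train_pixel_classifier(feats, labels, seed = 5)
  m2 <- train_pixel_classifier(feats, labels, seed = 5)
  expect_identical(m1$net$wts, m2$net$wts)
  # held-out tile from a different seed
  sc2 <- gen_if_lymphnode(seed = 22, size = 256, n_lymphatic = 5, n_blood = 5,
                          noise_sd = 0.02)
  p <- predict_pixel_classifier(m1, compute_pixel_features(sc2$channels$cd31))
  truth2 <- sc2$channels$cd31 > 0.4
  acc <- mean((p > 0.5) == truth2)
  expect_gte(acc, 0.95)
  expect_error(train_pixel_classifier(feats, matrix(1, 256, 256)), "both classes")
})

test_that("segmentation recovers disk geometry with sub-pixel accuracy", {
  px <- 0.65
  n <- 120
  r_um <- 10; r_px <- r_um / px
  prob <- matrix(0, n, n); prob[disk_mask(n, r_px)] <- 1
  obj <- segment_vessels(prob, pixel_size = px)
  expect_equal(nrow(obj), 1)
  expect_equal(obj$area_um2, pi * r_um^2, tolerance = 0.05)
  expect_equal(obj$perimeter_um, 2 * pi * r_um, tolerance = 0.02)
  expect_gt(obj$circularity, 0.95)
  expect_gt(obj$solidity, 0.97)
  # two disjoint disks -> two objects
  prob2 <- matrix(0, n, n)
  prob2[disk_mask(n, 10, cx = 30, cy = 30)] <- 1
  prob2[disk_mask(n, 10, cx = 85, cy = 85)] <- 1
  expect_equal(nrow(segment_vessels(prob2, pixel_size = px)), 2)
  # notched disk loses solidity
  prob3 <- matrix(0, n, n); prob3[disk_mask(n, 25)] <- 1
  prob3[55:65, 60:120] <- 0
  obj3 <- segment_vessels(prob3, pixel_size = px)
  expect_lt(obj3$solidity, 0.95)
  # empty map -> empty frame, not an error
  expect_equal(nrow(segment_vessels(matrix(0, 20, 20), pixel_size = px)), 0)
})

test_that("digitized circle perimeters converge to 2*pi*r within 2% at r >= 10 px", {
  for (r in c(10, 14, 20)) {
    n <- 2 * r + 30
    prob <- matrix(0, n, n); prob[disk_mask(n, r)] <- 1
    obj <- segment_vessels(prob, pixel_size = 1)
    expect_lt(abs(obj$perimeter_um - 2 * pi * r) / (2 * pi * r), 0.02)
    # VCI of the digitized circle is within 2% of the ideal 1
    expect_lt(abs(vascular_complexity_index(obj) - 1), 0.02)
  }
})

test_that("object classification reaches 95% on generator cohorts; fallback rule is deterministic", {
  sc <- gen_if_lymphnode(seed = 31, size = 400, n_lymphatic = 10, n_blood = 10,
                         noise_sd = 0.02)
  obj <- segment_vessels((sc$channels$cd31 > 0.4) * 1, pixel_size = sc$pixel_size,
                         channels = list(cd31 = sc$channels$cd31,
                                         lyve1 = sc$channels$lyve1))
  # match objects to truth by nearest centroid
  truth <- sc$truth[sc$truth$class != "debris", ]
  nearest <- vapply(seq_len(nrow(obj)), function(i) {
    d <- (truth$centroid_x * sc$pixel_size - obj$centroid_x_um[i])^2 +
         (truth$centroid_y * sc$pixel_size - obj$centroid_y_um[i])^2
    which.min(d)
  }, 1L)
  # deterministic fallback rule
  cls <- classify_objects(obj, lyve1_background = sc$params$background,
                          lyve1_background_sd = 0.02)
  acc <- mean(cls$class == truth$class[nearest])
  expect_gte(acc, 0.95)
  # background-level LYVE1 object is blood under the fallback rule
  one <- obj[1, , drop = FALSE]
  one$lyve1_mean <- sc$params$background
  expect_equal(classify_objects(one, lyve1_background = sc$params$background,
                                lyve1_background_sd = 0.02)$class, "blood")
  # trained forest also separates the classes
  model <- train_object_classifier(obj, truth$class[nearest], seed = 9)
  cls_rf <- classify_objects(obj, model = model)
  expect_gte(mean(cls_rf$class == truth$class[nearest]), 0.95)
})

test_that("the 15 um^2 filter retains exactly the true vessel set and is idempotent", {
  sc <- gen_if_lymphnode(seed = 41, size = 400, n_lymphatic = 6, n_blood = 6,
                         n_debris = 8, noise_sd = 0)
  obj <- segment_vessels((sc$channels$cd31 > 0.4) * 1,
                         pixel_size = sc$pixel_size, min_pixels = 1L)
  expect_equal(nrow(obj), 20)   # everything segmented, debris included
  kept <- filter_by_area(obj)
  expect_equal(nrow(kept), 12)
  expect_equal(attr(kept, "removed"), 8)
  again <- filter_by_area(kept)
  expect_equal(again$id, kept$id)
  # boundary rule: exact 15 um^2 retained, min 0 keeps all
  fake <- data.frame(id = 1:3, area_um2 = c(10, 15, 20))
  expect_equal(filter_by_area(fake)$id, c(2, 3))
  expect_equal(nrow(filter_by_area(fake, 0)), 3)
  expect_error(filter_by_area(fake, -1), "min_area")
})

test_that("VCI closed forms, additivity and invariances hold", {
  r <- 7
  expect_equal(vascular_complexity_index(2 * pi * r, pi * r^2), 1)
  s <- 3.2
  expect_equal(vascular_complexity_index(4 * s, s^2), 4 / pi)
  n <- 5
  expect_equal(vascular_complexity_index(rep(2 * pi * r, n), rep(pi * r^2, n)), n)
  # scale invariance
  p <- c(20, 35, 12); a <- c(25, 70, 9)
  expect_equal(vascular_complexity_index(3.7 * p, 3.7^2 * a),
               vascular_complexity_index(p, a))
  # isoperimetric floor for a single convex object (here: random rectangles)
  set.seed(1)
  for (i in 1:10) {
    w <- runif(1, 1, 50); h <- runif(1, 1, 50)
    expect_gte(vascular_complexity_index(2 * (w + h), w * h), 1)
  }
  expect_warning(v <- vascular_complexity_index(numeric(0), numeric(0)),
                 "undefined")
  expect_true(is.na(v))
})

test_that("node summaries match generator composition and serialize", {
  sc <- gen_if_lymphnode(seed = 51, size = 400, n_lymphatic = 7, n_blood = 5,
                         noise_sd = 0)
  obj <- segment_vessels((sc$channels$cd31 > 0.4) * 1,
                         pixel_size = sc$pixel_size,
                         channels = list(cd31 = sc$channels$cd31,
                                         lyve1 = sc$channels$lyve1))
  obj <- filter_by_area(obj)
  cls <- classify_objects(obj, lyve1_background = sc$params$background,
                          lyve1_background_sd = 0.02)
  rec <- summarize_node(cls, sc$node_polygon_um)
  expect_equal(rec$lymphatic$count, 7)
  expect_equal(rec$blood$count, 5)
  truth_lym <- sum(sc$truth$area_um2[sc$truth$class == "lymphatic"])
  net <- polygon_area(sc$node_polygon_um$x, sc$node_polygon_um$y)
  expect_equal(rec$lymphatic$area_percent, 100 * truth_lym / net,
               tolerance = 0.05)
  # summaries recomputable from surviving objects
  expect_equal(rec$blood$vci,
               vascular_complexity_index(cls[cls$class == "blood", ]))
  expect_no_error(jsonlite::toJSON(unclass(rec), auto_unbox = TRUE))
  # no vessels -> zeroes
  empty <- summarize_node(cls[0, ], sc$node_polygon_um)
  expect_equal(empty$lymphatic$count, 0)
  expect_equal(empty$blood$area_percent, 0)
  # artifact bigger than node is rejected
  big <- list(x = c(0, 1e4, 1e4, 0), y = c(0, 0, 1e4, 1e4))
  expect_error(summarize_node(cls, sc$node_polygon_um,
                              artifact_polygons = list(big)),
               "invalid annotation")
})

test_that("overlapping fragments merge; disjoint objects are untouched", {
  theta <- seq(0, 2 * pi, length.out = 33)[-33]
  circ <- function(cx, cy, r) list(x = cx + r * cos(theta),
                                   y = cy + r * sin(theta))
  obj <- data.frame(id = 1:3,
                    area_um2 = c(pi * 25, pi * 16, pi * 25),
                    perimeter_um = c(2 * pi * 5, 2 * pi * 4, 2 * pi * 5),
                    circularity = 1, solidity = 1,
                    centroid_x_um = c(10, 12, 60), centroid_y_um = 10,
                    class = "unassigned")
  attr(obj, "polygons") <- list(circ(10, 10, 5), circ(12, 10, 4),
                                circ(60, 10, 5))
  merged <- merge_overlapping(obj)
  expect_equal(nrow(merged), 2)        # the two overlapping circles pooled
  expect_equal(max(merged$area_um2), pi * 25 + pi * 16)
  far <- obj
  attr(far, "polygons") <- list(circ(10, 10, 5), circ(30, 10, 4),
                                circ(60, 10, 5))
  expect_equal(nrow(merge_overlapping(far)), 3)
})

test_that("pipeline output is byte-identical for a fixed seed", {
  run <- function() {
    sc <- gen_if_lymphnode(seed = 61, size = 256, n_lymphatic = 4, n_blood = 4,
                           noise_sd = 0.02)
    obj <- segment_vessels((sc$channels$cd31 > 0.4) * 1,
                           pixel_size = sc$pixel_size,
                           channels = list(lyve1 = sc$channels$lyve1))
    classify_objects(filter_by_area(obj),
                     lyve1_background = sc$params$background,
                     lyve1_background_sd = 0.02)
  }
  a <- run(); b <- run()
  attr(a, "polygons") <- NULL; attr(b, "polygons") <- NULL
  attr(a, "removed") <- NULL; attr(b, "removed") <- NULL
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})
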