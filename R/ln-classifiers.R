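## Pixel- and object-level classifiers for the lymph-node vessel pipeline:
## a small multilayer perceptron marks CD31-positive pixels; segmented
## vessel objects are then split into lymphatic (LYVE-1+) and blood
## (LYVE-1-) classes by a seeded random-forest or a deterministic
## threshold rule.

#' Train the CD31 pixel classifier
#'
#' A multilayer perceptron (single hidden layer, default 5 nodes) on the
#' pixel feature stack, trained on a class-balanced sample of labelled
#' pixels (equal numbers of positive and ignore pixels). Deterministic for
#' a fixed seed.
#'
#' @param features feature array from [compute_pixel_features()].
#' @param labels matrix matching the image: 1 = CD31-positive, 0 = ignore,
#'   NA = unlabelled.
#' @param hidden hidden-layer size.
#' @param max_per_class cap on sampled training pixels per class.
#' @param seed RNG seed controlling sampling and weight initialization.
#' @return A `pixel_classifier_model`.
#' @export
train_pixel_classifier <- function(features, labels, hidden = 5,
                                   max_per_class = 5000, seed = 1) {
  stopifnot(length(dim(features)) == 3, all(dim(labels) == dim(features)[1:2]))
  lab <- as.vector(labels)
  pos <- which(!is.na(lab) & lab == 1)
  neg <- which(!is.na(lab) & lab == 0)
  if (!length(pos) || !length(neg))
    stop("training error: both classes must be present in the labels",
         call. = FALSE)
  nf <- dim(features)[3]
  flat <- matrix(features, ncol = nf)
  colnames(flat) <- dimnames(features)[[3]]
  with_seed(seed, {
    n <- min(length(pos), length(neg), max_per_class)
    take <- c(sample(pos, n), sample(neg, n))
    x <- flat[take, , drop = FALSE]
    y <- nnet::class.ind(factor(ifelse(lab[take] == 1, "cd31", "ignore"),
                                levels = c("cd31", "ignore")))
    ctr <- colMeans(x); scl <- pmax(apply(x, 2, sd), 1e-12)
    net <- nnet::nnet(scale(x, ctr, scl), y, size = hidden, softmax = TRUE,
                      maxit = 300, decay = 1e-4, trace = FALSE, MaxNWts = 5000)
  })
  structure(list(net = net, center = ctr, scale = scl,
                 feature_names = colnames(flat), hidden = hidden, seed = seed),
            class = "pixel_classifier_model")
}

#' Predict CD31 probability per pixel
#'
#' @param model a `pixel_classifier_model`.
#' @param features feature array with the planes the model was trained on.
#' @return Matrix of CD31 probabilities in `[0, 1]`.
#' @export
predict_pixel_classifier <- function(model, features) {
  stopifnot(inherits(model, "pixel_classifier_model"))
  nf <- dim(features)[3]
  flat <- matrix(features, ncol = nf)
  p <- predict(model$net, scale(flat, model$center, model$scale))[, "cd31"]
  matrix(p, nrow = dim(features)[1])
}

#' Train the lymphatic/blood object classifier
#'
#' A seeded random forest over the seven per-object features (CD31 mean,
#' median and sd; LYVE-1 mean and sd; circularity; solidity), standing in
#' for interactive random-trees training.
#'
#' @param objects vessel-object data frame (see [segment_vessels()]).
#' @param classes factor or character vector of `"lymphatic"`/`"blood"`
#'   training labels, one per object.
#' @param n_trees forest size.
#' @param seed RNG seed.
#' @return An `object_classifier_model`.
#' @export
train_object_classifier <- function(objects, classes, n_trees = 100, seed = 1) {
  feats <- object_feature_frame(objects)
  cls <- factor(as.character(classes), levels = c("lymphatic", "blood"))
  if (any(is.na(cls))) stop("classes must be 'lymphatic' or 'blood'", call. = FALSE)
  with_seed(seed, {
    rf <- randomForest::randomForest(feats, cls, ntree = n_trees)
  })
  structure(list(forest = rf, seed = seed), class = "object_classifier_model")
}

object_feature_frame <- function(objects) {
  need <- c("cd31_mean", "cd31_median", "cd31_sd", "lyve1_mean", "lyve1_sd",
            "circularity", "solidity")
  miss <- setdiff(need, names(objects))
  if (length(miss))
    stop("missing object features: ", paste(miss, collapse = ", "), call. = FALSE)
  objects[need]
}

#' Classify vessel objects as lymphatic or blood
#'
#' With a trained [train_object_classifier()] model, predicts each object's
#' class from its intensity and shape features. Without a model, applies
#' the deterministic fallback rule: an object whose mean LYVE-1 intensity
#' exceeds the background level by more than `k_sd` background standard
#' deviations is lymphatic, otherwise blood.
#'
#' @param objects vessel-object data frame.
#' @param model optional `object_classifier_model`.
#' @param lyve1_background,lyve1_background_sd background LYVE-1 mean and sd
#'   (used by the fallback rule).
#' @param k_sd threshold multiplier for the fallback rule.
#' @return `objects` with a `class` column (`"lymphatic"`/`"blood"`).
#' @export
classify_objects <- function(objects, model = NULL, lyve1_background = 0,
                             lyve1_background_sd = 0, k_sd = 2) {
  if (nrow(objects) == 0) {
    objects$class <- character(0)
    return(objects)
  }
  if (!is.null(model)) {
    stopifnot(inherits(model, "object_classifier_model"))
    objects$class <- as.character(predict(model$forest,
                                          object_feature_frame(objects)))
  } else {
    if (!"lyve1_mean" %in% names(objects))
      stop("missing object features: lyve1_mean", call. = FALSE)
    cut <- lyve1_background + k_sd * lyve1_background_sd
    objects$class <- ifelse(objects$lyve1_mean > cut, "lymphatic", "blood")
  }
  objects
}
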