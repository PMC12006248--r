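## Pixel feature stack for the lymph-node CD31 pixel classifier:
## Gaussian-smoothed intensity plus Hessian determinant and extreme
## eigenvalues, each at a set of smoothing scales.

shift_mat <- function(m, dy, dx) {
  # replicate-edge shift: value at (y, x) becomes m[y + dy, x + dx]
  nr <- nrow(m); nc <- ncol(m)
  m[pmin(pmax(seq_len(nr) + dy, 1L), nr), pmin(pmax(seq_len(nc) + dx, 1L), nc)]
}

hessian_features <- function(sm) {
  gxx <- shift_mat(sm, 0, 1) - 2 * sm + shift_mat(sm, 0, -1)
  gyy <- shift_mat(sm, 1, 0) - 2 * sm + shift_mat(sm, -1, 0)
  gxy <- (shift_mat(sm, 1, 1) - shift_mat(sm, 1, -1) -
          shift_mat(sm, -1, 1) + shift_mat(sm, -1, -1)) / 4
  tr <- gxx + gyy
  disc <- sqrt(pmax((gxx - gyy)^2 + 4 * gxy^2, 0))
  list(det = gxx * gyy - gxy^2,
       eig_max = (tr + disc) / 2,
       eig_min = (tr - disc) / 2)
}

#' Pixel feature stack
#'
#' Computes, for each smoothing scale, the Gaussian-smoothed intensity and
#' the determinant, maximum and minimum eigenvalue of the Hessian of the
#' smoothed image — the feature set driving the CD31 pixel classifier.
#'
#' @param image single-channel numeric matrix.
#' @param scales smoothing scales (Gaussian sigma), pixels.
#' @param base_resolution image resolution the scales refer to, um/px
#'   (recorded in the output attributes).
#' @return y-by-x-by-feature array; feature planes are named
#'   `gaussian_s<scale>`, `hessian_det_s<scale>`, `hessian_eig_max_s<scale>`,
#'   `hessian_eig_min_s<scale>`.
#' @export
compute_pixel_features <- function(image, scales = c(2, 4),
                                   base_resolution = 0.65) {
  stopifnot(is.matrix(image), all(scales > 0))
  if (min(dim(image)) < 2 * ceiling(3 * max(scales)) + 1)
    stop("image smaller than the largest smoothing kernel", call. = FALSE)
  planes <- list()
  for (s in scales) {
    sm <- as.matrix(EBImage::gblur(image, sigma = s))
    hess <- hessian_features(sm)
    planes[[paste0("gaussian_s", s)]] <- sm
    planes[[paste0("hessian_det_s", s)]] <- hess$det
    planes[[paste0("hessian_eig_max_s", s)]] <- hess$eig_max
    planes[[paste0("hessian_eig_min_s", s)]] <- hess$eig_min
  }
  out <- array(unlist(planes, use.names = FALSE),
               dim = c(dim(image), length(planes)),
               dimnames = list(NULL, NULL, names(planes)))
  attr(out, "scales") <- scales
  attr(out, "base_resolution") <- base_resolution
  out
}
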