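#' Multiscale isotropic and oriented pixel features
#'
#' Computes, for each scale, one isotropic Laplacian-of-Gaussian response and
#' `n_orient` oriented elongated Gaussian second-derivative (ridge) responses.
#' The oriented filters respond to tubular structures (neurites) while the
#' LoG captures blob-like contrast; together they feed the pixel classifier.
#'
#' @param img an [image2d()] or matrix.
#' @param scales vector of positive Gaussian scales (sigma, px).
#' @param n_orient number of filter orientations.
#' @param elongation long/short axis ratio of the oriented filters.
#' @return A `feature_bank`: list with `features` (n_pixel x n_feature
#'   matrix), `shape`, `scales`, `n_orient`.
#' @export
compute_features <- function(img, scales = c(1, 2, 4), n_orient = 8,
                             elongation = 3) {
  m <- if (inherits(img, "image2d")) img$pixels else img
  stopifnot(length(scales) >= 1)
  if (any(scales <= 0)) stop("scales must be positive")
  feats <- matrix(0, length(m), length(scales) * (1 + n_orient))
  cn <- character(ncol(feats))
  col <- 1
  for (s in scales) {
    feats[, col] <- as.vector(conv2(m, log_kernel(s)))
    cn[col] <- sprintf("log_s%g", s)
    col <- col + 1
    for (o in seq_len(n_orient)) {
      th <- pi * (o - 1) / n_orient
      feats[, col] <- as.vector(conv2(m, ridge_kernel(s, th, elongation)))
      cn[col] <- sprintf("ridge_s%g_o%d", s, o)
      col <- col + 1
    }
  }
  colnames(feats) <- cn
  structure(list(features = feats, shape = dim(m), scales = scales,
                 n_orient = n_orient), class = "feature_bank")
}

# Scale-normalized Laplacian-of-Gaussian kernel (negated: bright blobs > 0).
log_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  g <- expand.grid(y = -r:r, x = -r:r)
  v <- (g$y^2 + g$x^2 - 2 * sigma^2) / sigma^2 *
    exp(-(g$y^2 + g$x^2) / (2 * sigma^2))
  k <- -matrix(v, 2 * r + 1, 2 * r + 1)
  k - mean(k)
}

# Elongated second-derivative-of-Gaussian ridge kernel at orientation theta
# (theta = direction of the ridge axis); positive on bright ridges.
ridge_kernel <- function(sigma, theta, elongation = 3) {
  su <- elongation * sigma
  sv <- sigma
  r <- ceiling(3 * su)
  g <- expand.grid(y = -r:r, x = -r:r)
  u <- g$y * sin(theta) + g$x * cos(theta)
  v <- g$y * cos(theta) - g$x * sin(theta)
  env <- exp(-u^2 / (2 * su^2) - v^2 / (2 * sv^2))
  k <- -matrix((v^2 / sv^4 - 1 / sv^2) * env, 2 * r + 1, 2 * r + 1)
  k - mean(k)
}

#' Train the pixelwise foreground classifier
#'
#' Linear-kernel SVM on the feature bank, trained on a balanced,
#' deterministic subsample of foreground/background pixels of one (or more,
#' concatenated) labelled images. Training is a one-off per image type;
#' prediction is deterministic.
#'
#' @param features a [compute_features()] bank.
#' @param labels logical/0-1 matrix of the same shape (TRUE = neuron).
#' @param n_per_class training pixels sampled per class (evenly spaced, no
#'   RNG).
#' @return A `segmentation_model`.
#' @export
train_classifier <- function(features, labels, n_per_class = 1500) {
  stopifnot(inherits(features, "feature_bank"))
  lab <- as.logical(as_mat(labels))
  if (!identical(length(lab), nrow(features$features)))
    stop("labels shape does not match feature bank")
  if (length(unique(lab)) < 2) stop("both classes must be present in labels")
  pick <- function(idx) idx[unique(round(seq(1, length(idx),
                                             length.out = min(n_per_class, length(idx)))))]
  sel <- c(pick(which(lab)), pick(which(!lab)))
  fit <- e1071::svm(x = features$features[sel, , drop = FALSE],
                    y = factor(lab[sel], levels = c(FALSE, TRUE)),
                    kernel = "linear", scale = TRUE, cost = 1)
  structure(list(svm = fit, scales = features$scales,
                 n_orient = features$n_orient), class = "segmentation_model")
}

#' Segment neurons from background
#'
#' Applies a trained classifier (or, model-free, Otsu thresholding of the
#' intensity image), then removes small components and fills small holes so
#' that the mask is a connected tubular foreground usable by seeding.
#'
#' @param img an [image2d()] or matrix.
#' @param model optional `segmentation_model`; `NULL` selects the Otsu
#'   fallback.
#' @param min_size minimum connected-component area kept (px).
#' @param max_hole maximum hole area filled (px).
#' @param features optional precomputed [compute_features()] bank.
#' @return A `binary_mask`: logical matrix with attribute
#'   `provenance = "computed"`.
#' @export
segment_image <- function(img, model = NULL, min_size = 20, max_hole = 10,
                          features = NULL) {
  m <- if (inherits(img, "image2d")) img$pixels else img
  if (is.null(model)) {
    if (max(m) == min(m)) {
      mask <- matrix(FALSE, nrow(m), ncol(m))
    } else {
      mn <- (m - min(m)) / (max(m) - min(m))
      thr <- EBImage::otsu(EBImage::Image(mn), range = c(0, 1))
      mask <- mn > thr
    }
  } else {
    if (is.null(features))
      features <- compute_features(m, model$scales, model$n_orient)
    pred <- predict(model$svm, features$features)
    mask <- matrix(pred == "TRUE", nrow(m), ncol(m))
  }
  mask <- clean_mask(mask, min_size, max_hole)
  structure(mask, provenance = "computed", class = c("binary_mask", class(mask)))
}

#' Wrap a user-supplied mask
#'
#' @param mask logical/0-1 matrix.
#' @return A `binary_mask` with `provenance = "supplied"`.
#' @export
as_binary_mask <- function(mask) {
  m <- as_mat(mask) > 0
  structure(m, provenance = "supplied", class = c("binary_mask", class(m)))
}
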