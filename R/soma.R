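#' Directional ratio map of a binary mask
#'
#' At each foreground pixel, oriented line filters of a fixed length are
#' applied to the mask over `n_orient` orientations; the score is the
#' minimum response divided by the maximum response. Isotropic interiors
#' (somas) score near 1 because every orientation is fully covered; thin
#' tubes (neurites) score near `width / length`. Filters act on the mask,
#' not on intensities, so the descriptor measures geometry and is robust to
#' staining variation.
#'
#' @param mask logical/0-1 matrix (the segmentation foreground).
#' @param length line filter length in px (odd, >= 3); choose it to exceed
#'   twice the widest neurite.
#' @param n_orient number of orientations (>= 4).
#' @return A `directional_ratio` list: `score` matrix in \code{[0, 1]}
#'   (0 on background), `length`, `n_orient`.
#' @export
directional_ratio <- function(mask, length = 15, n_orient = 16) {
  stopifnot(length >= 3, n_orient >= 4)
  if (length %% 2 == 0) length <- length + 1
  m <- as_mat(mask) * 1
  if (!any(m > 0)) {
    return(structure(list(score = matrix(0, nrow(m), ncol(m)),
                          length = length, n_orient = n_orient),
                     class = "directional_ratio"))
  }
  h <- (length - 1) / 2
  t_seq <- -h:h
  resp_min <- NULL
  resp_max <- NULL
  for (o in seq_len(n_orient)) {
    th <- pi * (o - 1) / n_orient
    yy <- round(t_seq * sin(th))
    xx <- round(t_seq * cos(th))
    k <- matrix(0, 2 * h + 1, 2 * h + 1)
    for (i in seq_along(t_seq))
      k[yy[i] + h + 1, xx[i] + h + 1] <- k[yy[i] + h + 1, xx[i] + h + 1] + 1 / length
    r <- conv2(m, k)
    if (is.null(resp_min)) { resp_min <- r; resp_max <- r }
    else { resp_min <- pmin(resp_min, r); resp_max <- pmax(resp_max, r) }
  }
  score <- matrix(0, nrow(m), ncol(m))
  fg <- m > 0 & resp_max > 0
  # rounded to suppress FFT convolution noise, so thresholding the score is
  # reproducible across equivalent inputs (e.g. rotated copies)
  score[fg] <- round(pmin(pmax(resp_min[fg] / resp_max[fg], 0), 1), 6)
  structure(list(score = score, length = length, n_orient = n_orient),
            class = "directional_ratio")
}

new_soma_region <- function(id, mask) {
  w <- which(mask, arr.ind = TRUE)
  structure(list(id = id, mask = mask,
                 centroid = c(mean(w[, 1]), mean(w[, 2])),
                 area = nrow(w)),
            class = "soma_region")
}

#' Detect soma regions
#'
#' Thresholds the directional-ratio score, opens morphologically, keeps
#' components above a minimum area, and refines each region boundary by
#' geodesic dilation inside the foreground restricted to pixels whose score
#' stays above half the threshold — so neurite stumps are excluded. Regions
#' are optionally split when clustered somas merge into one component.
#'
#' @param mask segmentation foreground (logical matrix).
#' @param dr optional precomputed [directional_ratio()].
#' @param dr_threshold score threshold for the isotropic (soma) core.
#' @param length,n_orient passed to [directional_ratio()] when `dr` is NULL.
#' @param min_area minimum soma area (px).
#' @param open_radius radius of the morphological opening disk.
#' @param refine_iter geodesic dilation extent (px) of the boundary
#'   refinement.
#' @param split split clustered somas with [split_clustered_somas()].
#' @return List of `soma_region` (id, mask, centroid, area); possibly empty.
#' @export
detect_somas <- function(mask, dr = NULL, dr_threshold = 0.6, length = 15,
                         n_orient = 16, min_area = 100, open_radius = 2,
                         refine_iter = 5, split = TRUE) {
  m <- as_mat(mask) > 0
  if (!any(m)) return(list())
  if (is.null(dr)) dr <- directional_ratio(m, length, n_orient)
  core <- dr$score >= dr_threshold
  if (open_radius > 0 && any(core)) {
    br <- EBImage::makeBrush(2 * open_radius + 1, "disc")
    core <- as_mat(EBImage::dilate(EBImage::erode(EBImage::Image(core * 1), br), br)) > 0
  }
  if (!any(core)) return(list())
  lab <- as_mat(EBImage::bwlabel(EBImage::Image(core * 1)))
  sz <- tabulate(lab[lab > 0])
  keep <- which(sz >= min_area)
  if (!length(keep)) return(list())
  lab[!(lab %in% keep)] <- 0L
  lab <- as_mat(EBImage::bwlabel(EBImage::Image((lab > 0) * 1)))
  # geodesic refinement: grow cores within {foreground, score >= thr/2},
  # limited to refine_iter px from the core
  constraint <- m & dr$score >= dr_threshold / 2
  dist_core <- as_mat(EBImage::distmap(EBImage::Image((lab == 0) * 1)))
  grow <- constraint & (lab > 0 | dist_core <= refine_iter)
  filled <- lab
  todo <- which(grow & lab == 0, arr.ind = TRUE)
  if (nrow(todo)) {
    core_px <- which(lab > 0, arr.ind = TRUE)
    core_lab <- lab[core_px]
    nn <- nearest_seed(todo, core_px)
    filled[todo] <- core_lab[nn]
  }
  regions <- list()
  for (i in sort(unique(filled[filled > 0]))) {
    # keep only the part connected to this core (nearest-core labelling can
    # capture satellites across background)
    part <- filled == i
    comp <- as_mat(EBImage::bwlabel(EBImage::Image(part * 1)))
    core_comp <- unique(comp[part & lab == i])
    part <- part & (comp %in% core_comp)
    if (!any(part)) next
    reg <- new_soma_region(length(regions) + 1L, part)
    if (split) {
      parts <- split_clustered_somas(reg)
      for (p in parts) {
        p$id <- length(regions) + 1L
        regions[[p$id]] <- p
      }
    } else {
      reg$id <- length(regions) + 1L
      regions[[reg$id]] <- reg
    }
  }
  regions
}

#' Split clustered somas
#'
#' Watershed on the interior Euclidean distance transform with h-maxima
#' style merging (the `tolerance` of [EBImage::watershed()]); a convex
#' region returns unchanged, touching somas split along the distance-valley.
#' The outputs are disjoint connected regions whose union is the input.
#'
#' @param region a `soma_region`.
#' @param tolerance minimum height of a distance maximum to seed its own
#'   region (px).
#' @return List of `soma_region`.
#' @export
split_clustered_somas <- function(region, tolerance = 2) {
  stopifnot(inherits(region, "soma_region"))
  d <- EBImage::distmap(EBImage::Image(region$mask * 1))
  ws <- as_mat(EBImage::watershed(d, tolerance = tolerance))
  ids <- sort(unique(ws[ws > 0]))
  if (length(ids) <= 1) return(list(region))
  lapply(seq_along(ids), function(k) new_soma_region(k, ws == ids[k]))
}

#' Soma label image
#'
#' @param regions list of `soma_region`.
#' @param shape image dimensions.
#' @return Integer matrix, pixel value = soma id (0 background).
#' @export
soma_label_image <- function(regions, shape) {
  lab <- matrix(0L, shape[1], shape[2])
  for (r in regions) lab[r$mask] <- r$id
  lab
}
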