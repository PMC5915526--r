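#' Match predicted neurites against ground truth
#'
#' Somas are paired by centroid proximity (greedy nearest pairs under
#' `soma_tol`). A true neurite is a true positive when predicted neurites of
#' the same (matched) neuron cover at least `cover_frac` of its centerline
#' within `dist_tol` px; uncovered true neurites are false negatives. A
#' predicted neurite whose own trace mostly follows a true neurite of a
#' different neuron — or follows nothing — is a false positive.
#'
#' @param pred list of `neuron_tree` from [extract_trees()].
#' @param truth a `ground_truth` from [generate_phantom()], or a compatible
#'   list of trees with `soma$centroid` and `neurites[[i]]$pts`.
#' @param cover_frac coverage fraction defining a correct trace.
#' @param dist_tol distance tolerance (px).
#' @param soma_tol maximum soma-centroid pairing distance (px).
#' @return A `neurite_match` list: counts `TP`, `FP`, `FN`, per-neurite
#'   `records` data.frame, and the soma pairing.
#' @export
match_neurites <- function(pred, truth, cover_frac = 0.8, dist_tol = 3,
                           soma_tol = 20) {
  true_trees <- if (inherits(truth, "ground_truth")) truth$trees else truth
  pc <- t(vapply(pred, function(t) t$soma$centroid, numeric(2)))
  tc <- t(vapply(true_trees, function(t) t$soma$centroid, numeric(2)))
  # greedy nearest-pair soma assignment under the tolerance
  d <- sqrt(outer(pc[, 1], tc[, 1], "-")^2 + outer(pc[, 2], tc[, 2], "-")^2)
  pair_pred <- rep(NA_integer_, nrow(pc))
  used_t <- logical(nrow(tc))
  repeat {
    d_open <- d
    d_open[!is.na(pair_pred), ] <- Inf
    d_open[, used_t] <- Inf
    if (all(!is.finite(d_open))) break
    k <- arrayInd(which.min(d_open), dim(d_open))
    if (d_open[k] > soma_tol) break
    pair_pred[k[1]] <- k[2]
    used_t[k[2]] <- TRUE
  }
  if (all(is.na(pair_pred))) stop("soma matching failed: no pairs under tolerance")

  dense_pred <- lapply(pred, function(t)
    lapply(t$neurites, function(nn)
      polyline_resample(nn$nodes[, c("y", "x"), drop = FALSE], 1)$pts))
  dense_true <- lapply(true_trees, function(t)
    lapply(t$neurites, function(nn) polyline_resample(nn$pts, 1)$pts))

  records <- list()
  TP <- 0L; FN <- 0L
  for (ti in seq_along(true_trees)) {
    pi <- match(ti, pair_pred)
    for (ni in seq_along(dense_true[[ti]])) {
      tp_pts <- dense_true[[ti]][[ni]]
      cov <- 0
      if (!is.na(pi) && length(dense_pred[[pi]])) {
        allp <- do.call(rbind, dense_pred[[pi]])
        cov <- mean(min_dist_to_set(tp_pts, allp) <= dist_tol)
      }
      ok <- cov >= cover_frac
      if (ok) TP <- TP + 1L else FN <- FN + 1L
      records[[length(records) + 1]] <-
        data.frame(kind = "true", neuron = ti, neurite = ni,
                   matched_neuron = if (is.na(pi)) NA_integer_ else pi,
                   coverage = cov, correct = ok)
    }
  }
  FP <- 0L
  for (pi in seq_along(pred)) {
    ti <- pair_pred[pi]
    for (ni in seq_along(dense_pred[[pi]])) {
      pp <- dense_pred[[pi]][[ni]]
      if (nrow(pp) < 3) next   # stub traces are not detections
      best_frac <- 0; best_t <- NA_integer_
      for (tj in seq_along(true_trees)) {
        allt <- do.call(rbind, dense_true[[tj]])
        if (is.null(allt)) next
        fr <- mean(min_dist_to_set(pp, allt) <= dist_tol)
        if (fr > best_frac) { best_frac <- fr; best_t <- tj }
      }
      wrong <- (best_frac < 0.5) || (is.na(ti)) || (!is.na(best_t) && best_t != ti)
      if (wrong) FP <- FP + 1L
      records[[length(records) + 1]] <-
        data.frame(kind = "pred", neuron = pi, neurite = ni,
                   matched_neuron = best_t, coverage = best_frac,
                   correct = !wrong)
    }
  }
  structure(list(TP = TP, FP = FP, FN = FN,
                 records = do.call(rbind, records),
                 soma_pairs = pair_pred),
            class = "neurite_match")
}

#' Neurite-level performance metrics
#'
#' `sensitivity = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `dice = 2 TP / (2 TP + FN + FP)`; the Dice coefficient is the harmonic
#' mean of the first two.
#'
#' @param result a `neurite_match`, or a list/vector with TP, FP, FN.
#' @return Named numeric vector (sensitivity, precision, dice); all zero
#'   (with a `defined` attribute FALSE) when every count is zero.
#' @export
trace_metrics <- function(result) {
  TP <- result$TP; FP <- result$FP; FN <- result$FN
  if (TP + FN + FP == 0) {
    out <- c(sensitivity = 0, precision = 0, dice = 0)
    attr(out, "defined") <- FALSE
    return(out)
  }
  out <- c(sensitivity = if (TP + FN > 0) TP / (TP + FN) else 0,
           precision = if (TP + FP > 0) TP / (TP + FP) else 0,
           dice = 2 * TP / (2 * TP + FN + FP))
  attr(out, "defined") <- TRUE
  out
}

#' Crossing resolution rate
#'
#' A recorded crossing is solved when both involved neurites are correctly
#' traced and assigned (TP) and the part of each true centerline distal to
#' the crossing point is covered by its own neuron's predicted trace — i.e.
#' the tracer did not swap onto the intersecting neurite.
#'
#' @param pred list of `neuron_tree`.
#' @param truth a `ground_truth` with a `crossings` table.
#' @param match optional precomputed [match_neurites()] result.
#' @param cover_frac,dist_tol coverage proxy parameters.
#' @return Fraction of crossings solved; `NA` (attribute
#'   `defined = FALSE`) when the phantom has no crossings.
#' @export
crossing_resolution_rate <- function(pred, truth, match = NULL,
                                     cover_frac = 0.8, dist_tol = 3) {
  stopifnot(inherits(truth, "ground_truth"))
  cr <- truth$crossings
  if (is.null(cr) || nrow(cr) == 0) {
    out <- NA_real_
    attr(out, "defined") <- FALSE
    return(out)
  }
  if (is.null(match)) match <- match_neurites(pred, truth, cover_frac, dist_tol)
  rec <- match$records
  solved <- logical(nrow(cr))
  for (k in seq_len(nrow(cr))) {
    ok <- TRUE
    for (side in c("a", "b")) {
      ti <- cr[[paste0("neuron_", side)]][k]
      ni <- cr[[paste0("neurite_", side)]][k]
      s_at <- cr[[paste0("s_", side)]][k]
      r <- rec[rec$kind == "true" & rec$neuron == ti & rec$neurite == ni, ]
      if (nrow(r) != 1 || !r$correct) { ok <- FALSE; break }
      pi <- match$soma_pairs
      pi <- match(ti, pi)
      nn <- truth$trees[[ti]]$neurites[[ni]]
      distal <- nn$pts[nn$arclength > s_at + dist_tol, , drop = FALSE]
      if (nrow(distal) >= 3) {
        allp <- do.call(rbind, lapply(pred[[pi]]$neurites, function(x)
          polyline_resample(x$nodes[, c("y", "x"), drop = FALSE], 1)$pts))
        cov <- mean(min_dist_to_set(distal, allp) <= dist_tol)
        if (cov < cover_frac) { ok <- FALSE; break }
      }
    }
    solved[k] <- ok
  }
  out <- mean(solved)
  attr(out, "defined") <- TRUE
  out
}
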