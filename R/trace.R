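#' Tracing configuration
#'
#' Parameters of the tree-extraction routine: soma-mask dilation rates for
#' neurite initialization, the seed threshold applied to the normalized
#' sharpened distance transform, and the geometry of the fan search
#' (initial rectangle length 10 px, growing by 2 px over up to 10 rounds,
#' sweeping in angle up to a hard limit of 2*pi/5).
#'
#' @param dilation_rates increasing scaling factors (> 1) applied to the
#'   soma mask about its centroid.
#' @param seed_threshold threshold `tau` on the min-max-normalized sharpened
#'   distance transform.
#' @param L0 initial search-rectangle length (px).
#' @param L_step length increment per search round (px).
#' @param max_rounds number of search rounds before a neurite is declared
#'   completely traced.
#' @param fan_max maximum angular deviation of the search windows (radians).
#' @param fan_step angular step between successive window pairs (radians).
#' @param length_decay multiplicative length shrink per angular step (the
#'   off-axis rectangles are slightly shorter than the axis one).
#' @param width_min minimum rectangle width (px); the width used is
#'   `max(width_min, 2 * Df(current seed))` so the window spans the local
#'   neurite diameter.
#' @param heading_lag arclength (px) over which the expected orientation is
#'   measured (principal axis of the trailing trace nodes); the window keeps
#'   the estimate stable where merged structures displace single seeds
#'   sideways.
#' @param max_turn maximum change of the heading estimate per accepted seed
#'   (radians): neurites change orientation smoothly, so the expected
#'   orientation is slew-rate limited; the actual trace may still turn up
#'   to `fan_max` at any step.
#' @param min_path_fg minimum fraction of the straight connecting segment
#'   that must lie on the segmentation foreground for a seed to be accepted
#'   (tolerates short seeding gaps but forbids jumping across background
#'   onto a different neurite).
#' @param branching spawn child branches when a search round finds seeds in
#'   disjoint angular sub-fans (and none dead-ahead).
#' @param branch_max_dev maximum angular deviation (radians) at which an
#'   off-axis sub-fan may spawn a branch; seeds deviating more are treated
#'   as belonging to an intersecting neurite, not a bifurcation.
#' @param conflict_dist distance (px) at which a claimed seed near another
#'   tree's nodes is logged as a contested assignment.
#' @return A `trace_config` list.
#' @export
trace_config <- function(dilation_rates = c(1.1, 1.2, 1.3),
                         seed_threshold = 0.16, L0 = 10, L_step = 2,
                         max_rounds = 10, fan_max = 2 * pi / 5,
                         fan_step = pi / 16, length_decay = 0.95,
                         width_min = 3, heading_lag = 16, max_turn = pi / 9,
                         min_path_fg = 0.6,
                         branching = TRUE,
                         branch_max_dev = pi / 5, conflict_dist = 2) {
  stopifnot(all(diff(dilation_rates) > 0), all(dilation_rates > 1),
            seed_threshold > 0, seed_threshold < 1, L0 > 0,
            fan_max <= pi / 2, fan_step > 0, length_decay > 0,
            length_decay <= 1)
  structure(as.list(environment()), class = "trace_config")
}

#' Euclidean distance transform of a binary mask
#'
#' `Df(x) = min over background y of ||x - y||`; exact Euclidean metric,
#' 0 on background. Its ridge is the neurite centerline.
#'
#' @param f logical/0-1 matrix; must contain at least one background pixel.
#' @return Numeric matrix of distances.
#' @export
distance_map <- function(f) {
  m <- as_mat(f) > 0
  if (!any(!m)) stop("Df undefined: mask has no background pixel")
  as_mat(EBImage::distmap(EBImage::Image(m * 1), metric = "euclidean"))
}

#' Morphological skeleton (Zhang-Suen thinning)
#'
#' @param mask logical/0-1 matrix.
#' @param symmetrize union the thinnings of the four quarter-turn rotations
#'   of the mask (mapped back), making the result exactly equivariant under
#'   90-degree rotation at the cost of an occasionally 2-px-wide ridge.
#' @return Logical matrix of centerline pixels.
#' @export
skeletonize <- function(mask, symmetrize = FALSE) {
  if (symmetrize) {
    m <- as_mat(mask) > 0
    sk <- skeletonize(m)
    r1 <- rot90_mat(m)
    sk1 <- skeletonize(r1)
    r2 <- rot90_mat(r1)
    sk2 <- skeletonize(r2)
    r3 <- rot90_mat(r2)
    sk3 <- skeletonize(r3)
    # map each skeleton back through the inverse rotations
    inv1 <- rot90_mat(rot90_mat(rot90_mat(sk1)))
    inv2 <- rot90_mat(rot90_mat(sk2))
    inv3 <- rot90_mat(sk3)
    return(sk | inv1 | inv2 | inv3)
  }
  p <- (as_mat(mask) > 0) * 1L
  nbr <- function(m, oy, ox) mat_shift(m, -oy, -ox)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P2 <- nbr(p, -1, 0); P3 <- nbr(p, -1, 1); P4 <- nbr(p, 0, 1)
      P5 <- nbr(p, 1, 1); P6 <- nbr(p, 1, 0); P7 <- nbr(p, 1, -1)
      P8 <- nbr(p, 0, -1); P9 <- nbr(p, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      cond <- p == 1 & B >= 2 & B <= 6 & A == 1
      cond <- cond & if (sub == 1) {
        (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) { p[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  p > 0
}

# TRUE for each point of `pts` lying inside some ball (seed, radius df).
covered_by_balls <- function(pts, seed_pos, df, slack = 0) {
  if (nrow(seed_pos) == 0) return(rep(FALSE, nrow(pts)))
  out <- logical(nrow(pts))
  r2 <- (df + slack)^2
  for (i0 in seq(1, nrow(pts), by = 2000L)) {
    i1 <- min(i0 + 1999L, nrow(pts))
    d2 <- outer(pts[i0:i1, 1], seed_pos[, 1], "-")^2 +
      outer(pts[i0:i1, 2], seed_pos[, 2], "-")^2
    out[i0:i1] <- rowSums(d2 <= rep(r2, each = i1 - i0 + 1)) > 0
  }
  out
}

# Index of the nearest seed for each point. Exact distance ties (common
# with integer pixel coordinates) are broken by the seed's (y, x) position,
# so the labelling does not depend on the storage order of the seeds.
nearest_seed <- function(pts, seed_pos) {
  n <- nrow(seed_pos)
  rnk <- integer(n)
  rnk[order(seed_pos[, 1], seed_pos[, 2])] <- seq_len(n)
  eps <- rnk * 1e-6 / max(n, 1)
  out <- integer(nrow(pts))
  for (i0 in seq(1, nrow(pts), by = 2000L)) {
    i1 <- min(i0 + 1999L, nrow(pts))
    d2 <- outer(pts[i0:i1, 1], seed_pos[, 1], "-")^2 +
      outer(pts[i0:i1, 2], seed_pos[, 2], "-")^2
    d2 <- sweep(d2, 2, eps, "+")
    out[i0:i1] <- max.col(-d2, ties.method = "first")
  }
  out
}

# Greedy ball suppression: iterate candidates in decreasing Df order; each
# kept seed removes all remaining candidates inside its Df-ball. Ties in Df
# are broken by distance to the image centre (invariant under quarter-turn
# rotations of the input), then by index.
suppress_seeds <- function(pos, df, keep_first = 0L, centre = NULL) {
  n <- nrow(pos)
  if (n == 0) return(integer(0))
  cd <- if (is.null(centre)) rep(0, n) else
    (pos[, 1] - centre[1])^2 + (pos[, 2] - centre[2])^2
  ord <- order(-df, cd, seq_len(n))
  alive <- rep(TRUE, n)
  kept <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    d2 <- (pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2
    kill <- alive & d2 <= df[i]^2
    kill[i] <- FALSE
    if (i <= keep_first) kill[seq_len(keep_first)] <- FALSE
    alive[kill] <- FALSE
  }
  sort(kept)
}

#' Compute centerline seeds from the distance transform
#'
#' The distance transform of the segmentation is convolved with a 3x3
#' sharpening kernel (centre 2, others -1/8) to enhance its ridge maxima,
#' min-max normalized over the foreground and thresholded at
#' `seed_threshold`; surviving candidates are pruned so that each kept
#' seed's ball of radius `Df(s)` contains no other seed. Where the balls of
#' neighbouring seeds fail to cover the foreground skeleton (gaps, typically
#' on thin segments dominated by the global normalization), the distance
#' response is re-normalized locally inside the gap region, thresholding and
#' suppression are re-run there, and remaining chain breaks are closed by
#' promoting skeleton pixels to seeds.
#'
#' @param f segmentation foreground (logical matrix).
#' @param cfg a [trace_config()].
#' @param repair run the gap-repair stage.
#' @return A data.frame (class `seed_set`) with columns `y`, `x`, `df`.
#' @export
compute_seeds <- function(f, cfg = trace_config(), repair = TRUE) {
  f <- as_mat(f) > 0
  empty <- data.frame(y = numeric(0), x = numeric(0), df = numeric(0))
  class(empty) <- c("seed_set", "data.frame")
  if (!any(f)) return(empty)
  Df <- distance_map(f)
  k <- matrix(-1 / 8, 3, 3); k[2, 2] <- 2
  resp <- conv2(Df, k)
  rf <- resp[f]
  rng <- range(rf)
  norm <- matrix(0, nrow(f), ncol(f))
  norm[f] <- if (diff(rng) > 0) (rf - rng[1]) / diff(rng) else 1
  cand <- which(f & norm >= cfg$seed_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  dfc <- Df[cand]
  centre <- (dim(f) + 1) / 2
  kept <- suppress_seeds(cand, dfc, centre = centre)
  pos <- cand[kept, , drop = FALSE]
  dfk <- dfc[kept]

  if (repair) {
    skel <- skeletonize(f, symmetrize = TRUE)
    sk <- which(skel, arr.ind = TRUE)
    # stage 1: local re-thresholding inside uncovered skeleton regions
    for (pass in 1:6) {
      unc <- !covered_by_balls(sk, pos, dfk)
      if (!any(unc)) break
      gm <- matrix(FALSE, nrow(f), ncol(f))
      gm[sk[unc, , drop = FALSE]] <- TRUE
      gm_d <- as_mat(EBImage::dilate(EBImage::Image(gm * 1),
                                     EBImage::makeBrush(3, "box"))) > 0
      lab <- as_mat(EBImage::bwlabel(EBImage::Image(gm_d * 1)))
      lab[!gm] <- 0L
      added <- 0L
      for (g in sort(unique(lab[lab > 0]))) {
        gp <- which(lab == g, arr.ind = TRUE)
        y0 <- max(1, min(gp[, 1]) - 6); y1 <- min(nrow(f), max(gp[, 1]) + 6)
        x0 <- max(1, min(gp[, 2]) - 6); x1 <- min(ncol(f), max(gp[, 2]) + 6)
        sub_f <- f[y0:y1, x0:x1]
        sub_r <- resp[y0:y1, x0:x1]
        srf <- sub_r[sub_f]
        if (!length(srf)) next
        srng <- range(srf)
        sub_n <- matrix(0, nrow(sub_f), ncol(sub_f))
        sub_n[sub_f] <- if (diff(srng) > 0) (srf - srng[1]) / diff(srng) else 1
        nc <- which(sub_f & sub_n >= cfg$seed_threshold, arr.ind = TRUE)
        if (nrow(nc) == 0) next
        nc[, 1] <- nc[, 1] + y0 - 1; nc[, 2] <- nc[, 2] + x0 - 1
        # drop candidates already inside an existing seed's ball
        inball <- covered_by_balls(nc, pos, dfk)
        nc <- nc[!inball, , drop = FALSE]
        if (nrow(nc) == 0) next
        ki <- suppress_seeds(nc, Df[nc], centre = centre)
        pos <- rbind(pos, nc[ki, , drop = FALSE])
        dfk <- c(dfk, Df[nc[ki, , drop = FALSE]])
        added <- added + length(ki)
      }
      if (added == 0L) {
        # fallback: promote the deepest uncovered skeleton pixel per region
        gp_all <- sk[unc, , drop = FALSE]
        best <- which.max(Df[gp_all])
        pos <- rbind(pos, gp_all[best, , drop = FALSE])
        dfk <- c(dfk, Df[gp_all[best, , drop = FALSE]])
      }
    }
    # stage 2: enforce intersecting balls between consecutive seeds along
    # skeleton paths (label skeleton pixels by nearest seed; adjacent pixels
    # with different labels define consecutive pairs)
    for (pass in 1:60) {
      lab_sk <- nearest_seed(sk, pos)
      viol <- NULL
      off <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
      skm <- matrix(0L, nrow(f), ncol(f))
      skm[sk] <- seq_len(nrow(sk))
      for (o in seq_len(nrow(off))) {
        a <- sk
        b <- cbind(sk[, 1] + off[o, 1], sk[, 2] + off[o, 2])
        ok <- b[, 1] >= 1 & b[, 1] <= nrow(f) & b[, 2] >= 1 & b[, 2] <= ncol(f)
        bi <- rep(0L, nrow(sk)); bi[ok] <- skm[b[ok, , drop = FALSE]]
        sel <- which(bi > 0)
        la <- lab_sk[sel]; lb <- lab_sk[bi[sel]]
        diffpair <- sel[la != lb]
        if (length(diffpair)) {
          s1 <- lab_sk[diffpair]; s2 <- lab_sk[bi[diffpair]]
          dd <- sqrt((pos[s1, 1] - pos[s2, 1])^2 + (pos[s1, 2] - pos[s2, 2])^2)
          bad <- dd > dfk[s1] + dfk[s2]
          if (any(bad)) viol <- rbind(viol, cbind(diffpair[bad], bi[diffpair][bad]))
        }
      }
      if (is.null(viol)) break
      newp <- unique(rbind(sk[viol[, 1], , drop = FALSE],
                           sk[viol[, 2], , drop = FALSE]))
      dup <- covered_by_balls(newp, pos, rep(0.01, nrow(pos)))
      newp <- newp[!dup, , drop = FALSE]
      if (nrow(newp) == 0) break
      pos <- rbind(pos, newp)
      dfk <- c(dfk, Df[newp])
    }
  }
  out <- data.frame(y = as.numeric(pos[, 1]), x = as.numeric(pos[, 2]),
                    df = as.numeric(dfk))
  out <- out[order(out$y, out$x), ]
  rownames(out) <- NULL
  class(out) <- c("seed_set", "data.frame")
  out
}

# Mutable seed store used during tracing.
seed_env <- function(seeds) {
  e <- new.env(parent = emptyenv())
  e$pos <- cbind(seeds$y, seeds$x)
  e$df <- seeds$df
  e$alive <- rep(TRUE, nrow(e$pos))
  e$owner <- rep(0L, nrow(e$pos))
  e
}

wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

# Distance from each row of pts to the segment [a, b]. Points whose
# projection falls beyond b (ahead of the segment) are reported as Inf when
# `forward_open` is set, so corridor cleanup never consumes seeds lying
# ahead of the accepted one.
point_segment_dist <- function(pts, a, b, forward_open = FALSE) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-12) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t_raw <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t_par <- pmin(pmax(t_raw, 0), 1)
  d <- sqrt((pts[, 1] - (a[1] + t_par * ab[1]))^2 +
              (pts[, 2] - (a[2] + t_par * ab[2]))^2)
  if (forward_open) d[t_raw > 1] <- Inf
  d
}

#' Search for the next seed in an orientation-constrained fan
#'
#' Round `r` (r = 0, ..., max_rounds - 1) uses rectangles of length
#' `L0 + L_step * r`. Within a round the axis-aligned rectangle is tested
#' first; if empty, pairs of rectangles at angular offsets `+-m * fan_step`
#' (each slightly shorter than the last) are tested until the offset exceeds
#' `fan_max`. The first window containing alive seeds returns its best seed
#' (minimal distance, then minimal angular deviation, then lowest index).
#' If all rounds fail the neurite is considered completely traced.
#'
#' @param current numeric `(y, x)` of the current trace point.
#' @param theta expected neurite orientation (radians).
#' @param seeds a seed store created by [seed_env()] from a `seed_set`, or a
#'   `seed_set` data.frame (searched read-only).
#' @param cfg a [trace_config()].
#' @param df_current local clearance radius at the current point; sets the
#'   rectangle width `max(width_min, 2 * df_current)`.
#' @param collect also report all alive seeds in the winning round's off-axis
#'   fan, clustered into angular sub-fans (used for branch spawning).
#' @param f optional segmentation foreground; when given, a seed is only
#'   eligible if at least `min_path_fg` of the straight segment from the
#'   current point to it lies on the foreground.
#' @return `NULL` if no seed is found, else a list with `idx`, `round`,
#'   `deviation` and (if `collect`) `branches` — one representative seed per
#'   additional angular sub-fan.
#' @export
next_seed_search <- function(current, theta, seeds, cfg = trace_config(),
                             df_current = 1.5, collect = FALSE, f = NULL) {
  if (is.data.frame(seeds)) seeds <- seed_env(seeds)
  width <- max(cfg$width_min, 2 * df_current)
  L_last <- cfg$L0 + cfg$L_step * (cfg$max_rounds - 1)
  idx <- which(seeds$alive)
  if (!length(idx)) return(NULL)
  dy <- seeds$pos[idx, 1] - current[1]
  dx <- seeds$pos[idx, 2] - current[2]
  d <- sqrt(dy^2 + dx^2)
  near <- d <= (L_last + width) & d > 1e-9
  idx <- idx[near]; dy <- dy[near]; dx <- dx[near]; d <- d[near]
  if (!length(idx)) return(NULL)
  dev <- wrap_angle(atan2(dy, dx) - theta)
  m_max <- floor(cfg$fan_max / cfg$fan_step + 1e-9)

  path_cache <- rep(NA, length(idx))
  path_pass <- function(sel) {
    if (is.null(f)) return(sel)
    for (j in sel) {
      if (is.na(path_cache[j])) {
        q <- seeds$pos[idx[j], ]
        n <- max(2L, ceiling(d[j]))
        t_seq <- seq(0, 1, length.out = n + 1)
        yy <- pmin(pmax(round(current[1] + t_seq * (q[1] - current[1])), 1), nrow(f))
        xx <- pmin(pmax(round(current[2] + t_seq * (q[2] - current[2])), 1), ncol(f))
        path_cache[j] <<- mean(f[cbind(yy, xx)]) >= cfg$min_path_fg
      }
    }
    sel[path_cache[sel] > 0]
  }

  # rectangle test plus a sector cap: a window at angular offset phi only
  # accepts seeds deviating at most |phi| + fan_step from the expected
  # orientation, so the swept windows form an approximately circular sector
  # and a wide rectangle cannot capture seeds of a transversal neurite.
  in_window <- function(phi, len) {
    u <- d * cos(dev - phi)
    v <- d * sin(dev - phi)
    u > 1e-9 & u <= len & abs(v) <= width / 2 &
      abs(dev) <= min(abs(phi) + cfg$fan_step, cfg$fan_max)
  }
  best_of <- function(sel) {
    o <- order(d[sel], abs(dev[sel]), idx[sel])
    sel[o[1]]
  }

  for (r in seq_len(cfg$max_rounds) - 1L) {
    L <- cfg$L0 + cfg$L_step * r
    ax <- path_pass(which(in_window(0, L)))
    if (length(ax)) {
      b <- best_of(ax)
      return(list(idx = idx[b], round = r, deviation = dev[b],
                  branches = list()))
    }
    hits <- integer(0)
    first_hits <- integer(0)
    win_m <- 1L
    while (win_m <= m_max) {
      len_m <- L * cfg$length_decay^win_m
      phi <- win_m * cfg$fan_step
      sel <- path_pass(which(in_window(phi, len_m) | in_window(-phi, len_m)))
      if (length(sel)) {
        hits <- union(hits, sel)
        if (!length(first_hits)) first_hits <- sel
        if (!collect) break
      }
      win_m <- win_m + 1L
    }
    if (length(hits)) {
      b <- best_of(first_hits)
      res <- list(idx = idx[b], round = r, deviation = dev[b],
                  branches = list())
      if (collect && length(hits) > 1) {
        o <- order(dev[hits])
        hh <- hits[o]
        cl <- cumsum(c(1, diff(dev[hh]) > cfg$fan_step))
        main_cl <- cl[which(hh == b)]
        for (g in setdiff(unique(cl), main_cl)) {
          sel <- hh[cl == g]
          rep_b <- best_of(sel)
          if (abs(dev[rep_b]) <= cfg$branch_max_dev)
            res$branches <- c(res$branches, list(idx[rep_b]))
        }
      }
      return(res)
    }
  }
  NULL
}

#' Initialize neurite starts around a soma
#'
#' The soma mask is scaled about its centroid by the three dilation rates;
#' the symmetric differences S1 xor S0 and S3 xor S2 are intersected with
#' the segmented structures (soma regions excluded), yielding for each
#' neurite a short segment in each ring. Ring-component centroids are paired
#' by mutual nearest neighbours; the inner-to-outer direction gives the
#' initial orientation and the nearest soma-boundary pixel to the inner
#' centroid gives the start point. Unpaired components are discarded with a
#' message.
#'
#' @param soma a `soma_region`.
#' @param f segmentation foreground; the soma mask must lie inside it.
#' @param cfg a [trace_config()].
#' @param exclude optional logical matrix of pixels to remove from the rings
#'   (typically the union of all soma masks).
#' @return List of `neurite_start` (`soma_id`, `point`, `theta0`).
#' @export
initialize_neurites <- function(soma, f, cfg = trace_config(), exclude = NULL) {
  f <- as_mat(f) > 0
  S0 <- soma$mask
  if (any(S0 & !f)) stop("soma mask is not contained in the segmentation foreground")
  ctr <- soma$centroid
  # relative dilation rates give rings proportional to soma size; for small
  # somas enforce a minimum ring thickness of 1.5 px so the rasterized
  # rings stay connected bands
  r_eq <- sqrt(soma$area / pi)
  rates <- pmax(cfg$dilation_rates, 1 + seq_along(cfg$dilation_rates) * 1.5 / r_eq)
  scl <- function(rate) scale_mask(S0, ctr, rate)
  S1 <- scl(rates[1]); S2 <- scl(rates[2])
  S3 <- scl(rates[3])
  fg <- f
  fg[S0] <- FALSE
  if (!is.null(exclude)) fg[as_mat(exclude) > 0] <- FALSE
  ring1 <- xor(S1, S0) & fg
  ring2 <- xor(S3, S2) & fg
  comp_centroids <- function(ring) {
    if (!any(ring)) return(matrix(numeric(0), 0, 2))
    lab <- as_mat(EBImage::bwlabel(EBImage::Image(ring * 1)))
    sz <- tabulate(lab[lab > 0])
    lab[lab %in% which(sz < 2)] <- 0L
    label_centroids(lab)
  }
  cin <- comp_centroids(ring1)
  cout <- comp_centroids(ring2)
  if (nrow(cin) == 0 || nrow(cout) == 0) return(list())
  d2 <- outer(cin[, 1], cout[, 1], "-")^2 + outer(cin[, 2], cout[, 2], "-")^2
  ni <- apply(d2, 1, which.min)   # nearest outer for each inner
  no <- apply(d2, 2, which.min)   # nearest inner for each outer
  max_pair <- max(8, 0.8 * r_eq)
  bnd <- which(mask_boundary(S0), arr.ind = TRUE)
  starts <- list()
  for (i in seq_len(nrow(cin))) {
    j <- ni[i]
    radial <- atan2(cin[i, 1] - ctr[1], cin[i, 2] - ctr[2])
    th <- NA_real_
    if (no[j] == i && sqrt(d2[i, j]) <= max_pair) {
      th <- atan2(cout[j, 1] - cin[i, 1], cout[j, 2] - cin[i, 2])
    }
    if (is.na(th) || abs(wrap_angle(th - radial)) > pi / 3) {
      # outer partner missing, contested, or pointing away from the
      # emanating direction (e.g. a neurite of another neuron passing
      # through the rings): use the radial direction. Genuine neurites
      # emanate roughly radially, so this recovers them, while ring
      # segments of tangentially passing neurites produce no trace.
      message("initialize_neurites: ring pairing unreliable, using radial direction")
      th <- radial
    }
    bi <- which.min((bnd[, 1] - cin[i, 1])^2 + (bnd[, 2] - cin[i, 2])^2)
    starts[[length(starts) + 1]] <-
      structure(list(soma_id = soma$id,
                     point = c(bnd[bi, 1], bnd[bi, 2]), theta0 = th),
                class = "neurite_start")
  }
  ord <- order(vapply(starts, function(s) s$theta0 %% (2 * pi), numeric(1)))
  starts[ord]
}

# Geometric scaling of a binary mask about a centre point by factor `rate`
# (inverse mapping with nearest-neighbour lookup).
scale_mask <- function(mask, centre, rate) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) return(mask & FALSE)
  ry <- range(w[, 1]); rx <- range(w[, 2])
  pad <- ceiling(max(ry[2] - centre[1], centre[1] - ry[1],
                     rx[2] - centre[2], centre[2] - rx[1]) * rate) + 2
  ys <- max(1, floor(centre[1] - pad)):min(nrow(mask), ceiling(centre[1] + pad))
  xs <- max(1, floor(centre[2] - pad)):min(ncol(mask), ceiling(centre[2] + pad))
  gy <- rep(ys, times = length(xs))
  gx <- rep(xs, each = length(ys))
  sy <- round(centre[1] + (gy - centre[1]) / rate)
  sx <- round(centre[2] + (gx - centre[2]) / rate)
  ok <- sy >= 1 & sy <= nrow(mask) & sx >= 1 & sx <= ncol(mask)
  inside <- logical(length(gy))
  inside[ok] <- mask[cbind(sy[ok], sx[ok])]
  out <- mask & FALSE
  out[cbind(gy[inside], gx[inside])] <- TRUE
  out
}

#' Trace a single neurite from its start
#'
#' Repeatedly applies [next_seed_search()]: the expected orientation is the
#' initial orientation for the first step and afterwards the direction of
#' the two preceding trace nodes. Accepted seeds are marked consumed and
#' connected by straight segments; tracing stops when the fan search fails.
#'
#' @param start a `neurite_start` (or list with `point`, `theta0`).
#' @param seeds a mutable seed store ([seed_env()]) or `seed_set`.
#' @param cfg a [trace_config()].
#' @param owner integer id recorded on consumed seeds.
#' @param f optional segmentation foreground for the connecting-segment
#'   check (see [next_seed_search()]).
#' @return List with `nodes` (matrix y, x, arclength, radius, seed) and
#'   `branches` (list of spawn requests: `parent_node`, `seed`, `theta`).
#' @export
trace_neurite <- function(start, seeds, cfg = trace_config(), owner = 1L,
                          f = NULL) {
  if (is.data.frame(seeds)) seeds <- seed_env(seeds)
  cur <- start$point
  theta <- start$theta0
  nodes <- matrix(c(cur, 0, 1.5, NA), 1, 5,
                  dimnames = list(NULL, c("y", "x", "arclength", "radius", "seed")))
  branches <- list()
  df_cur <- 1.5
  repeat {
    res <- next_seed_search(cur, theta, seeds, cfg, df_current = df_cur,
                            collect = cfg$branching, f = f)
    if (is.null(res)) break
    i <- res$idx
    seeds$alive[i] <- FALSE
    seeds$owner[i] <- owner
    p <- seeds$pos[i, ]
    step <- sqrt(sum((p - cur)^2))
    nodes <- rbind(nodes, c(p, nodes[nrow(nodes), "arclength"] + step,
                            seeds$df[i], i))
    # consume redundant seeds in a narrow corridor along the accepted
    # segment (near-duplicates from local gap repair), so a later trace
    # cannot ride the same centerline
    live <- which(seeds$alive)
    if (length(live)) {
      seg_d <- point_segment_dist(seeds$pos[live, , drop = FALSE], cur, p,
                                  forward_open = TRUE)
      kill <- live[seg_d <= 3]
      if (length(kill)) {
        seeds$alive[kill] <- FALSE
        seeds$owner[kill] <- owner
      }
    }
    for (b in res$branches) {
      # a branch seed whose clearance ball still intersects the continuing
      # seed's ball lies in the same merged blob (junction), not on a
      # separated arm of a bifurcation
      d_mb <- sqrt(sum((seeds$pos[b, ] - seeds$pos[i, ])^2))
      if (d_mb <= seeds$df[b] + seeds$df[i]) next
      if (!branch_back_clear(cur, seeds$pos[b, ], seeds, nodes, cfg)) next
      seeds$alive[b] <- FALSE
      seeds$owner[b] <- owner
      branches[[length(branches) + 1]] <-
        list(parent_node = nrow(nodes) - 1L, seed = b,
             theta = atan2(seeds$pos[b, 1] - cur[1], seeds$pos[b, 2] - cur[2]))
    }
    theta_est <- lagged_heading(nodes, cfg$heading_lag, start$theta0)
    theta <- theta + max(min(wrap_angle(theta_est - theta), cfg$max_turn),
                         -cfg$max_turn)
    cur <- p
    df_cur <- seeds$df[i]
  }
  list(nodes = nodes, branches = branches)
}

# Transversality guard for branch spawning: a genuine bifurcation has no
# seeds along the back-extension of the branch direction, whereas a neurite
# that merely crosses here continues behind the junction. Seeds (alive or
# already consumed) in a narrow rectangle opposite the branch direction —
# excluding those belonging to the current trace — veto the spawn.
branch_back_clear <- function(cur, branch_pos, seeds, nodes, cfg) {
  th_b <- atan2(branch_pos[1] - cur[1], branch_pos[2] - cur[2])
  back <- th_b + pi
  dy <- seeds$pos[, 1] - cur[1]
  dx <- seeds$pos[, 2] - cur[2]
  d <- sqrt(dy^2 + dx^2)
  dev <- wrap_angle(atan2(dy, dx) - back)
  u <- d * cos(dev)
  v <- d * sin(dev)
  cand <- which(u >= 2 & u <= cfg$L0 + 4 & abs(v) <= 2.5 & abs(dev) <= pi / 6)
  if (!length(cand)) return(TRUE)
  own <- min_dist_to_set(seeds$pos[cand, , drop = FALSE],
                         nodes[, 1:2, drop = FALSE])
  !any(own > 3)
}

# Expected orientation from the trailing `lag` px of the trace: the
# principal axis (total least squares) of the trace nodes in that window,
# oriented from older to newer. At typical seed spacing this reduces to the
# two-preceding-seeds direction; where seeds are dense or displaced
# sideways by merged structures (junction blobs) the fit averages the
# displacement out instead of letting one seed corrupt the heading.
lagged_heading <- function(nodes, lag, theta0) {
  k <- nrow(nodes)
  if (k < 2) return(theta0)
  s_cur <- nodes[k, "arclength"]
  sel <- which(nodes[, "arclength"] >= s_cur - lag)
  if (length(sel) < 2) sel <- c(k - 1L, k)
  P <- nodes[sel, c("y", "x"), drop = FALSE]
  if (nrow(P) == 2)
    return(atan2(P[2, 1] - P[1, 1], P[2, 2] - P[1, 2]))
  Pc <- sweep(P, 2, colMeans(P))
  v <- eigen(crossprod(Pc), symmetric = TRUE)$vectors[, 1]
  span <- P[nrow(P), ] - P[1, ]
  if (sum(v * span) < 0) v <- -v
  atan2(v[1], v[2])
}

#' Extract one directed rooted tree per soma
#'
#' Somas are processed in descending area order. For each soma, neurite
#' starts are initialized from the dilation rings, each start is traced by
#' the fan search, and branch spawns (disjoint angular sub-fans with an
#' empty axis window) are traced as child neurites rooted at their parent
#' node. Seeds consumed by one neuron stay dead for later neurons, which is
#' what resolves apparent crossings: the later trace skips the shared
#' junction and continues on its own side. Seeds claimed within
#' `conflict_dist` of a previously extracted tree are recorded in the
#' per-tree conflict log.
#'
#' @param somas list of `soma_region`.
#' @param f segmentation foreground.
#' @param seeds optional precomputed `seed_set`; computed from `f` if NULL.
#' @param cfg a [trace_config()].
#' @return List of `neuron_tree`: `id`, `soma`, `neurites` (each with
#'   `nodes`, `parent`, `label`), `conflicts` count.
#' @export
extract_trees <- function(somas, f, seeds = NULL, cfg = trace_config()) {
  if (length(somas) == 0) stop("no somas: nothing to trace")
  f <- as_mat(f) > 0
  if (is.null(seeds)) seeds <- compute_seeds(f, cfg)
  env <- seed_env(seeds)
  soma_union <- matrix(FALSE, nrow(f), ncol(f))
  for (s in somas) soma_union <- soma_union | s$mask
  if (nrow(env$pos)) {
    inside <- soma_union[env$pos]
    env$alive[inside] <- FALSE
  }
  prev_nodes <- matrix(numeric(0), 0, 2)
  trees <- list()
  ord <- order(-vapply(somas, function(s) as.numeric(s$area), numeric(1)))
  for (s in somas[ord]) {
    starts <- initialize_neurites(s, f, cfg, exclude = soma_union)
    neurites <- list()
    jobs <- lapply(starts, function(st)
      list(start = st, parent = NULL, arclen0 = 0, first_seed = NULL))
    conflicts <- 0L
    qi <- 1
    while (qi <= length(jobs)) {
      job <- jobs[[qi]]; qi <- qi + 1
      if (!is.null(job$first_seed)) {
        # branch job: first node is the already-claimed seed
        i <- job$first_seed
        p <- env$pos[i, ]
        st <- list(point = p, theta0 = job$theta)
        tr <- trace_neurite(st, env, cfg, owner = s$id, f = f)
        tr$nodes[1, "arclength"] <- 0
        tr$nodes[1, "radius"] <- env$df[i]
        tr$nodes[1, "seed"] <- i
        tr$nodes[, "arclength"] <- tr$nodes[, "arclength"] + job$arclen0
      } else {
        tr <- trace_neurite(job$start, env, cfg, owner = s$id, f = f)
        tr$nodes[, "arclength"] <- tr$nodes[, "arclength"] + job$arclen0
      }
      ni <- length(neurites) + 1L
      neurites[[ni]] <- list(nodes = tr$nodes, parent = job$parent,
                             label = "unassigned")
      if (nrow(prev_nodes) && nrow(tr$nodes) > 1) {
        nd <- min_dist_to_set(tr$nodes[-1, 1:2, drop = FALSE], prev_nodes)
        conflicts <- conflicts + sum(nd < cfg$conflict_dist)
      }
      for (b in tr$branches) {
        jobs[[length(jobs) + 1]] <-
          list(start = NULL, parent = c(ni, b$parent_node),
               arclen0 = tr$nodes[b$parent_node, "arclength"] +
                 sqrt(sum((env$pos[b$seed, ] - tr$nodes[b$parent_node, 1:2])^2)),
               first_seed = b$seed, theta = b$theta)
      }
    }
    tree <- structure(list(id = s$id, soma = s, neurites = neurites,
                           conflicts = conflicts), class = "neuron_tree")
    validate_tree(tree)
    trees[[length(trees) + 1]] <- tree
    for (nn in neurites) prev_nodes <- rbind(prev_nodes, nn$nodes[, 1:2, drop = FALSE])
  }
  trees[order(vapply(trees, function(t) as.numeric(t$id), numeric(1)))]
}

#' Partition somas of a large image into rectangular tiles
#'
#' Somas are grouped by single-linkage clustering of their centroids with a
#' distance cutoff; each group gets a rectangle that fully contains its soma
#' masks plus a margin (clipped to the image). A soma whose mask overlaps a
#' rectangle's boundary belongs to no subset of that rectangle; every soma
#' appears in exactly one tile.
#'
#' @param somas list of `soma_region`.
#' @param shape image dimensions `c(ny, nx)`.
#' @param max_tile maximum tile side (px); a soma larger than this errors.
#' @param margin padding around each group's bounding box (px); should cover
#'   the expected neurite extent.
#' @param cutoff single-linkage distance cutoff (px).
#' @return List of tiles: `rect = c(y0, y1, x0, x1)`, `soma_ids`.
#' @export
tile_large_image <- function(somas, shape, max_tile = 1024, margin = 200,
                             cutoff = 100) {
  stopifnot(length(somas) >= 1)
  ctr <- t(vapply(somas, function(s) s$centroid, numeric(2)))
  for (s in somas) {
    w <- which(s$mask, arr.ind = TRUE)
    if (diff(range(w[, 1])) + 1 > max_tile || diff(range(w[, 2])) + 1 > max_tile)
      stop("soma ", s$id, " larger than max_tile")
  }
  grp <- if (nrow(ctr) == 1) 1L else
    cutree(hclust(dist(ctr), method = "single"), h = cutoff)
  tiles <- list()
  for (g in sort(unique(grp))) {
    ids <- which(grp == g)
    y0 <- Inf; y1 <- -Inf; x0 <- Inf; x1 <- -Inf
    for (i in ids) {
      w <- which(somas[[i]]$mask, arr.ind = TRUE)
      y0 <- min(y0, min(w[, 1])); y1 <- max(y1, max(w[, 1]))
      x0 <- min(x0, min(w[, 2])); x1 <- max(x1, max(w[, 2]))
    }
    rect <- c(max(1, y0 - margin), min(shape[1], y1 + margin),
              max(1, x0 - margin), min(shape[2], x1 + margin))
    tiles[[length(tiles) + 1]] <-
      list(rect = rect, soma_ids = vapply(somas[ids], function(s) as.integer(s$id), integer(1)))
  }
  tiles
}
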