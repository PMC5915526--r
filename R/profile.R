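#' Sample a background-corrected intensity profile along a neurite
#'
#' The traced polyline is resampled at a uniform arclength step; the raw
#' value at each sample is the bilinear interpolation of the image. The
#' local background is the mean over a pair of 3x3 windows centred on the
#' perpendicular to the local trace direction, placed just beyond the local
#' structure edge on each side (an `offset`-px gap between edge and window).
#' Windows overlapping segmented structures are pushed outward until clear;
#' if one side cannot be cleared within `max_push` px the other side alone
#' is used, and if neither can, the global robust background (median of
#' background pixels) is used. Corrected = raw - background, not clamped.
#'
#' @param img an [image2d()] or matrix (the channel to profile).
#' @param f segmentation foreground used to locate structure edges.
#' @param nodes neurite node matrix with columns `y`, `x` (and optionally
#'   `arclength`), ordered from the soma.
#' @param step sampling step (px).
#' @param neuron_id,neurite_id identifiers carried into the output.
#' @param window background window side (px, odd).
#' @param offset gap between the structure edge and the window (px).
#' @param max_push maximum outward push of a blocked window (px).
#' @return An `intensity_profile`: arrays `arclength_px`, `arclength_um`,
#'   `raw`, `background`, `corrected`.
#' @export
sample_profile <- function(img, f, nodes, step = 1, neuron_id = 1L,
                           neurite_id = 1L, window = 3, offset = 2,
                           max_push = 15) {
  m <- if (inherits(img, "image2d")) img$pixels else img
  px <- if (inherits(img, "image2d")) img$pixel_size else 0.28
  f <- as_mat(f) > 0
  stopifnot(step > 0)
  pts <- nodes[, c("y", "x"), drop = FALSE]
  rs <- polyline_resample(pts, step)
  n <- nrow(rs$pts)
  raw <- bilinear(m, rs$pts[, 1], rs$pts[, 2])
  glob_bg <- if (any(!f)) median(m[!f]) else 0
  hw <- (window - 1) / 2
  woff <- as.matrix(expand.grid(dy = -hw:hw, dx = -hw:hw))
  bg <- numeric(n)
  for (i in seq_len(n)) {
    p <- rs$pts[i, ]
    i0 <- max(1, i - 1); i1 <- min(n, i + 1)
    tg <- rs$pts[i1, ] - rs$pts[i0, ]
    tl <- sqrt(sum(tg^2))
    if (tl < 1e-9) tg <- c(0, 1) else tg <- tg / tl
    nrm <- c(-tg[2], tg[1])
    vals <- c()
    for (sgn in c(1, -1)) {
      v <- window_background(m, f, p, sgn * nrm, offset, hw, woff, max_push)
      if (!is.na(v)) vals <- c(vals, v)
    }
    bg[i] <- if (length(vals)) mean(vals) else glob_bg
  }
  structure(list(neuron_id = neuron_id, neurite_id = neurite_id,
                 arclength_px = rs$s, arclength_um = rs$s * px,
                 raw = raw, background = bg, corrected = raw - bg),
            class = "intensity_profile")
}

# Mean of one 3x3 background window on one side of the trace, or NA.
window_background <- function(m, f, p, nrm, offset, hw, woff, max_push) {
  # walk to the structure edge along the normal
  t_edge <- 0
  for (t in seq(0.5, max_push + 5, by = 0.5)) {
    q <- p + t * nrm
    if (q[1] < 1 || q[1] > nrow(m) || q[2] < 1 || q[2] > ncol(m)) return(NA_real_)
    if (!f[round(q[1]), round(q[2])]) { t_edge <- t; break }
  }
  if (t_edge == 0) return(NA_real_)
  for (push in 0:max_push) {
    ctr <- p + (t_edge + offset + hw + push) * nrm
    yy <- round(ctr[1]) + woff[, 1]
    xx <- round(ctr[2]) + woff[, 2]
    if (any(yy < 1 | yy > nrow(m) | xx < 1 | xx > ncol(m))) return(NA_real_)
    idx <- cbind(yy, xx)
    if (!any(f[idx])) return(mean(m[idx]))
  }
  NA_real_
}

#' AIS heterogeneity and polarity metrics
#'
#' Over the axon-initial-segment interval (70 px from the soma by default,
#' 19.6 um at 0.28 um/px): the area `A_AIS` under the corrected axon
#' profile (trapezoidal), its variance `V_AIS`, the least-squares Gaussian
#' bell fit `g(x) = H exp(-(x - mu)^2 / (2 sigma^2))`, the mean dendrite
#' area `A_den` over the same interval, and the polarity ratio
#' `R_AD = A_AIS / A_den`.
#'
#' @param profile_axon an `intensity_profile` of the axon.
#' @param profiles_dendrites list of two dendrite `intensity_profile`s.
#' @param interval_px AIS interval length (px).
#' @return An `ais_metrics` list: `A_AIS`, `V_AIS`, `H`, `mu`, `sigma`,
#'   `A_den`, `R_AD`, and flags `fit_ok`, `rad_defined`.
#' @export
ais_metrics <- function(profile_axon, profiles_dendrites, interval_px = 70) {
  clip <- function(p) {
    sel <- p$arclength_px <= interval_px + 1e-9
    list(x = p$arclength_px[sel], y = p$corrected[sel])
  }
  if (max(profile_axon$arclength_px) < interval_px)
    stop("axon profile shorter than the AIS interval")
  ax <- clip(profile_axon)
  A <- trapz(ax$x, ax$y)
  V <- var(ax$y)
  fit_ok <- TRUE
  H <- mu <- sigma <- NA_real_
  if (all(ax$y == 0)) {
    fit_ok <- FALSE
  } else {
    st <- list(H = max(ax$y), mu = ax$x[which.max(ax$y)], sigma = interval_px / 6)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ H * exp(-(x - mu)^2 / (2 * sigma^2)),
                        data = data.frame(x = ax$x, y = ax$y), start = st,
                        lower = c(H = -Inf, mu = -interval_px, sigma = 1),
                        upper = c(H = Inf, mu = 2 * interval_px, sigma = interval_px),
                        control = minpack.lm::nls.lm.control(ftol = 1e-12,
                                                             maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) fit_ok <- FALSE else {
      cf <- coef(fit)
      H <- unname(cf["H"]); mu <- unname(cf["mu"]); sigma <- unname(cf["sigma"])
    }
  }
  A_den <- NA_real_
  if (length(profiles_dendrites)) {
    dens <- vapply(profiles_dendrites, function(p) {
      d <- clip(p); trapz(d$x, d$y)
    }, numeric(1))
    A_den <- mean(dens)
  }
  rad_defined <- is.finite(A_den) && A_den > 0
  structure(list(A_AIS = A, V_AIS = V, H = H, mu = mu, sigma = sigma,
                 A_den = A_den, R_AD = if (rad_defined) A / A_den else NA_real_,
                 fit_ok = fit_ok, rad_defined = rad_defined),
            class = "ais_metrics")
}

#' Identify the axon among a neuron's profiles
#'
#' Default rule: the neurite with the highest mean corrected target-channel
#' intensity over its first `interval_px` of arclength (AIS markers such as
#' Nav channels are enriched there). Neurites shorter than the interval are
#' excluded; returns `NA` if none qualify (mirroring the exclusion of
#' neurons whose axon is not visible).
#'
#' @param profiles list of `intensity_profile` for one neuron.
#' @param interval_px AIS interval (px).
#' @return Index into `profiles`, or `NA_integer_`.
#' @export
identify_axon <- function(profiles, interval_px = 70) {
  if (!length(profiles)) return(NA_integer_)
  score <- vapply(profiles, function(p) {
    if (max(p$arclength_px) < interval_px) return(-Inf)
    mean(p$corrected[p$arclength_px <= interval_px])
  }, numeric(1))
  if (all(!is.finite(score))) return(NA_integer_)
  which.max(score)
}

#' Select the dendrite pair for the polarity ratio
#'
#' The two non-axon neurites whose mean radius is closest to the axon's
#' (comparable thickness), spanning at least the AIS interval.
#'
#' @param profiles list of `intensity_profile`.
#' @param radii mean radius per neurite (px), same length as `profiles`.
#' @param axon index of the axon profile.
#' @param interval_px AIS interval (px).
#' @return Integer indices (up to 2) of the chosen dendrites.
#' @export
select_dendrites <- function(profiles, radii, axon, interval_px = 70) {
  cand <- setdiff(seq_along(profiles), axon)
  cand <- cand[vapply(cand, function(i)
    max(profiles[[i]]$arclength_px) >= interval_px, logical(1))]
  if (!length(cand)) return(integer(0))
  cand[order(abs(radii[cand] - radii[axon]))][seq_len(min(2, length(cand)))]
}

#' Compare AIS metrics between two groups of neurons
#'
#' Two-tailed two-sample t-tests (equal variances) on each metric.
#'
#' @param metrics_a,metrics_b lists of `ais_metrics`, one per neuron.
#' @param metrics which fields to test.
#' @return data.frame with columns metric, t, df, p, mean_a, mean_b.
#' @export
compare_groups <- function(metrics_a, metrics_b,
                           metrics = c("A_AIS", "V_AIS", "H", "R_AD")) {
  if (length(metrics_a) < 2 || length(metrics_b) < 2)
    stop("need at least 2 neurons per group")
  rows <- lapply(metrics, function(mname) {
    a <- vapply(metrics_a, function(m) as.numeric(m[[mname]]), numeric(1))
    b <- vapply(metrics_b, function(m) as.numeric(m[[mname]]), numeric(1))
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    tt <- t.test(a, b, var.equal = TRUE)
    data.frame(metric = mname, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_a = mean(a), mean_b = mean(b))
  })
  do.call(rbind, rows)
}
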