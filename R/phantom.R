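#' Specification of a synthetic multi-neuron phantom
#'
#' The phantom emulates a maximum-intensity projection of a confocal image of
#' a sparse neuronal culture: somas are filled ellipses, neurites smooth
#' curves of finite width emanating radially from the soma boundary, with a
#' spatially varying background and optional Poisson (shot) noise. Forced
#' crossings place a straight neurite of a second neuron through a point of
#' an existing neurite at a controlled angle, reproducing the apparent
#' intersections created by z-projection.
#'
#' @param shape image size `c(ny, nx)` in pixels.
#' @param n_neurons total number of neurons (crossing neurons included).
#' @param soma_radius range (px) of the soma major semi-axis.
#' @param soma_aspect_max maximum ellipse aspect ratio (>= 1).
#' @param neurites_per_soma integer range of neurites per soma.
#' @param neurite_length range (px) of neurite arclength.
#' @param neurite_halfwidth range (px) of neurite half-width.
#' @param curvature_max maximum tangent-angle change per pixel (radians).
#' @param n_crossings number of forced crossings; each consumes one neuron
#'   of `n_neurons` as the dedicated crossing neuron.
#' @param crossing_angles range (radians, in (0, pi/2]) of crossing angles.
#' @param intensity range of per-neuron foreground intensity.
#' @param background constant background level.
#' @param background_gradient peak-to-peak amplitude of a linear background
#'   ramp added across the field.
#' @param poisson if `TRUE`, the rendered image is Poisson-sampled.
#' @param min_separation minimum distance between soma centres (px).
#' @param seed RNG seed; the phantom is bit-identical for a fixed seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(512, 512), n_neurons = 4,
                         soma_radius = c(9, 15), soma_aspect_max = 1.4,
                         neurites_per_soma = c(3, 3),
                         neurite_length = c(120, 220),
                         neurite_halfwidth = c(1.8, 2.8),
                         curvature_max = 0.03,
                         n_crossings = 0, crossing_angles = c(pi / 4, pi / 2),
                         intensity = c(150, 220), background = 15,
                         background_gradient = 8, poisson = TRUE,
                         min_separation = 90, seed = 1) {
  stopifnot(all(shape > 0), n_neurons >= 1, all(soma_radius > 0),
            soma_aspect_max >= 1, all(neurites_per_soma >= 0),
            all(neurite_length > 0), all(neurite_halfwidth > 0),
            curvature_max >= 0, n_crossings >= 0,
            all(crossing_angles > 0), all(crossing_angles <= pi / 2))
  if (n_crossings > 0 && n_neurons - n_crossings < 1)
    stop("need at least one host neuron besides the crossing neurons")
  structure(as.list(environment()), class = "phantom_spec")
}

# Uniform integer draw from an inclusive range (safe for degenerate ranges,
# unlike sample(n, 1)).
sample_range <- function(rng) {
  lo <- as.integer(rng[1]); hi <- as.integer(rng[2])
  if (hi <= lo) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# Point on the boundary of an ellipse (centre cy,cx; semi-axes a,b; axis
# orientation phi) along direction psi from the centre.
ellipse_boundary_point <- function(cy, cx, a, b, phi, psi) {
  t <- 1 / sqrt((cos(psi - phi) / a)^2 + (sin(psi - phi) / b)^2)
  c(cy + t * sin(psi), cx + t * cos(psi))
}

ellipse_mask <- function(shape, cy, cx, a, b, phi) {
  m <- matrix(FALSE, shape[1], shape[2])
  ri <- ceiling(a) + 1
  ys <- max(1, floor(cy - ri)):min(shape[1], ceiling(cy + ri))
  xs <- max(1, floor(cx - ri)):min(shape[2], ceiling(cx + ri))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- dy * sin(phi) + dx * cos(phi)
  v <- dy * cos(phi) - dx * sin(phi)
  m[ys, xs] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

# Random smooth centerline: unit steps, AR(1) heading increments bounded by
# curv_max, straight for the first `straight_until` px; stops at the border.
gen_centerline <- function(start, theta0, length_px, curv_max, shape,
                           straight_until = 0, border = 4) {
  n_max <- ceiling(length_px)
  pts <- matrix(NA_real_, n_max + 1, 2)
  pts[1, ] <- start
  theta <- theta0
  dth <- 0
  k <- 1
  while (k <= n_max) {
    if (k > straight_until) {
      dth <- 0.6 * dth + runif(1, -1, 1) * curv_max * 0.8
      dth <- max(min(dth, curv_max), -curv_max)
      theta <- theta + dth
    }
    p <- pts[k, ] + c(sin(theta), cos(theta))
    if (p[1] < border || p[1] > shape[1] - border ||
        p[2] < border || p[2] > shape[2] - border) break
    k <- k + 1
    pts[k, ] <- p
  }
  pts[seq_len(k), , drop = FALSE]
}

# Paint a tube of half-width hw around a (y,x) polyline into logical mask m.
draw_tube <- function(m, pts, hw) {
  fine <- polyline_resample(pts, 0.5)$pts
  ctr <- unique(round(fine))
  off <- disk_offsets(hw)
  yy <- rep(ctr[, 1], each = nrow(off)) + rep(off[, 1], nrow(ctr))
  xx <- rep(ctr[, 2], each = nrow(off)) + rep(off[, 2], nrow(ctr))
  keep <- yy >= 1 & yy <= nrow(m) & xx >= 1 & xx <= ncol(m)
  m[cbind(yy[keep], xx[keep])] <- TRUE
  m
}

#' Generate a synthetic multi-neuron image with exact ground truth
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{channels}{list with a `structural` [image_stack()] (one slice),
#'       Poisson-sampled if requested.}
#'     \item{truth}{a `ground_truth` list: per-neuron trees (soma geometry
#'       and true centerlines with arclength), `label` image (pixel to
#'       neuron id, first-come at overlaps), `soma_label` image, per-neuron
#'       binary masks, the noiseless intensity image, the background field,
#'       and a `crossings` data.frame (location, neurons, neurites,
#'       arclengths and angle of every forced crossing).}
#'   }
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  # a sampled host layout can make the crossing construction geometrically
  # infeasible; resample the whole layout a few times before giving up
  for (attempt in 1:6) {
    out <- tryCatch(generate_phantom_once(spec), error = function(e) e)
    if (!inherits(out, "error")) return(out)
  }
  stop(conditionMessage(out))
}

generate_phantom_once <- function(spec) {
  shape <- spec$shape
  n_host <- spec$n_neurons - spec$n_crossings
  margin <- max(spec$soma_radius) + 30

  # occupancy store: accepted centerline / soma-boundary points with their
  # clearance radii. New structures must keep clear of stored points except
  # inside explicit exemption disks (own soma, intended crossing site), so
  # the forced crossings are the only inter-neuron overlaps and the truth's
  # crossing table is exhaustive.
  occ_pts <- matrix(numeric(0), 0, 2)
  occ_clr <- numeric(0)
  occ_add <- function(pts, clr) {
    occ_pts <<- rbind(occ_pts, pts)
    occ_clr <<- c(occ_clr, rep(clr, length.out = nrow(pts)))
  }
  # index of the first point of `pts` conflicting with the store (0 = none)
  first_conflict <- function(pts, hw, exempt = NULL) {
    if (nrow(occ_pts) == 0 || nrow(pts) == 0) return(0L)
    margin_d <- occ_clr + hw + 3
    for (i0 in seq(1, nrow(pts), by = 500L)) {
      i1 <- min(i0 + 499L, nrow(pts))
      d2 <- outer(pts[i0:i1, 1], occ_pts[, 1], "-")^2 +
        outer(pts[i0:i1, 2], occ_pts[, 2], "-")^2
      hit <- d2 <= rep(margin_d^2, each = i1 - i0 + 1)
      bad <- which(rowSums(hit) > 0)
      for (b in bad) {
        p <- pts[i0 + b - 1L, ]
        ex <- FALSE
        if (!is.null(exempt)) for (e in exempt)
          if ((p[1] - e[1])^2 + (p[2] - e[2])^2 <= e[3]^2) { ex <- TRUE; break }
        if (!ex) return(i0 + b - 1L)
      }
    }
    0L
  }

  place_soma <- function(centers, a, fixed = NULL, sep = spec$min_separation) {
    for (try in 1:2000) {
      c_new <- if (!is.null(fixed)) fixed else
        c(runif(1, margin, shape[1] - margin), runif(1, margin, shape[2] - margin))
      ok <- TRUE
      if (nrow(centers) > 0) {
        d <- sqrt((centers[, 1] - c_new[1])^2 + (centers[, 2] - c_new[2])^2)
        ok <- all(d >= sep)
      }
      if (ok && nrow(occ_pts) > 0) {
        d <- sqrt((occ_pts[, 1] - c_new[1])^2 + (occ_pts[, 2] - c_new[2])^2)
        ok <- all(d >= occ_clr + a + 10)
      }
      if (ok) return(c_new)
      if (!is.null(fixed)) return(NULL)
    }
    stop("phantom spec infeasible: could not place somas without overlap")
  }

  # grow one neurite avoiding occupied space; returns NULL if infeasible
  grow_neurite <- function(bp, psi, hw, own_exempt, extra_exempt = NULL,
                           straight_until = 0, min_len = 30,
                           min_len_strict = NULL) {
    best <- NULL
    for (try in 1:15) {
      len <- runif(1, spec$neurite_length[1], spec$neurite_length[2])
      pts <- gen_centerline(bp, psi, len, spec$curvature_max, shape,
                            straight_until = straight_until)
      ci <- first_conflict(pts, hw, exempt = c(list(own_exempt), extra_exempt))
      if (ci == 0L) { best <- pts; break }
      if (ci > 8) {
        trunc <- pts[seq_len(max(2, ci - 6L)), , drop = FALSE]
        if (is.null(best) || nrow(trunc) > nrow(best)) best <- trunc
      }
    }
    if (is.null(best)) return(NULL)
    s <- polyline_arclength(best)
    need <- if (is.null(min_len_strict)) min_len else min_len_strict
    if (s[length(s)] < need) return(NULL)
    best
  }

  soma_boundary_pts <- function(ctr, a, b, phi) {
    psis <- seq(0, 2 * pi, length.out = max(16, ceiling(2 * pi * a)))
    t(vapply(psis, function(p) ellipse_boundary_point(ctr[1], ctr[2], a, b, phi, p),
             numeric(2)))
  }

  neurons <- list()
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n_host)) {
    a <- runif(1, spec$soma_radius[1], spec$soma_radius[2])
    b <- a / runif(1, 1, spec$soma_aspect_max)
    phi <- runif(1, 0, pi)
    ctr <- place_soma(centers, a)
    centers <- rbind(centers, ctr)
    # soma boundaries carry a wide clearance so no foreign neurite passes or
    # terminates inside the initialization rings of another neuron — the
    # forced crossings are then the only inter-neuron interactions
    occ_add(soma_boundary_pts(ctr, a, b, phi), 6)
    k <- sample_range(spec$neurites_per_soma)
    base <- runif(1, 0, 2 * pi)
    angs <- if (k > 0) (base + 2 * pi * (0:(k - 1)) / k +
                          runif(k, -0.3, 0.3) * pi / max(k, 2)) %% (2 * pi) else numeric(0)
    own_ex <- c(ctr, a + max(spec$neurite_halfwidth) + 13)
    neurites <- list()
    for (psi in angs) {
      hw <- runif(1, spec$neurite_halfwidth[1], spec$neurite_halfwidth[2])
      pts <- NULL
      for (jit in 1:7) {
        psi_j <- psi + if (jit == 1) 0 else runif(1, -0.6, 0.6)
        bp <- ellipse_boundary_point(ctr[1], ctr[2], a, b, phi, psi_j)
        pts <- grow_neurite(bp, psi_j, hw, own_ex)
        if (!is.null(pts)) break
      }
      if (is.null(pts)) next
      occ_add(pts, hw)
      neurites[[length(neurites) + 1]] <-
        list(pts = pts, arclength = polyline_arclength(pts), halfwidth = hw)
    }
    neurons[[i]] <- list(id = i, soma = list(centroid = ctr, a = a, b = b, phi = phi),
                         neurites = neurites)
  }

  # Forced crossings: dedicated neurons whose first neurite runs straight
  # through a point of a host neurite at the sampled angle.
  crossings <- data.frame()
  host_pool <- which(vapply(neurons, function(n) length(n$neurites) > 0, TRUE))
  if (spec$n_crossings > 0 && length(host_pool) == 0)
    stop("phantom spec infeasible: crossings require host neurites")
  for (j in seq_len(spec$n_crossings)) {
    placed <- FALSE
    for (try in 1:400) {
      hi <- host_pool[((j + try - 2) %% length(host_pool)) + 1]
      host <- neurons[[hi]]
      if (!length(host$neurites)) next
      ni <- sample(seq_along(host$neurites), 1)
      nn <- host$neurites[[ni]]
      if (nrow(nn$pts) < 60) next
      s_total <- nn$arclength[length(nn$arclength)]
      s_at <- runif(1, 0.45, 0.7) * s_total
      ki <- which.min(abs(nn$arclength - s_at))
      if (ki < 3 || ki > nrow(nn$pts) - 2) next
      P <- nn$pts[ki, ]
      # crossings are pairwise by design: keep crossing sites apart so no
      # three neurites meet in one blob
      if (nrow(crossings) &&
          min((crossings$y - P[1])^2 + (crossings$x - P[2])^2) < 50^2) next
      tg <- nn$pts[ki + 1, ] - nn$pts[ki - 1, ]
      th_a <- atan2(tg[1], tg[2])
      gam <- runif(1, spec$crossing_angles[1], spec$crossing_angles[2])
      sgn <- sample(c(-1, 1), 1)
      th_b <- th_a + sgn * gam
      back <- runif(1, 55, 110)
      C <- P - back * c(sin(th_b), cos(th_b))
      if (C[1] < margin || C[1] > shape[1] - margin ||
          C[2] < margin || C[2] > shape[2] - margin) next
      a <- runif(1, spec$soma_radius[1], spec$soma_radius[2])
      b <- a / runif(1, 1, spec$soma_aspect_max)
      phi <- runif(1, 0, pi)
      sep_c <- if (try <= 200) spec$min_separation else 0.75 * spec$min_separation
      if (is.null(place_soma(centers, a, fixed = C, sep = sep_c))) next
      bp <- ellipse_boundary_point(C[1], C[2], a, b, phi, th_b)
      boundary_to_P <- sqrt(sum((P - bp)^2))
      hw <- runif(1, spec$neurite_halfwidth[1], spec$neurite_halfwidth[2])
      own_ex <- c(C, a + max(spec$neurite_halfwidth) + 13)
      # exemption around the crossing point: at angle gam the two tubes
      # stay within clearance of each other for ~clearance/sin(gam) px
      r_ex <- (hw + nn$halfwidth + 4) / max(sin(gam), 0.2) + 4
      cross_ex <- list(c(P, r_ex))
      pts <- grow_neurite(bp, th_b, hw, own_ex, extra_exempt = cross_ex,
                          straight_until = boundary_to_P + 12,
                          min_len_strict = boundary_to_P + 30)
      if (is.null(pts)) next
      occ_add(soma_boundary_pts(C, a, b, phi), 6)
      occ_add(pts, hw)
      k <- max(1L, sample_range(spec$neurites_per_soma))
      extra <- list()
      if (k > 1) {
        angs <- (th_b + seq(2 * pi / k, by = 2 * pi / k, length.out = k - 1) +
                   runif(k - 1, -0.2, 0.2)) %% (2 * pi)
        for (psi in angs) {
          bp2 <- ellipse_boundary_point(C[1], C[2], a, b, phi, psi)
          hw2 <- runif(1, spec$neurite_halfwidth[1], spec$neurite_halfwidth[2])
          p2 <- grow_neurite(bp2, psi, hw2, own_ex)
          if (is.null(p2)) next
          occ_add(p2, hw2)
          extra[[length(extra) + 1]] <-
            list(pts = p2, arclength = polyline_arclength(p2), halfwidth = hw2)
        }
      }
      id <- length(neurons) + 1L
      cross_neurite <- list(pts = pts, arclength = polyline_arclength(pts),
                            halfwidth = hw)
      neurons[[id]] <- list(id = id,
                            soma = list(centroid = C, a = a, b = b, phi = phi),
                            neurites = c(list(cross_neurite), extra))
      centers <- rbind(centers, C)
      crossings <- rbind(crossings, data.frame(
        y = P[1], x = P[2], angle = gam,
        neuron_a = hi, neurite_a = ni, s_a = nn$arclength[ki],
        neuron_b = id, neurite_b = 1L,
        s_b = boundary_to_P))
      placed <- TRUE
      break
    }
    if (!placed) stop("phantom spec infeasible: could not place crossing ", j)
  }

  # Render: per-neuron masks, label image (first-come), soma labels.
  label <- matrix(0L, shape[1], shape[2])
  soma_label <- matrix(0L, shape[1], shape[2])
  masks <- list()
  trees <- list()
  for (i in seq_along(neurons)) {
    nn <- neurons[[i]]
    m <- ellipse_mask(shape, nn$soma$centroid[1], nn$soma$centroid[2],
                      nn$soma$a, nn$soma$b, nn$soma$phi)
    soma_mask <- m
    for (ne in nn$neurites) m <- draw_tube(m, ne$pts, ne$halfwidth)
    masks[[i]] <- m
    label[m & label == 0L] <- i
    soma_label[soma_mask & soma_label == 0L] <- i
    trees[[i]] <- list(id = i,
                       soma = list(centroid = nn$soma$centroid,
                                   mask = soma_mask, area = sum(soma_mask),
                                   a = nn$soma$a, b = nn$soma$b,
                                   phi = nn$soma$phi),
                       neurites = nn$neurites)
  }

  intens <- runif(length(neurons), spec$intensity[1], spec$intensity[2])
  signal <- matrix(0, shape[1], shape[2])
  for (i in seq_along(masks)) signal[masks[[i]]] <- pmax(signal[masks[[i]]], intens[i])
  gx <- outer(rep(1, shape[1]), seq(0, 1, length.out = shape[2]))
  gy <- outer(seq(0, 1, length.out = shape[1]), rep(1, shape[2]))
  wdir <- runif(2)
  grad <- (wdir[1] * gx + wdir[2] * gy) / max(sum(wdir), 1e-9)
  bg <- spec$background + spec$background_gradient * grad
  noiseless <- signal + bg
  img <- if (spec$poisson) {
    matrix(stats::rpois(length(noiseless), noiseless), shape[1], shape[2])
  } else noiseless

  truth <- structure(list(trees = trees, label = label, soma_label = soma_label,
                          neuron_masks = masks, signal = signal,
                          background = bg, noiseless = noiseless,
                          intensity = intens, crossings = crossings,
                          spec = spec),
                     class = "ground_truth")
  list(channels = list(structural = image_stack(img, channel = "structural",
                                                pixel_size_xy = 0.28)),
       truth = truth)
}

#' Paint a Gaussian bell along one neurite's arclength
#'
#' Renders a target-channel image in which the centerline intensity of the
#' chosen neurite equals `g(s) = H exp(-(s - mu)^2 / (2 sigma^2))` at
#' arclength `s` from the soma; used to emulate an AIS-enriched marker
#' (e.g. Nav channels reported by a PanNav stain) with known parameters.
#'
#' @param truth a `ground_truth` from [generate_phantom()].
#' @param neuron,neurite indices of the neurite to paint.
#' @param H,mu,sigma Gaussian amplitude, centre (px arclength) and width (px).
#' @return An [image2d()]; all other pixels are 0.
#' @export
render_bell_signal <- function(truth, neuron, neurite, H, mu, sigma) {
  stopifnot(inherits(truth, "ground_truth"), sigma > 0)
  if (neuron < 1 || neuron > length(truth$trees))
    stop("unknown neuron id: ", neuron)
  tr <- truth$trees[[neuron]]
  if (neurite < 1 || neurite > length(tr$neurites))
    stop("unknown neurite id: ", neurite, " for neuron ", neuron)
  ne <- tr$neurites[[neurite]]
  shape <- dim(truth$label)
  out <- matrix(0, shape[1], shape[2])
  if (H == 0) return(image2d(out, channel = "target"))
  rs <- polyline_resample(ne$pts, 0.25)
  g <- H * exp(-(rs$s - mu)^2 / (2 * sigma^2))
  # each tube pixel takes the value of its nearest centerline sample, so
  # the along-arclength profile on (and near) the centerline equals g(s)
  off <- disk_offsets(ne$halfwidth)
  best <- matrix(Inf, shape[1], shape[2])
  for (k in seq_len(nrow(rs$pts))) {
    yy <- round(rs$pts[k, 1]) + off[, 1]
    xx <- round(rs$pts[k, 2]) + off[, 2]
    keep <- yy >= 1 & yy <= shape[1] & xx >= 1 & xx <= shape[2]
    idx <- cbind(yy[keep], xx[keep])
    d2 <- (idx[, 1] - rs$pts[k, 1])^2 + (idx[, 2] - rs$pts[k, 2])^2
    upd <- d2 < best[idx]
    if (any(upd)) {
      best[idx[upd, , drop = FALSE]] <- d2[upd]
      out[idx[upd, , drop = FALSE]] <- g[k]
    }
  }
  image2d(out, channel = "target")
}

#' Standard phantom suite
#'
#' Twelve seeded phantoms with 2-8 neurons per image, one or two forced
#' crossings at angles of at least 45 degrees, bright foreground over a
#' ramped background with Poisson noise — the fixed conditions used by the
#' package's own validation of seeding, tracing and crossing resolution.
#'
#' @param n_images number of phantoms.
#' @param seed base seed; image i uses `seed * 1000 + i`.
#' @param ... overrides passed to [phantom_spec()].
#' @return A list of `phantom_spec`.
#' @export
phantom_suite <- function(n_images = 12, seed = 1, ...) {
  n_neu <- rep(c(2:8, 3:7), length.out = n_images)
  lapply(seq_len(n_images), function(i) {
    nc <- if (n_neu[i] >= 4) 2L else 1L
    phantom_spec(n_neurons = n_neu[i], n_crossings = nc,
                 crossing_angles = c(pi / 4, pi / 2),
                 intensity = c(160, 220), background = 15,
                 background_gradient = 8, poisson = TRUE,
                 seed = seed * 1000 + i, ...)
  })
}
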