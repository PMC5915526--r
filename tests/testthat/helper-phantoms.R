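# Shared fixtures and cached heavy computations. The standard suite and the
# crossing-angle suite are traced once and reused across test files.

.nt_cache <- new.env(parent = emptyenv())

run_tracing_pipeline <- function(spec) {
  ph <- generate_phantom(spec)
  img <- project_mip(ph$channels$structural)
  mask <- segment_image(img)
  somas <- detect_somas(mask)
  seeds <- compute_seeds(mask)
  trees <- suppressMessages(extract_trees(somas, mask, seeds, trace_config()))
  list(ph = ph, img = img, mask = mask, somas = somas, seeds = seeds,
       trees = trees)
}

standard_suite_runs <- function() {
  if (is.null(.nt_cache$suite)) {
    specs <- phantom_suite(12, seed = 1)
    .nt_cache$suite <- lapply(specs, run_tracing_pipeline)
  }
  .nt_cache$suite
}

crossing_suite_runs <- function() {
  if (is.null(.nt_cache$angles)) {
    runs <- list()
    for (ang in c(45, 60, 90)) {
      for (i in 1:4) {
        a <- ang * pi / 180
        spec <- phantom_spec(n_neurons = 4, n_crossings = 2,
                             crossing_angles = c(a, a),
                             seed = 7000 + ang * 10 + i)
        runs[[length(runs) + 1]] <- run_tracing_pipeline(spec)
      }
    }
    .nt_cache$angles <- runs
  }
  .nt_cache$angles
}

# Convert ground-truth trees into the predicted-tree container so the
# evaluation can be exercised against a perfect reconstruction.
truth_as_trees <- function(truth) {
  lapply(truth$trees, function(tr) {
    soma <- structure(list(id = tr$id, mask = tr$soma$mask,
                           centroid = tr$soma$centroid, area = tr$soma$area),
                      class = "soma_region")
    neurites <- lapply(tr$neurites, function(nn) {
      nodes <- cbind(y = nn$pts[, 1], x = nn$pts[, 2],
                     arclength = nn$arclength,
                     radius = rep(nn$halfwidth, nrow(nn$pts)),
                     seed = rep(NA_real_, nrow(nn$pts)))
      list(nodes = nodes, parent = NULL, label = "unassigned")
    })
    structure(list(id = tr$id, soma = soma, neurites = neurites,
                   conflicts = 0L), class = "neuron_tree")
  })
}

# Filled disk mask helper.
disk_mask <- function(shape, cy, cx, r) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[(row(m) - cy)^2 + (col(m) - cx)^2 <= r^2] <- TRUE
  m
}

# Straight tube between two points.
tube_mask <- function(m, from, to, hw = 2) {
  n <- ceiling(sqrt(sum((to - from)^2)))
  pts <- cbind(seq(from[1], to[1], length.out = n),
               seq(from[2], to[2], length.out = n))
  neurotracer:::draw_tube(m, pts, hw)
}

rot90_mat <- neurotracer:::rot90_mat

pooled_match <- function(runs) {
  TP <- FP <- FN <- 0L
  solved <- 0; total <- 0
  for (r in runs) {
    m <- match_neurites(r$trees, r$ph$truth)
    TP <- TP + m$TP; FP <- FP + m$FP; FN <- FN + m$FN
    cr <- crossing_resolution_rate(r$trees, r$ph$truth, m)
    n_cr <- nrow(r$ph$truth$crossings)
    if (n_cr > 0 && is.finite(cr)) {
      solved <- solved + cr * n_cr
      total <- total + n_cr
    }
  }
  list(TP = TP, FP = FP, FN = FN, solved = solved, crossings = total)
}
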