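#' Pipeline configuration
#'
#' Nested configuration for the full run: preprocessing, segmentation, soma
#' detection, tracing and profiling. Serializes losslessly to JSON.
#'
#' @param denoise a [denoise_config()] or NULL to skip denoising.
#' @param segmentation list: `min_size`, `max_hole` (see [segment_image()]).
#' @param soma list: `length`, `n_orient`, `dr_threshold`, `min_area`
#'   (see [detect_somas()]).
#' @param trace a [trace_config()].
#' @param profile list: `step`, `interval_px`.
#' @param tile list: `max_tile`, `margin`, `cutoff` (see
#'   [tile_large_image()]).
#' @param seed RNG seed recorded in the run report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(denoise = denoise_config(),
                            segmentation = list(min_size = 20, max_hole = 10),
                            soma = list(length = 15, n_orient = 16,
                                        dr_threshold = 0.6, min_area = 100),
                            trace = trace_config(),
                            profile = list(step = 1, interval_px = 70),
                            tile = list(max_tile = 1024, margin = 200,
                                        cutoff = 100),
                            seed = 1) {
  structure(list(denoise = denoise, segmentation = segmentation, soma = soma,
                 trace = trace, profile = profile, tile = tile, seed = seed),
            class = "pipeline_config")
}

#' Run the full extraction pipeline on one image
#'
#' Stages: optional denoising, segmentation (skipped when a mask is
#' supplied), soma detection (skipped when somas are supplied), seeding and
#' tree extraction, and intensity profiling of every neurite on the target
#' channel. The run is deterministic given the configuration.
#'
#' @param structural an [image2d()] (or matrix): the channel traced
#'   (somatodendritic / MAP2-like).
#' @param target optional [image2d()] profiled along the traces; defaults
#'   to the structural channel.
#' @param mask optional supplied segmentation (skips the segment stage).
#' @param somas optional supplied list of `soma_region` (skips detection).
#' @param model optional `segmentation_model`; NULL selects Otsu fallback.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, SWCs, masks, profile CSV,
#'   an overlay PNG and a JSON run report are written there.
#' @return List: `mask`, `somas`, `seeds`, `trees`, `profiles`, `report`.
#' @export
run_pipeline <- function(structural, target = NULL, mask = NULL, somas = NULL,
                         model = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  t0 <- proc.time()[3]
  img <- if (inherits(structural, "image2d")) structural else image2d(structural)
  if (is.null(target)) target <- img
  report <- list(config_seed = config$seed, stages = list())
  tic <- function() proc.time()[3]
  stage <- function(name, skipped, t_start, info = list()) {
    report$stages[[name]] <<- c(list(skipped = skipped,
                                     seconds = round(tic() - t_start, 3)), info)
  }

  ts <- tic()
  work <- img
  if (!is.null(config$denoise) && is.null(mask)) {
    work <- denoise(img, config$denoise)
    stage("preprocess", FALSE, ts)
  } else stage("preprocess", TRUE, ts)

  ts <- tic()
  if (is.null(mask)) {
    mask <- segment_image(work, model = model,
                          min_size = config$segmentation$min_size,
                          max_hole = config$segmentation$max_hole)
    stage("segment", FALSE, ts, list(foreground_px = sum(mask)))
  } else {
    mask <- as_binary_mask(mask)
    stage("segment", TRUE, ts, list(foreground_px = sum(mask)))
  }

  ts <- tic()
  if (is.null(somas)) {
    somas <- detect_somas(mask, dr_threshold = config$soma$dr_threshold,
                          length = config$soma$length,
                          n_orient = config$soma$n_orient,
                          min_area = config$soma$min_area)
    stage("somas", FALSE, ts, list(n_somas = length(somas)))
  } else stage("somas", TRUE, ts, list(n_somas = length(somas)))
  if (!length(somas)) stop("no somas detected: cannot extract trees")

  ts <- tic()
  seeds <- compute_seeds(mask, config$trace)
  stage("seeding", FALSE, ts, list(n_seeds = nrow(seeds)))

  ts <- tic()
  trees <- extract_trees(somas, mask, seeds, config$trace)
  stage("trace", FALSE, ts,
        list(n_neurites = sum(vapply(trees, function(t)
          length(t$neurites), integer(1))),
          conflicts = sum(vapply(trees, function(t)
            as.integer(t$conflicts), integer(1)))))

  ts <- tic()
  profiles <- list()
  for (tr in trees) {
    for (ni in seq_along(tr$neurites)) {
      nn <- tr$neurites[[ni]]
      if (nrow(nn$nodes) < 2) next
      profiles[[length(profiles) + 1]] <-
        sample_profile(target, mask, nn$nodes, step = config$profile$step,
                       neuron_id = tr$id, neurite_id = ni)
    }
  }
  stage("profile", FALSE, ts, list(n_profiles = length(profiles)))
  report$total_seconds <- round(tic() - t0, 3)

  res <- list(mask = mask, somas = somas, seeds = seeds, trees = trees,
              profiles = profiles, report = report)
  if (!is.null(out_dir)) write_run_artifacts(res, img, out_dir)
  res
}

write_run_artifacts <- function(res, img, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in res$trees)
    write_swc(tr, file.path(out_dir, sprintf("neuron_%03d.swc", tr$id)),
              pixel_size = img$pixel_size)
  write_mask(res$mask * 1L, file.path(out_dir, "mask.png"))
  write_mask(soma_label_image(res$somas, dim(res$mask)),
             file.path(out_dir, "somas.png"))
  if (length(res$profiles))
    write_profile_csv(res$profiles, file.path(out_dir, "profiles.csv"))
  write_overlay_png(img$pixels, res$trees, file.path(out_dir, "overlay.png"))
  jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# Grayscale image with per-neuron coloured trace nodes.
write_overlay_png <- function(m, trees, path) {
  g <- m / max(m, 1)
  rgb <- array(rep(g, 3), c(dim(m), 3))
  cols <- grDevices::rainbow(max(1, length(trees)))
  for (i in seq_along(trees)) {
    cc <- grDevices::col2rgb(cols[i]) / 255
    for (nn in trees[[i]]$neurites) {
      pts <- polyline_resample(nn$nodes[, c("y", "x"), drop = FALSE], 1)$pts
      pts <- round(pts)
      keep <- pts[, 1] >= 1 & pts[, 1] <= nrow(m) &
        pts[, 2] >= 1 & pts[, 2] <= ncol(m)
      pts <- pts[keep, , drop = FALSE]
      for (ch in 1:3) rgb[cbind(pts, ch)] <- cc[ch]
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Run the pipeline tile-by-tile on a large image
#'
#' Somas are grouped by proximity into rectangles ([tile_large_image()]);
#' each tile is traced independently on its crop of the mask and the
#' resulting trees are merged with globally unique ids. Trees whose nodes
#' touch a tile border (that is not an image border) are flagged truncated.
#'
#' @inheritParams run_pipeline
#' @param mask segmentation foreground of the full image (required).
#' @param somas list of `soma_region` of the full image (required).
#' @return List: `trees` (merged), `tiles`, `report`.
#' @export
run_tiled <- function(structural, mask, somas, config = pipeline_config()) {
  img <- if (inherits(structural, "image2d")) structural else image2d(structural)
  mask <- as_mat(mask) > 0
  tiles <- tile_large_image(somas, dim(mask), max_tile = config$tile$max_tile,
                            margin = config$tile$margin,
                            cutoff = config$tile$cutoff)
  trees <- list()
  truncated <- integer(0)
  for (tl in tiles) {
    r <- tl$rect
    sub <- mask[r[1]:r[2], r[3]:r[4]]
    sub_somas <- lapply(tl$soma_ids, function(id) {
      s <- somas[[which(vapply(somas, function(x) as.integer(x$id),
                               integer(1)) == id)]]
      sm <- s$mask[r[1]:r[2], r[3]:r[4]]
      reg <- new_soma_region(s$id, sm)
      reg
    })
    sub_trees <- extract_trees(sub_somas, sub, cfg = config$trace)
    for (tr in sub_trees) {
      for (ni in seq_along(tr$neurites)) {
        tr$neurites[[ni]]$nodes[, "y"] <- tr$neurites[[ni]]$nodes[, "y"] + r[1] - 1
        tr$neurites[[ni]]$nodes[, "x"] <- tr$neurites[[ni]]$nodes[, "x"] + r[3] - 1
      }
      w <- which(tr$soma$mask, arr.ind = TRUE)
      full_mask <- matrix(FALSE, nrow(mask), ncol(mask))
      full_mask[cbind(w[, 1] + r[1] - 1, w[, 2] + r[3] - 1)] <- TRUE
      tr$soma <- new_soma_region(tr$id, full_mask)
      # truncated at a tile border that is not the image border?
      trunc <- FALSE
      for (nn in tr$neurites) {
        yy <- nn$nodes[, "y"]; xx <- nn$nodes[, "x"]
        at_edge <- (yy <= r[1] + 1 & r[1] > 1) | (yy >= r[2] - 1 & r[2] < nrow(mask)) |
          (xx <= r[3] + 1 & r[3] > 1) | (xx >= r[4] - 1 & r[4] < ncol(mask))
        if (any(at_edge)) trunc <- TRUE
      }
      if (trunc) truncated <- c(truncated, tr$id)
      trees[[length(trees) + 1]] <- tr
    }
  }
  list(trees = trees, tiles = tiles,
       report = list(n_tiles = length(tiles), truncated_trees = truncated))
}
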