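#' Construct an image stack
#'
#' A confocal acquisition is a thin z-stack (typically 10-30 optical
#' sections); the stack is the unit read from disk and collapsed to 2D by
#' [project_mip()] or [project_aip()] before any analysis.
#'
#' @param voxels 3D numeric array ordered (z, y, x), finite and non-negative;
#'   a 2D matrix is promoted to a single-slice stack.
#' @param channel channel identifier (e.g. `"MAP2"`, `"PanNav"`).
#' @param pixel_size_xy lateral pixel size in micrometres per pixel.
#' @param z_step axial step in micrometres.
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, channel = "ch1", pixel_size_xy = 0.28, z_step = 1) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1, dim(voxels)))
  stopifnot(length(dim(voxels)) == 3, dim(voxels)[1] >= 1)
  if (!all(is.finite(voxels)) || any(voxels < 0))
    stop("stack intensities must be finite and non-negative")
  structure(list(voxels = voxels, channel = channel,
                 pixel_size_xy = pixel_size_xy, z_step = z_step),
            class = "image_stack")
}

#' Construct a 2D image
#'
#' @param pixels numeric matrix (y, x), finite and non-negative.
#' @param pixel_size micrometres per pixel (0.28 by default, the scale of a
#'   63x confocal acquisition).
#' @param channel channel identifier.
#' @return An `image2d` object.
#' @export
image2d <- function(pixels, pixel_size = 0.28, channel = "ch1") {
  stopifnot(is.matrix(pixels))
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("image intensities must be finite and non-negative")
  structure(list(pixels = pixels, pixel_size = pixel_size, channel = channel),
            class = "image2d")
}

#' Maximum intensity projection
#'
#' Collapses a z-stack to 2D by taking, per (y, x) pixel, the maximum over z.
#'
#' @param stack an [image_stack()].
#' @return An [image2d()] with the stack's metadata.
#' @export
project_mip <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  if (length(v) == 0) stop("empty stack: nothing to project")
  image2d(apply(v, c(2, 3), max), pixel_size = stack$pixel_size_xy,
          channel = stack$channel)
}

#' Average intensity projection
#'
#' @inheritParams project_mip
#' @return An [image2d()] holding the per-pixel mean over z.
#' @export
project_aip <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  if (length(v) == 0) stop("empty stack: nothing to project")
  image2d(apply(v, c(2, 3), mean), pixel_size = stack$pixel_size_xy,
          channel = stack$channel)
}

#' Read a TIFF file as one image stack per channel
#'
#' Multi-page TIFFs are read as z-slices; multi-sample (RGB-like) pages are
#' split into separate per-channel stacks.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_xy,z_step metadata to attach (not stored in plain TIFF).
#' @return A list of [image_stack()], one per channel.
#' @export
read_tiff_stack <- function(path, pixel_size_xy = 0.28, z_step = 1) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nch <- if (length(dim(pages[[1]])) == 3) dim(pages[[1]])[3] else 1L
  lapply(seq_len(nch), function(ch) {
    slices <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , ch] else p)
    v <- array(0, c(length(slices), nrow(slices[[1]]), ncol(slices[[1]])))
    for (z in seq_along(slices)) v[z, , ] <- slices[[z]]
    image_stack(v, channel = paste0("ch", ch),
                pixel_size_xy = pixel_size_xy, z_step = z_step)
  })
}

#' Write a 2D image or stack to TIFF (16-bit, lossless for integer data)
#'
#' @param img an [image2d()], [image_stack()] or plain matrix.
#' @param path output path.
#' @param max_value full-scale value used for 16-bit encoding.
#' @export
write_tiff_image <- function(img, path, max_value = 65535) {
  if (inherits(img, "image2d")) img <- img$pixels
  if (inherits(img, "image_stack")) {
    pages <- lapply(seq_len(dim(img$voxels)[1]), function(z) img$voxels[z, , ])
  } else pages <- list(img)
  pages <- lapply(pages, function(p) pmin(pmax(p / max_value, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write / read an integer label mask as 16-bit PNG
#'
#' @param mask integer or logical matrix (labels 0..65535).
#' @param path file path.
#' @return `read_mask` returns an integer matrix.
#' @export
write_mask <- function(mask, path) {
  m <- as_mat(mask)
  storage.mode(m) <- "integer"
  if (any(m < 0) || any(m > 65535)) stop("labels must be in 0..65535")
  # lossless 16-bit labels as a two-channel (high byte, low byte) PNG
  arr <- array(0, c(nrow(m), ncol(m), 3))
  arr[, , 1] <- (m %/% 256L) / 255
  arr[, , 2] <- (m %% 256L) / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) != 3) stop("not a label PNG written by write_mask")
  matrix(as.integer(round(m[, , 1] * 255) * 256L + round(m[, , 2] * 255)),
         dim(m)[1], dim(m)[2])
}

swc_type_code <- function(label) {
  switch(label, axon = 2L, dendrite = 3L, 0L)
}

#' Write a neuron tree to SWC
#'
#' Standard 7-column SWC (`id type x y z radius parent`): one sample per tree
#' node, soma as type 1 at the root, axon 2, dendrite 3, unassigned 0.
#' Pixel coordinates are scaled to micrometres; z is 0 for 2D traces.
#'
#' @param tree a `neuron_tree` (see [extract_trees()]).
#' @param path output path.
#' @param pixel_size micrometres per pixel.
#' @export
write_swc <- function(tree, path, pixel_size = 0.28) {
  stopifnot(inherits(tree, "neuron_tree"))
  validate_tree(tree)
  rows <- list()
  soma_r <- sqrt(tree$soma$area / pi) * pixel_size
  rows[[1]] <- c(1, 1, (tree$soma$centroid[2] - 1) * pixel_size,
                 (tree$soma$centroid[1] - 1) * pixel_size, 0, soma_r, -1)
  nid <- 1L
  first_id <- integer(length(tree$neurites))
  last_id <- integer(length(tree$neurites))
  for (i in seq_along(tree$neurites)) {
    nn <- tree$neurites[[i]]
    par <- nn$parent
    parent_id <- if (is.null(par)) 1L else {
      # parent = (neurite index, node index); neurites are emitted in order
      first_id[par[1]] + par[2] - 1L
    }
    tc <- swc_type_code(nn$label)
    nodes <- nn$nodes
    for (k in seq_len(nrow(nodes))) {
      nid <- nid + 1L
      if (k == 1) first_id[i] <- nid
      r <- if ("radius" %in% colnames(nodes)) nodes[k, "radius"] * pixel_size else pixel_size
      rows[[nid]] <- c(nid, tc, (nodes[k, "x"] - 1) * pixel_size,
                       (nodes[k, "y"] - 1) * pixel_size, 0, r,
                       if (k == 1) parent_id else nid - 1L)
      last_id[i] <- nid
    }
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC neuron trace (x,y in um; z = 0; 2D)", con)
  write.table(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an SWC file
#'
#' @param path SWC file path.
#' @param pixel_size micrometres per pixel used to recover pixel coordinates.
#' @return A data.frame with columns id, type, x, y, z, radius, parent plus
#'   pixel-space columns row, col.
#' @export
read_swc <- function(path, pixel_size = 0.28) {
  if (!file.exists(path)) stop("cannot read SWC: ", path)
  tab <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  tab$row <- tab$y / pixel_size + 1
  tab$col <- tab$x / pixel_size + 1
  tab
}

#' Write intensity profiles to CSV
#'
#' @param profiles a list of `intensity_profile` objects (see
#'   [sample_profile()]), or a single one.
#' @param path output path.
#' @export
write_profile_csv <- function(profiles, path) {
  if (inherits(profiles, "intensity_profile")) profiles <- list(profiles)
  tabs <- lapply(profiles, function(p) {
    data.frame(neuron_id = p$neuron_id, neurite_id = p$neurite_id,
               arclength_px = p$arclength_px, arclength_um = p$arclength_um,
               raw = p$raw, background = p$background, corrected = p$corrected)
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

# Tree invariant checks shared by writers and the tracer.
validate_tree <- function(tree) {
  n <- length(tree$neurites)
  for (i in seq_len(n)) {
    par <- tree$neurites[[i]]$parent
    if (!is.null(par)) {
      if (par[1] >= i || par[1] < 1)
        stop("neuron tree is not acyclic: neurite ", i,
             " has parent neurite ", par[1])
    }
    s <- tree$neurites[[i]]$nodes[, "arclength"]
    if (length(s) > 1 && any(diff(s) <= 0))
      stop("arclength must be strictly increasing along a neurite")
  }
  invisible(TRUE)
}
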