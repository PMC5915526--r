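# Internal geometry / raster helpers shared across modules.

as_mat <- function(x) {
  if (inherits(x, "Image")) return(EBImage::imageData(x))
  if (is.matrix(x)) return(x)
  stop("expected a matrix or EBImage Image")
}

# 2D convolution with reflected boundaries; kernel must have odd dimensions.
conv2 <- function(m, kernel) {
  as_mat(EBImage::filter2(EBImage::Image(m), kernel, boundary = "replicate"))
}

# Shift a matrix by (dy, dx), padding with `fill`.
mat_shift <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Bilinear interpolation of matrix `m` at fractional (y, x); clamped to edges.
bilinear <- function(m, y, x) {
  nr <- nrow(m); nc <- ncol(m)
  y <- pmin(pmax(y, 1), nr)
  x <- pmin(pmax(x, 1), nc)
  y0 <- pmin(floor(y), nr - 1L); x0 <- pmin(floor(x), nc - 1L)
  y0 <- pmax(y0, 1L); x0 <- pmax(x0, 1L)
  fy <- y - y0; fx <- x - x0
  m[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    m[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    m[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    m[cbind(y0 + 1, x0 + 1)] * fy * fx
}

# Cumulative Euclidean arclength along a polyline given as (y, x) matrix.
polyline_arclength <- function(pts) {
  if (nrow(pts) < 2) return(rep(0, nrow(pts)))
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  c(0, cumsum(d))
}

# Resample a polyline at uniform arclength spacing `step`, keeping endpoints.
polyline_resample <- function(pts, step = 1) {
  s <- polyline_arclength(pts)
  total <- s[length(s)]
  if (total == 0) return(list(pts = pts[1, , drop = FALSE], s = 0))
  su <- unique(c(seq(0, total, by = step), total))
  y <- approx(s, pts[, 1], xout = su, ties = "ordered")$y
  x <- approx(s, pts[, 2], xout = su, ties = "ordered")$y
  list(pts = cbind(y = y, x = x), s = su)
}

# Integer pixel offsets of a filled disk of radius r (r >= 0).
disk_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  g <- g[g$dy^2 + g$dx^2 <= r^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

# Stamp value `val` onto matrix entries (centers + disk offsets), taking max.
stamp_disks <- function(m, centers, r, val) {
  off <- disk_offsets(r)
  nr <- nrow(m); nc <- ncol(m)
  for (k in seq_len(nrow(centers))) {
    yy <- centers[k, 1] + off[, 1]
    xx <- centers[k, 2] + off[, 2]
    keep <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    idx <- cbind(yy[keep], xx[keep])
    v <- if (length(val) > 1) val[k] else val
    m[idx] <- pmax(m[idx], v)
  }
  m
}

# Rotate a matrix by 90 degrees counter-clockwise in (row, col) space:
# point (y, x) in an nr x nc matrix maps to (nc - x + 1, y).
rot90_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Map (y, x) points under the same rotation as rot90_mat for an nr x nc image.
rot90_points <- function(pts, nc) cbind(nc - pts[, 2] + 1, pts[, 1])

# Connected-component centroids of a labelled integer matrix.
label_centroids <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) {
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y", "x"))))
  }
  out <- t(vapply(ids, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }, numeric(2)))
  dimnames(out) <- list(NULL, c("y", "x"))
  out
}

# Boundary pixels of a binary mask (foreground with a 4-neighbour background).
mask_boundary <- function(mask) {
  er <- mat_shift(mask, 1, 0, FALSE) & mat_shift(mask, -1, 0, FALSE) &
    mat_shift(mask, 0, 1, FALSE) & mat_shift(mask, 0, -1, FALSE)
  mask & !er
}

# Minimum distance from each point in `a` to any point in `b` (both (y,x)
# matrices), computed in chunks to bound memory.
min_dist_to_set <- function(a, b, chunk = 2000L) {
  if (nrow(b) == 0) return(rep(Inf, nrow(a)))
  out <- numeric(nrow(a))
  for (i0 in seq(1, nrow(a), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(a))
    d2 <- outer(a[i0:i1, 1], b[, 1], "-")^2 + outer(a[i0:i1, 2], b[, 2], "-")^2
    out[i0:i1] <- sqrt(apply(d2, 1, min))
  }
  out
}

# Remove connected components smaller than min_size; fill holes smaller than
# max_hole (holes are background components not touching the image border).
clean_mask <- function(mask, min_size = 20, max_hole = 10) {
  mask <- mask > 0
  if (any(mask)) {
    lab <- as_mat(EBImage::bwlabel(EBImage::Image(mask * 1)))
    sz <- tabulate(lab[lab > 0])
    drop <- which(sz < min_size)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  if (max_hole > 0 && any(!mask)) {
    labb <- as_mat(EBImage::bwlabel(EBImage::Image((!mask) * 1)))
    border_ids <- unique(c(labb[1, ], labb[nrow(labb), ], labb[, 1], labb[, ncol(labb)]))
    szb <- tabulate(labb[labb > 0])
    fill <- setdiff(which(szb < max_hole), border_ids)
    if (length(fill)) mask[labb %in% fill] <- TRUE
  }
  mask
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
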