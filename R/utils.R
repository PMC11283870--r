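# Low-level raster utilities shared across modules.
#
# Conventions used throughout the package (fixed here, once):
#  * Images are numeric arrays [row, col, channel] with values in [0, 1]
#    (as returned by png::readPNG); masks are logical matrices [row, col].
#  * Pixel coordinates are 0-based with x = column, y = row and the origin at
#    the top-left; the pixel in matrix cell [r, c] spans x in [c-1, c) and has
#    its center at (c - 0.5, r - 0.5).
#  * Bounding boxes are half-open integer (x_min, y_min, x_max, y_max).
#  * Angle math happens in "math" convention (y up); the image-to-math y flip
#    happens in exactly one place, mask_pixels_math().

#' Evaluate code with a temporarily fixed RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never disturb
#' the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

#' Label 8-connected foreground components
#'
#' Run-based two-pass labeling with union-find. Runs of foreground pixels per
#' row are linked to runs in the previous row that overlap horizontally when
#' extended by one pixel on each side (diagonal adjacency).
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered 1..n in order of first (row-major) appearance.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  reach <- if (connectivity == 8) 1L else 0L
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  if (!any(mask)) return(out)

  parent <- integer(0)
  uf_find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  uf_union <- function(a, b) {
    ra <- uf_find(a); rb <- uf_find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }

  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0); run_id <- integer(0)
  prev <- NULL
  for (r in seq_len(h)) {
    rowv <- mask[r, ]
    if (!any(rowv)) { prev <- NULL; next }
    rl <- rle(as.logical(rowv))
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    s <- starts[rl$values]; e <- ends[rl$values]
    ids <- integer(length(s))
    for (k in seq_along(s)) {
      nid <- length(parent) + 1L
      parent[nid] <- nid
      ids[k] <- nid
      if (!is.null(prev)) {
        ov <- which(prev$e >= s[k] - reach & prev$s <= e[k] + reach)
        for (j in ov) uf_union(ids[k], prev$id[j])
      }
    }
    run_row <- c(run_row, rep.int(r, length(s)))
    run_s <- c(run_s, s); run_e <- c(run_e, e); run_id <- c(run_id, ids)
    prev <- list(s = s, e = e, id = ids)
  }

  roots <- vapply(run_id, uf_find, integer(1))
  relabel <- integer(length(parent))
  nxt <- 0L
  final <- integer(length(roots))
  for (k in seq_along(roots)) {
    if (relabel[roots[k]] == 0L) { nxt <- nxt + 1L; relabel[roots[k]] <- nxt }
    final[k] <- relabel[roots[k]]
  }
  for (k in seq_along(run_row)) out[run_row[k], run_s[k]:run_e[k]] <- final[k]
  out
}

# Offsets of a disc of radius r (pixel units, Euclidean).
disc_offsets <- function(r) {
  r <- as.integer(ceiling(r))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

shift_mask <- function(mask, dr, dc) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- mask[rs - dr, cs - dc]
  out
}

#' Binary dilation / erosion with a disc structuring element
#'
#' @param mask Logical matrix.
#' @param radius Disc radius in pixels.
#' @return Logical matrix.
#' @export
binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- disc_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off))) out <- out | shift_mask(mask, off$dr[k], off$dc[k])
  out
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  !binary_dilate(!mask, radius)
}

#' Fill interior holes of a binary mask
#'
#' Background components not connected (4-connectivity through the complement,
#' which matches 8-connectivity of the foreground) to the image border are
#' turned into foreground.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  lab <- label_components(!mask, connectivity = 4)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels != 0L]
  holes <- lab != 0L & !(lab %in% border_labels)
  mask | holes
}

#' Intersection-over-union of two masks
#'
#' @param a,b Logical matrices of identical shape.
#' @return IoU in [0, 1]; 0 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

# (x, y) centers (0-based pixel coords) of foreground pixels, row-major order.
mask_pixel_centers <- function(mask) {
  idx <- which(t(mask))              # row-major
  w <- ncol(mask)
  c0 <- (idx - 1L) %% w              # 0-based col
  r0 <- (idx - 1L) %/% w             # 0-based row
  cbind(x = c0 + 0.5, y = r0 + 0.5)
}

#' Convert mask pixels to math-convention points
#'
#' The single place where the image y axis (down) is flipped to the math
#' convention (y up) used for line fitting and angle reporting: a leaf pointing
#' above the horizontal gets a positive angle.
#'
#' @param mask Logical matrix.
#' @param image_height Image height in pixels (defaults to `nrow(mask)`).
#' @return Two-column matrix of (x, y) points at pixel centers, y up.
#' @export
mask_pixels_math <- function(mask, image_height = nrow(mask)) {
  p <- mask_pixel_centers(mask)
  p[, 2] <- image_height - p[, 2]
  p
}

# Tight bbox of a mask, half-open 0-based (x_min, y_min, x_max, y_max).
mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (!length(rows)) stop("mask has no foreground pixels")
  c(x_min = cols[1] - 1L, y_min = rows[1] - 1L,
    x_max = cols[length(cols)], y_max = rows[length(rows)])
}

# Blank RGB canvas filled with a color (length-3 numeric in [0,1]).
blank_image <- function(width, height, color = c(0, 0, 0)) {
  arr <- array(0, dim = c(height, width, 3))
  for (ch in 1:3) arr[, , ch] <- color[ch]
  arr
}
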