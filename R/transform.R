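# Similarity transforms (flip / rotate / scale) of exemplars.
#
# Implemented by inverse mapping with nearest-neighbor sampling so masks stay
# strictly binary. The output canvas is the tight bound of the transformed
# patch rectangle; points (attachment point, mount sites) are mapped by the
# same forward transform and stay in float precision.

# Forward 2x2 linear map for flip -> rotate(theta) -> scale, acting on image
# coordinates (y down). Positive angle turns the exemplar counter-clockwise
# on screen.
similarity_matrix <- function(flip, angle_deg, scale) {
  th <- angle_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2, byrow = TRUE)
  # y-down coords: screen-CCW rotation is the math-CW matrix, hence the signs
  f <- if (flip) -1 else 1
  scale * rot %*% diag(c(f, 1))
}

#' Transform a leaf exemplar by a similarity transform
#'
#' Applies an optional horizontal flip, a rotation and an isotropic scaling to
#' the patch and all masks (nearest-neighbor, so masks stay binary), and maps
#' the attachment point by the same transform.
#'
#' @param exemplar A [leaf_exemplar()].
#' @param flip Mirror horizontally first?
#' @param angle_deg Rotation in degrees, counter-clockwise on screen.
#' @param scale Isotropic scale factor, > 0.
#' @return A transformed `leaf_exemplar`.
#' @export
transform_exemplar <- function(exemplar, flip = FALSE, angle_deg = 0, scale = 1) {
  stopifnot(scale > 0)
  tr <- transform_raster(exemplar$patch,
                         list(leaf = exemplar$leaf_mask,
                              midvein = exemplar$midvein_mask,
                              petiole = exemplar$petiole_mask),
                         rbind(exemplar$attachment_point),
                         flip, angle_deg, scale)
  if (!any(tr$masks$leaf))
    stop("transformed blade mask is empty (scale ", scale, " too extreme)")
  leaf_exemplar(patch = tr$patch, leaf_mask = tr$masks$leaf,
                midvein_mask = tr$masks$midvein, petiole_mask = tr$masks$petiole,
                attachment_point = c(x = tr$points[1, 1], y = tr$points[1, 2]),
                origin = exemplar$origin, source_id = exemplar$source_id)
}

# Shared raster transform: patch (RGB array), named list of masks, and an
# n x 2 matrix of (x, y) points, all in the same patch frame.
transform_raster <- function(patch, masks, points, flip, angle_deg, scale) {
  h <- dim(patch)[1]; w <- dim(patch)[2]
  A <- similarity_matrix(flip, angle_deg, scale)
  ctr <- c(w / 2, h / 2)
  corners <- rbind(c(0, 0), c(w, 0), c(0, h), c(w, h))
  tc <- t(A %*% (t(corners) - ctr))
  xr <- range(tc[, 1]); yr <- range(tc[, 2])
  out_w <- max(1L, as.integer(ceiling(xr[2] - xr[1])))
  out_h <- max(1L, as.integer(ceiling(yr[2] - yr[1])))
  shift <- c(-xr[1], -yr[1])  # forward: p' = A (p - ctr) + shift

  # inverse map output pixel centers
  Ainv <- solve(A)
  ox <- rep(seq_len(out_w) - 0.5, each = out_h) - shift[1]
  oy <- rep(seq_len(out_h) - 0.5, times = out_w) - shift[2]
  src <- Ainv %*% rbind(ox, oy)
  sc <- as.integer(round(src[1, ] + ctr[1] + 0.5))  # column index
  sr <- as.integer(round(src[2, ] + ctr[2] + 0.5))  # row index
  ok <- sr >= 1L & sr <= h & sc >= 1L & sc <= w
  lin <- (sc - 1L) * h + sr  # column-major linear index into h x w

  out_patch <- array(0, dim = c(out_h, out_w, dim(patch)[3]))
  for (ch in seq_len(dim(patch)[3])) {
    plane <- patch[, , ch]
    dst <- numeric(out_h * out_w)
    dst[ok] <- plane[lin[ok]]
    out_patch[, , ch] <- matrix(dst, out_h, out_w)
  }
  out_masks <- lapply(masks, function(m) {
    dst <- logical(out_h * out_w)
    dst[ok] <- m[lin[ok]]
    matrix(dst, out_h, out_w)
  })
  tp <- t(A %*% (t(points) - ctr) + shift)
  list(patch = out_patch, masks = out_masks, points = tp,
       size = c(width = out_w, height = out_h))
}
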