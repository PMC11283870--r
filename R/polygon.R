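# Mask <-> polygon conversion by edge point extraction.
#
# The boundary of the largest 8-connected component is traced pixel by pixel
# (Moore neighbor tracing), collapsed along straight runs, and serialized as a
# normalized-coordinate polygon. Rasterization draws the polygon edges and
# fills the interior by even-odd scanline, so for a simply connected component
# the round trip reproduces the mask exactly (holes are filled; additional
# components are dropped by the largest-component rule, one polygon per line).

# Moore boundary trace of a single 8-connected component containing (r0, c0),
# the topmost-then-leftmost foreground pixel. Returns an n x 2 matrix of
# (row, col) boundary pixels ordered counter-clockwise in image coordinates.
trace_boundary <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  r0 <- rows[1]
  c0 <- which(mask[r0, ])[1]
  # 8 neighbors in clockwise order starting West: W NW N NE E SE S SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  h <- nrow(mask); w <- ncol(mask)
  fg <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c]

  pts_r <- integer(0); pts_c <- integer(0)
  cur_r <- r0; cur_c <- c0
  back <- 1L  # index into neighbor list of the backtrack direction (start: West)
  first_move <- NA_integer_
  repeat {
    pts_r <- c(pts_r, cur_r); pts_c <- c(pts_c, cur_c)
    found <- 0L
    k <- back
    for (step in seq_len(8)) {
      k <- k %% 8L + 1L
      if (fg(cur_r + dr[k], cur_c + dc[k])) { found <- k; break }
    }
    if (found == 0L) break  # isolated pixel
    if (is.na(first_move)) first_move <- found
    prev_r <- cur_r; prev_c <- cur_c
    cur_r <- cur_r + dr[found]; cur_c <- cur_c + dc[found]
    # backtrack for the new pixel = direction pointing to the previous pixel
    back <- which(dr == prev_r - cur_r & dc == prev_c - cur_c)
    # Jacob's stopping criterion: back at start entering with the first move
    if (cur_r == r0 && cur_c == c0) {
      k2 <- back
      nxt <- 0L
      for (step in seq_len(8)) {
        k2 <- k2 %% 8L + 1L
        if (fg(cur_r + dr[k2], cur_c + dc[k2])) { nxt <- k2; break }
      }
      if (nxt == first_move || length(pts_r) > 4L * (h * w)) break
    }
  }
  cbind(row = pts_r, col = pts_c)
}

# Drop vertices interior to straight runs (exact collinearity), cyclically;
# the first vertex (the deterministic topmost-leftmost start) is always kept.
collapse_collinear <- function(pts) {
  n <- nrow(pts)
  if (n <= 3) return(pts)
  keep <- rep(TRUE, n)
  kept_prev <- function(i) { j <- i; repeat { j <- if (j == 1) n else j - 1; if (keep[j]) return(j) } }
  for (i in 2:n) {
    p <- kept_prev(i)
    nxt <- if (i == n) 1 else i + 1
    v1 <- pts[i, ] - pts[p, ]
    v2 <- pts[nxt, ] - pts[i, ]
    if (v1[1] * v2[2] - v1[2] * v2[1] == 0 && sum(v1 * v2) > 0) keep[i] <- FALSE
  }
  pts[keep, , drop = FALSE]
}

#' Convert an instance mask to a YOLO segmentation polygon
#'
#' Traces the boundary of the mask's largest 8-connected component into an
#' ordered vertex list (counter-clockwise in image coordinates, starting from
#' the topmost-then-leftmost boundary pixel) and normalizes the vertices, at
#' pixel centers, by image width and height.
#'
#' @param annotation An [instance_annotation()] (or a bare logical mask).
#' @return A [yolo_seg_record()].
#' @export
mask_to_polygon <- function(annotation) {
  if (is.matrix(annotation)) annotation <- instance_annotation("LEAF", annotation)
  mask <- annotation$mask
  if (!any(mask)) stop("cannot trace an empty mask")
  lab <- label_components(mask)
  if (max(lab) > 1L) {
    areas <- tabulate(lab[lab > 0L])
    mask <- lab == which.max(areas)
  }
  pts <- trace_boundary(mask)
  pts <- collapse_collinear(pts)
  # counter-clockwise in image coords <=> negative shoelace sum (y down)
  x <- pts[, "col"] - 0.5
  y <- pts[, "row"] - 0.5
  n <- length(x)
  if (n >= 3) {
    j <- c(2:n, 1)
    if (sum(x * y[j] - x[j] * y) > 0) {
      ord <- c(1, n:2)
      x <- x[ord]; y <- y[ord]
    }
  }
  while (length(x) < 3) { x <- c(x, x[length(x)]); y <- c(y, y[length(y)]) }
  w <- annotation$image_size[["width"]]; h <- annotation$image_size[["height"]]
  yolo_seg_record(annotation$class_index, as.vector(rbind(x / w, y / h)))
}

#' Rasterize a YOLO segmentation polygon to an instance mask
#'
#' Inverse of [mask_to_polygon()] up to 1-pixel boundary quantization: polygon
#' edges are drawn (so degenerate polygons rasterize to a 1-pixel-wide line,
#' never an empty mask) and the interior is filled by even-odd scanline over
#' pixel centers.
#'
#' @param record A [yolo_seg_record()].
#' @param image_size Integer (width, height).
#' @return An [instance_annotation()].
#' @export
polygon_to_mask <- function(record, image_size) {
  stopifnot(inherits(record, "yolo_seg_record"))
  w <- as.integer(image_size[1]); h <- as.integer(image_size[2])
  xs <- record$coords[seq(1, length(record$coords), 2)] * w
  ys <- record$coords[seq(2, length(record$coords), 2)] * h
  n <- length(xs)
  if (n < 3) stop("a polygon needs at least 3 vertices")
  mask <- matrix(FALSE, h, w)

  # edges: integer vertex pixels, connected by uniform stepping
  ci <- pmin(pmax(as.integer(round(xs + 0.5)), 1L), w)
  ri <- pmin(pmax(as.integer(round(ys + 0.5)), 1L), h)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    steps <- max(abs(ci[j] - ci[i]), abs(ri[j] - ri[i]), 1L)
    rr <- round(seq(ri[i], ri[j], length.out = steps + 1))
    cc <- round(seq(ci[i], ci[j], length.out = steps + 1))
    mask[cbind(rr, cc)] <- TRUE
  }

  # even-odd scanline fill over pixel centers y = r - 0.5
  x1 <- xs; y1 <- ys
  x2 <- xs[c(2:n, 1)]; y2 <- ys[c(2:n, 1)]
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  r_range <- max(1L, floor(min(ylo) + 0.5)):min(h, ceiling(max(yhi) + 0.5))
  for (r in r_range) {
    yc <- r - 0.5
    act <- which(ylo <= yc & yc < yhi)
    if (length(act) < 2) next
    xi <- x1[act] + (yc - y1[act]) * (x2[act] - x1[act]) / (y2[act] - y1[act])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      c_lo <- max(1L, as.integer(ceiling(xi[k] + 0.5 - 1e-9)))
      c_hi <- min(w, as.integer(floor(xi[k + 1] + 0.5 + 1e-9)))
      if (c_lo <= c_hi) mask[r, c_lo:c_hi] <- TRUE
    }
  }
  instance_annotation(component_class_label(record$class_index), mask)
}
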