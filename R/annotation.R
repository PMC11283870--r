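# Component classes, annotation palette and instance annotations.

.component_classes <- c(LEAF = 0L, MIDVEIN = 1L, PETIOLE = 2L, TRUNK = 3L)

#' Component classes and their stable indices
#'
#' The four annotated plant components and the class indices used in every
#' serialized format: LEAF = 0, MIDVEIN = 1, PETIOLE = 2, TRUNK = 3.
#'
#' @return Named integer vector mapping label to class index.
#' @export
component_classes <- function() .component_classes

#' @rdname component_classes
#' @param label Character class label.
#' @export
component_class_index <- function(label) {
  label <- match.arg(toupper(label), names(.component_classes))
  .component_classes[[label]]
}

#' @rdname component_classes
#' @param index Integer class index.
#' @export
component_class_label <- function(index) {
  m <- match(as.integer(index), .component_classes)
  if (anyNA(m)) stop("unknown class index: ", paste(index[is.na(m)], collapse = ", "))
  names(.component_classes)[m]
}

#' Annotation palette for color-coded annotation maps
#'
#' Manual annotation maps mark each leaf blade in green, its midvein in yellow
#' and its petiole in red; trunks use a fourth color (blue by default). A pixel
#' matches a class when every channel is within `tolerance` of the class color
#' (0-255 scale), which survives JPEG compression and anti-aliased edges; set
#' `tolerance = 0` for exact matching.
#'
#' @param leaf,midvein,petiole,trunk RGB triples on the 0-255 scale.
#' @param tolerance Per-channel tolerance (0-255).
#' @return An `annotation_palette` object.
#' @export
annotation_palette <- function(leaf = c(0, 255, 0), midvein = c(255, 255, 0),
                               petiole = c(255, 0, 0), trunk = c(0, 0, 255),
                               tolerance = 30) {
  cols <- list(LEAF = leaf, MIDVEIN = midvein, PETIOLE = petiole, TRUNK = trunk)
  for (nm in names(cols)) {
    v <- cols[[nm]]
    if (length(v) != 3 || any(v < 0) || any(v > 255))
      stop("palette color for ", nm, " must be an RGB triple in 0-255")
  }
  stopifnot(tolerance >= 0, tolerance <= 255)
  nm <- names(cols)
  for (i in seq_along(cols)) for (j in seq_along(cols)) {
    if (i < j && max(abs(cols[[i]] - cols[[j]])) <= 2 * tolerance)
      stop("palette colors ", nm[i], " and ", nm[j],
           " are not distinguishable under tolerance ", tolerance)
  }
  structure(list(colors = cols, tolerance = tolerance), class = "annotation_palette")
}

# Logical mask of pixels matching one palette color within tolerance.
palette_match <- function(image, color, tolerance) {
  abs(image[, , 1] * 255 - color[1]) <= tolerance &
    abs(image[, , 2] * 255 - color[2]) <= tolerance &
    abs(image[, , 3] * 255 - color[3]) <= tolerance
}

#' Construct an instance annotation
#'
#' One segmented object instance: class, binary raster mask on the image grid
#' and its tight half-open bounding box. This is the unit exchanged with
#' instance-segmentation tools in either the per-instance mask format or the
#' YOLO polygon format.
#'
#' @param class Character class label (see [component_classes()]).
#' @param mask Logical matrix (rows = image height, cols = width), >= 1
#'   foreground pixel.
#' @param instance_id Optional identifier linking organ annotations to their
#'   parent leaf.
#' @return An `instance_annotation` object with fields `class`, `class_index`,
#'   `mask`, `bbox`, `image_size` (width, height) and `instance_id`.
#' @export
instance_annotation <- function(class, mask, instance_id = NA_integer_) {
  class <- match.arg(toupper(class), names(.component_classes))
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) stop("instance annotation mask must have at least one foreground pixel")
  structure(list(
    class = class,
    class_index = .component_classes[[class]],
    mask = mask,
    bbox = mask_bbox(mask),
    image_size = c(width = ncol(mask), height = nrow(mask)),
    instance_id = instance_id
  ), class = "instance_annotation")
}

#' @export
print.instance_annotation <- function(x, ...) {
  cat(sprintf("<instance_annotation> %s: %d px, bbox [%d,%d)x[%d,%d) on %dx%d\n",
              x$class, sum(x$mask), x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4],
              x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Construct a YOLO segmentation record
#'
#' One line of a YOLO segmentation label file: the object class index followed
#' by the polygon vertices normalized to [0, 1] by image width and height.
#'
#' @param class_index Integer class index.
#' @param coords Even-length numeric vector of interleaved (x, y) pairs in
#'   [0, 1]; at least 3 vertices.
#' @return A `yolo_seg_record` object.
#' @export
yolo_seg_record <- function(class_index, coords) {
  class_index <- as.integer(class_index)
  stopifnot(length(class_index) == 1, class_index >= 0)
  coords <- as.numeric(coords)
  if (length(coords) %% 2 != 0) stop("coords must be interleaved (x, y) pairs")
  if (length(coords) < 6) stop("a polygon needs at least 3 vertices")
  if (any(coords < -1e-9) || any(coords > 1 + 1e-9))
    stop("normalized coordinates must lie in [0, 1]")
  structure(list(class_index = class_index,
                 coords = pmin(pmax(coords, 0), 1)),
            class = "yolo_seg_record")
}
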