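# Parsing palette-coded annotation maps into component exemplars.

#' Construct a leaf exemplar
#'
#' A cropped image patch with aligned blade, midvein and petiole masks and the
#' attachment point used to mount the leaf on a trunk during synthesis.
#' `leaf_mask` holds the blade pixels only; the three masks are disjoint, so
#' every annotated pixel belongs to exactly one class mask. The full leaf
#' region (as used for instance annotations and IoU matching) is their union.
#'
#' @param patch RGB array crop.
#' @param leaf_mask,midvein_mask,petiole_mask Logical matrices aligned to
#'   `patch`.
#' @param attachment_point Numeric (x, y) in patch pixel coordinates; computed
#'   with [compute_attachment_point()] when `NULL`.
#' @param origin Integer (x0, y0): position of the patch's top-left corner in
#'   the source image (0-based).
#' @param source_id Provenance string.
#' @return A `leaf_exemplar` object.
#' @export
leaf_exemplar <- function(patch, leaf_mask, midvein_mask = NULL, petiole_mask = NULL,
                          attachment_point = NULL, origin = c(0L, 0L),
                          source_id = "") {
  stopifnot(length(dim(patch)) == 3, is.matrix(leaf_mask))
  if (is.null(midvein_mask)) midvein_mask <- matrix(FALSE, nrow(leaf_mask), ncol(leaf_mask))
  if (is.null(petiole_mask)) petiole_mask <- matrix(FALSE, nrow(leaf_mask), ncol(leaf_mask))
  stopifnot(identical(dim(leaf_mask), dim(midvein_mask)),
            identical(dim(leaf_mask), dim(petiole_mask)),
            nrow(leaf_mask) == dim(patch)[1], ncol(leaf_mask) == dim(patch)[2])
  if (!any(leaf_mask)) stop("leaf exemplar requires a non-empty blade mask")
  ex <- structure(list(patch = patch, leaf_mask = leaf_mask,
                       midvein_mask = midvein_mask, petiole_mask = petiole_mask,
                       attachment_point = attachment_point,
                       origin = as.integer(origin), source_id = source_id),
                  class = "leaf_exemplar")
  if (is.null(ex$attachment_point)) ex$attachment_point <- compute_attachment_point(ex)
  ex
}

# Full leaf region: blade plus its organs.
exemplar_region <- function(ex) ex$leaf_mask | ex$midvein_mask | ex$petiole_mask

#' Construct a trunk exemplar
#'
#' @param patch RGB array crop.
#' @param trunk_mask Logical matrix aligned to `patch`.
#' @param attachment_sites Optional n x 2 matrix of candidate (x, y) mount
#'   points on the trunk; computed with [compute_attachment_sites()] when
#'   `NULL`.
#' @param source_id Provenance string.
#' @return A `trunk_exemplar` object.
#' @export
trunk_exemplar <- function(patch, trunk_mask, attachment_sites = NULL, source_id = "") {
  stopifnot(is.matrix(trunk_mask), any(trunk_mask))
  ex <- structure(list(patch = patch, trunk_mask = trunk_mask,
                       attachment_sites = attachment_sites, source_id = source_id),
                  class = "trunk_exemplar")
  if (is.null(ex$attachment_sites)) ex$attachment_sites <- compute_attachment_sites(trunk_mask)
  ex
}

#' Extract component exemplars from a palette-coded annotation map
#'
#' Finds the 8-connected components of each palette color, assigns every
#' midvein/petiole component to the leaf blade it overlaps most (falling back
#' to the most-adjacent blade within a 5-pixel dilation, since petioles are
#' often drawn extending just outside the blade), and crops one exemplar per
#' blade, padded by 2 pixels. Midvein or petiole components touching no blade
#' are discarded with a warning. Trunk-colored pixels yield one trunk exemplar
#' (the largest trunk component).
#'
#' @param raw_image RGB array (the photograph).
#' @param annotation_map RGB array of identical dimensions with palette colors.
#' @param palette An [annotation_palette()].
#' @param source_id Provenance string recorded on each exemplar.
#' @param adjacency_radius Dilation radius for the zero-overlap fallback.
#' @return `list(leaves = <list of leaf_exemplar>, trunk = <trunk_exemplar or NULL>)`.
#' @export
parse_annotation_map <- function(raw_image, annotation_map, palette = annotation_palette(),
                                 source_id = "", adjacency_radius = 5) {
  if (!identical(dim(raw_image)[1:2], dim(annotation_map)[1:2]))
    stop("raw image and annotation map dimensions differ")
  tol <- palette$tolerance
  leaf_px <- palette_match(annotation_map, palette$colors$LEAF, tol)
  midvein_px <- palette_match(annotation_map, palette$colors$MIDVEIN, tol)
  petiole_px <- palette_match(annotation_map, palette$colors$PETIOLE, tol)
  trunk_px <- palette_match(annotation_map, palette$colors$TRUNK, tol)

  leaf_lab <- label_components(leaf_px)
  n_leaves <- max(leaf_lab)

  assign_organs <- function(organ_px, organ_name) {
    out <- vector("list", n_leaves)
    if (!any(organ_px)) return(out)
    lab <- label_components(organ_px)
    for (k in seq_len(max(lab))) {
      comp <- lab == k
      hits <- leaf_lab[comp]
      tab <- tabulate(hits[hits > 0L], nbins = n_leaves)
      if (!any(tab > 0) && n_leaves > 0) {
        # adjacency fallback, restricted to the component's neighborhood
        bb <- mask_bbox(comp)
        r1 <- max(1L, bb["y_min"] + 1L - adjacency_radius)
        r2 <- min(nrow(comp), bb["y_max"] + adjacency_radius)
        c1 <- max(1L, bb["x_min"] + 1L - adjacency_radius)
        c2 <- min(ncol(comp), bb["x_max"] + adjacency_radius)
        near_mask <- binary_dilate(comp[r1:r2, c1:c2, drop = FALSE], adjacency_radius)
        near <- leaf_lab[r1:r2, c1:c2, drop = FALSE][near_mask]
        tab <- tabulate(near[near > 0L], nbins = n_leaves)
      }
      if (!any(tab > 0)) {
        warning(sprintf("%s component of %d px overlaps no leaf blade; discarded",
                        organ_name, sum(comp)))
        next
      }
      j <- which.max(tab)
      out[[j]] <- if (is.null(out[[j]])) comp else out[[j]] | comp
    }
    out
  }
  midvein_of <- assign_organs(midvein_px, "midvein")
  petiole_of <- assign_organs(petiole_px, "petiole")

  h <- nrow(leaf_px); w <- ncol(leaf_px)
  empty <- matrix(FALSE, h, w)
  leaves <- vector("list", n_leaves)
  for (j in seq_len(n_leaves)) {
    blade <- leaf_lab == j
    mv <- if (is.null(midvein_of[[j]])) empty else midvein_of[[j]]
    pt <- if (is.null(petiole_of[[j]])) empty else petiole_of[[j]]
    u <- blade | mv | pt
    bb <- mask_bbox(u)
    r1 <- max(1L, bb["y_min"] + 1L - 2L); r2 <- min(h, bb["y_max"] + 2L)
    c1 <- max(1L, bb["x_min"] + 1L - 2L); c2 <- min(w, bb["x_max"] + 2L)
    leaves[[j]] <- leaf_exemplar(
      patch = raw_image[r1:r2, c1:c2, , drop = FALSE],
      leaf_mask = blade[r1:r2, c1:c2],
      midvein_mask = mv[r1:r2, c1:c2],
      petiole_mask = pt[r1:r2, c1:c2],
      origin = c(c1 - 1L, r1 - 1L),
      source_id = source_id)
  }

  trunk <- NULL
  if (any(trunk_px)) {
    lab <- label_components(trunk_px)
    comp <- lab == which.max(tabulate(lab[lab > 0L]))
    bb <- mask_bbox(comp)
    r1 <- max(1L, bb["y_min"] + 1L - 2L); r2 <- min(h, bb["y_max"] + 2L)
    c1 <- max(1L, bb["x_min"] + 1L - 2L); c2 <- min(w, bb["x_max"] + 2L)
    trunk <- trunk_exemplar(raw_image[r1:r2, c1:c2, , drop = FALSE],
                            comp[r1:r2, c1:c2], source_id = source_id)
  }
  list(leaves = leaves, trunk = trunk)
}
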