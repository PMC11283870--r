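# Exemplar database: build from annotated image pairs, persist, reload.

#' Compute the mount point of a leaf exemplar
#'
#' When the petiole is present the attachment point is its free end: the
#' petiole pixel farthest (Euclidean) from the blade centroid. Without a
#' petiole it falls back to the blade boundary pixel closest to the patch's
#' bottom edge (lowest row; ties broken leftmost). Ties on distance are broken
#' by row-major pixel order, so the result is deterministic and translates
#' with the patch.
#'
#' @param exemplar A [leaf_exemplar()].
#' @return Numeric (x, y) at a pixel center in patch coordinates.
#' @export
compute_attachment_point <- function(exemplar) {
  if (any(exemplar$petiole_mask)) {
    blade <- exemplar$leaf_mask
    cen <- colMeans(mask_pixel_centers(blade))
    p <- mask_pixel_centers(exemplar$petiole_mask)
    d <- (p[, 1] - cen[1])^2 + (p[, 2] - cen[2])^2
    best <- which.max(d)           # first max in row-major order
    return(c(x = unname(p[best, 1]), y = unname(p[best, 2])))
  }
  mask <- exemplar$leaf_mask
  rows <- which(rowSums(mask) > 0)
  r <- rows[length(rows)]
  c <- which(mask[r, ])[1]
  c(x = c - 0.5, y = r - 0.5)
}

#' Candidate leaf mount points along a trunk mask
#'
#' Takes the per-row horizontal midpoint of the trunk mask (snapped to the
#' nearest trunk pixel in that row), restricted to the upper 80% of the
#' trunk's height, and keeps every `stride`-th row. This yields botanically
#' plausible mounts along the stem axis without modelling phyllotaxy.
#'
#' @param trunk_mask Logical matrix.
#' @param stride Row stride between consecutive sites (default 15).
#' @return n x 2 matrix of (x, y) pixel centers, all on the trunk mask.
#' @export
compute_attachment_sites <- function(trunk_mask, stride = 15) {
  rows <- which(rowSums(trunk_mask) > 0)
  top <- rows[1]
  height <- rows[length(rows)] - top + 1L
  upper <- rows[rows < top + 0.8 * height]
  if (!length(upper)) upper <- rows[1]
  keep <- upper[seq(1, length(upper), by = stride)]
  sites <- t(vapply(keep, function(r) {
    cols <- which(trunk_mask[r, ])
    mid <- (cols[1] + cols[length(cols)]) / 2
    c0 <- cols[which.min(abs(cols - mid))]
    c(c0 - 0.5, r - 0.5)
  }, numeric(2)))
  colnames(sites) <- c("x", "y")
  sites
}

#' Build a component database from annotated image pairs
#'
#' Parses each (photograph, annotation map) pair with
#' [parse_annotation_map()] and pools the resulting leaf and trunk exemplars.
#' The number of leaf exemplars equals the total number of annotated blade
#' components across all inputs.
#'
#' @param pairs List of `list(raw = <RGB array>, map = <RGB array>)` pairs
#'   (optionally with an `id` element used as the exemplar source id).
#' @param palette An [annotation_palette()].
#' @return A `component_database` with fields `leaves`, `trunks`, `palette`
#'   and `version`.
#' @export
build_database <- function(pairs, palette = annotation_palette()) {
  stopifnot(length(pairs) >= 1)
  leaves <- list(); trunks <- list()
  for (i in seq_along(pairs)) {
    pair <- pairs[[i]]
    id <- if (!is.null(pair$id)) pair$id else sprintf("pair_%03d", i)
    parsed <- parse_annotation_map(pair$raw, pair$map, palette, source_id = id)
    leaves <- c(leaves, parsed$leaves)
    if (is.null(parsed$trunk)) {
      if (length(parsed$leaves))
        warning("no trunk annotation in ", id, "; leaves stored without a trunk")
    } else {
      trunks <- c(trunks, list(parsed$trunk))
    }
  }
  if (!length(leaves) && !length(trunks))
    stop("no exemplars could be extracted from the supplied pairs")
  message(sprintf("component database: %d leaf and %d trunk exemplars from %d image pairs",
                  length(leaves), length(trunks), length(pairs)))
  structure(list(leaves = leaves, trunks = trunks, palette = palette,
                 version = "plantforge-db-1"),
            class = "component_database")
}

#' @export
print.component_database <- function(x, ...) {
  cat(sprintf("<component_database> %d leaves, %d trunks (%s)\n",
              length(x$leaves), length(x$trunks), x$version))
  invisible(x)
}

#' Persist / reload a component database
#'
#' Layout: `leaves/NNN_{patch,leaf,midvein,petiole}.png`,
#' `trunks/NNN_{patch,mask}.png` and a `db.json` index holding attachment
#' points, origins, source ids and the palette. The round trip is lossless:
#' masks bitwise, attachment points exact.
#'
#' @param db A `component_database`.
#' @param path Database directory.
#' @return `save_database` returns `path` invisibly; `load_database` returns
#'   the database.
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "component_database"))
  dir.create(file.path(path, "leaves"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "trunks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(db$leaves)) {
    ex <- db$leaves[[i]]
    p <- function(kind) file.path(path, "leaves", sprintf("%03d_%s.png", i, kind))
    png::writePNG(ex$patch, p("patch"))
    png::writePNG(ex$leaf_mask * 1, p("leaf"))
    png::writePNG(ex$midvein_mask * 1, p("midvein"))
    png::writePNG(ex$petiole_mask * 1, p("petiole"))
  }
  for (i in seq_along(db$trunks)) {
    ex <- db$trunks[[i]]
    png::writePNG(ex$patch, file.path(path, "trunks", sprintf("%03d_patch.png", i)))
    png::writePNG(ex$trunk_mask * 1, file.path(path, "trunks", sprintf("%03d_mask.png", i)))
  }
  index <- list(
    version = db$version,
    palette = list(colors = db$palette$colors, tolerance = db$palette$tolerance),
    leaves = lapply(db$leaves, function(ex)
      list(attachment_point = unname(ex$attachment_point),
           origin = unname(ex$origin), source_id = ex$source_id)),
    trunks = lapply(db$trunks, function(ex)
      list(attachment_sites = unname(apply(ex$attachment_sites, 1, c, simplify = FALSE)),
           source_id = ex$source_id))
  )
  jsonlite::write_json(index, file.path(path, "db.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_database
#' @export
load_database <- function(path) {
  index_path <- file.path(path, "db.json")
  if (!file.exists(index_path)) stop("no db.json found in ", path)
  index <- jsonlite::read_json(index_path)
  if (!identical(index$version, "plantforge-db-1"))
    stop("database version mismatch: found ", index$version %||% "<none>")
  read_mask <- function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m > 0.5
  }
  leaves <- lapply(seq_along(index$leaves), function(i) {
    meta <- index$leaves[[i]]
    p <- function(kind) file.path(path, "leaves", sprintf("%03d_%s.png", i, kind))
    leaf_exemplar(patch = png::readPNG(p("patch")),
                  leaf_mask = read_mask(p("leaf")),
                  midvein_mask = read_mask(p("midvein")),
                  petiole_mask = read_mask(p("petiole")),
                  attachment_point = stats::setNames(unlist(meta$attachment_point),
                                                     c("x", "y")),
                  origin = unlist(meta$origin), source_id = meta$source_id)
  })
  trunks <- lapply(seq_along(index$trunks), function(i) {
    meta <- index$trunks[[i]]
    sites <- do.call(rbind, lapply(meta$attachment_sites, unlist))
    colnames(sites) <- c("x", "y")
    trunk_exemplar(patch = png::readPNG(file.path(path, "trunks", sprintf("%03d_patch.png", i))),
                   trunk_mask = read_mask(file.path(path, "trunks", sprintf("%03d_mask.png", i))),
                   attachment_sites = sites, source_id = meta$source_id)
  })
  pal <- annotation_palette(leaf = unlist(index$palette$colors$LEAF),
                            midvein = unlist(index$palette$colors$MIDVEIN),
                            petiole = unlist(index$palette$colors$PETIOLE),
                            trunk = unlist(index$palette$colors$TRUNK),
                            tolerance = index$palette$tolerance)
  structure(list(leaves = leaves, trunks = trunks, palette = pal,
                 version = index$version),
            class = "component_database")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
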