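# Synthetic plant scene generation: trunk first, then randomly selected leaf
# exemplars transformed and mounted on trunk attachment sites, composited in
# z-order. Because every pasted pixel is tracked in an ownership buffer, the
# emitted instance annotations are pixel-exact by construction.

#' Synthesis configuration
#'
#' @param n_leaves_range Integer interval for the number of leaves per plant.
#'   The default 5-20 covers sapling-stage plants from sparse to dense.
#' @param scale_range,rotation_range_deg,flip_probability Augmentation
#'   parameters applied to each sampled leaf exemplar. Defaults are
#'   conservative (scale 0.8-1.2, rotation +/-25 deg, flip 0.5) so synthetic
#'   plants keep the structural pattern of real ones.
#' @param occlusion_policy `"visible"` (modal masks: each annotation contains
#'   exactly the pixels where the instance is visible) or `"amodal"` (full
#'   transformed extent, clipped to the canvas).
#' @param min_visible_fraction Leaves whose visible fraction falls below this
#'   are dropped from both the image and the annotations.
#' @param background_color RGB triple in [0, 1]; default near-black, matching
#'   imaging against a high-absorbance black cloth.
#' @param image_size Integer (width, height) of the output canvas.
#' @param seed Integer master seed.
#' @return A `synthesis_config` object.
#' @export
synthesis_config <- function(n_leaves_range = c(5L, 20L),
                             scale_range = c(0.8, 1.2),
                             rotation_range_deg = c(-25, 25),
                             flip_probability = 0.5,
                             occlusion_policy = c("visible", "amodal"),
                             min_visible_fraction = 0.25,
                             background_color = c(0.04, 0.04, 0.04),
                             image_size = c(384L, 512L),
                             seed = 1L) {
  occlusion_policy <- match.arg(occlusion_policy)
  stopifnot(length(n_leaves_range) == 2, n_leaves_range[1] <= n_leaves_range[2],
            n_leaves_range[1] >= 1,
            length(scale_range) == 2, scale_range[1] <= scale_range[2], scale_range[1] > 0,
            length(rotation_range_deg) == 2,
            rotation_range_deg[1] <= rotation_range_deg[2],
            flip_probability >= 0, flip_probability <= 1,
            min_visible_fraction > 0, min_visible_fraction <= 1,
            length(image_size) == 2, all(image_size >= 16))
  structure(list(n_leaves_range = as.integer(n_leaves_range),
                 scale_range = scale_range,
                 rotation_range_deg = rotation_range_deg,
                 flip_probability = flip_probability,
                 occlusion_policy = occlusion_policy,
                 min_visible_fraction = min_visible_fraction,
                 background_color = background_color,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "synthesis_config")
}

# Paste `patch` pixels selected by `mask` onto canvas/owner at integer offset
# (dx, dy) (position of the patch's top-left corner), claiming ownership id.
paste_component <- function(canvas, owner, patch, mask, dx, dy, id) {
  h <- nrow(owner); w <- ncol(owner)
  ph <- nrow(mask); pw <- ncol(mask)
  r1 <- max(1L, dy + 1L); r2 <- min(h, dy + ph)
  c1 <- max(1L, dx + 1L); c2 <- min(w, dx + pw)
  if (r1 > r2 || c1 > c2) return(list(canvas = canvas, owner = owner))
  sub <- mask[(r1 - dy):(r2 - dy), (c1 - dx):(c2 - dx), drop = FALSE]
  if (any(sub)) {
    ow <- owner[r1:r2, c1:c2, drop = FALSE]
    ow[sub] <- id
    owner[r1:r2, c1:c2] <- ow
    for (ch in 1:3) {
      cv <- canvas[r1:r2, c1:c2, ch]
      pv <- patch[(r1 - dy):(r2 - dy), (c1 - dx):(c2 - dx), ch]
      cv[sub] <- pv[sub]
      canvas[r1:r2, c1:c2, ch] <- cv
    }
  }
  list(canvas = canvas, owner = owner)
}

# Embed a patch-frame mask into the full canvas at offset (dx, dy), clipped.
embed_mask <- function(mask, dx, dy, width, height) {
  out <- matrix(FALSE, height, width)
  r1 <- max(1L, dy + 1L); r2 <- min(height, dy + nrow(mask))
  c1 <- max(1L, dx + 1L); c2 <- min(width, dx + ncol(mask))
  if (r1 <= r2 && c1 <= c2)
    out[r1:r2, c1:c2] <- mask[(r1 - dy):(r2 - dy), (c1 - dx):(c2 - dx), drop = FALSE]
  out
}

#' Synthesize one plant scene with pixel-exact annotations
#'
#' Draws a trunk exemplar (scaled to 90% of the canvas height, bottom-centered),
#' samples `n ~ uniform(n_leaves_range)` leaf exemplars with replacement, and
#' composites each - flipped / rotated / scaled, then translated so its
#' attachment point lands on a sampled trunk mount site - in z-order (later
#' over earlier). Leaves with visible fraction below
#' `config$min_visible_fraction` are removed and the scene recomposited; if no
#' leaf survives, sampling is retried once before erroring.
#'
#' @param db A non-empty [build_database()] result with at least one trunk.
#' @param config A [synthesis_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `synthetic_scene`: `image` (RGB array), `annotations` (list of
#'   [instance_annotation()]; the trunk, then per surviving leaf its LEAF
#'   annotation followed by its visible MIDVEIN / PETIOLE annotations, all
#'   sharing the leaf's `instance_id`), and `provenance` (seed, exemplar
#'   indices, transforms, offsets, kept flags).
#' @export
synthesize_plant <- function(db, config = synthesis_config(), seed = config$seed) {
  stopifnot(inherits(db, "component_database"))
  if (!length(db$leaves)) stop("component database has no leaf exemplars")
  if (!length(db$trunks)) stop("component database has no trunk exemplars")
  with_seed(seed, {
    scene <- .synthesize_once(db, config, seed)
    if (is.null(scene)) scene <- .synthesize_once(db, config, seed)
    if (is.null(scene))
      stop("no leaf survived the visibility filter after one regeneration")
    scene
  })
}

.synthesize_once <- function(db, config, seed) {
  w <- config$image_size[1]; h <- config$image_size[2]

  # trunk placement
  t_idx <- sample.int(length(db$trunks), 1)
  tex <- db$trunks[[t_idx]]
  t_rows <- range(which(rowSums(tex$trunk_mask) > 0))
  t_scale <- 0.9 * h / (t_rows[2] - t_rows[1] + 1)
  tt <- transform_raster(tex$patch, list(mask = tex$trunk_mask),
                         tex$attachment_sites, FALSE, 0, t_scale)
  t_bb <- mask_bbox(tt$masks$mask)
  t_dx <- as.integer(round(w / 2 - (t_bb["x_min"] + t_bb["x_max"]) / 2))
  t_dy <- as.integer(h - t_bb["y_max"])
  sites <- sweep(tt$points, 2, c(t_dx, t_dy), "+")

  # leaf sampling
  n <- config$n_leaves_range[1] +
    sample.int(config$n_leaves_range[2] - config$n_leaves_range[1] + 1L, 1) - 1L
  picks <- lapply(seq_len(n), function(i) {
    li <- sample.int(length(db$leaves), 1)
    flip <- stats::runif(1) < config$flip_probability
    ang <- stats::runif(1, config$rotation_range_deg[1], config$rotation_range_deg[2])
    sc <- stats::runif(1, config$scale_range[1], config$scale_range[2])
    site <- sites[sample.int(nrow(sites), 1), ]
    tr <- tryCatch(transform_exemplar(db$leaves[[li]], flip, ang, sc),
                   error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    off <- round(site - tr$attachment_point)
    list(exemplar = li, flip = flip, angle_deg = ang, scale = sc,
         offset = as.integer(off), transformed = tr, kept = TRUE)
  })
  picks <- Filter(Negate(is.null), picks)
  if (!length(picks)) return(NULL)

  compose <- function(active) {
    canvas <- blank_image(w, h, config$background_color)
    owner <- matrix(0L, h, w)
    pc <- paste_component(canvas, owner, tt$patch, tt$masks$mask, t_dx, t_dy, 1L)
    canvas <- pc$canvas; owner <- pc$owner
    for (i in seq_along(picks)) {
      if (!active[i]) next
      p <- picks[[i]]
      region <- exemplar_region(p$transformed)
      pc <- paste_component(canvas, owner, p$transformed$patch, region,
                            p$offset[1], p$offset[2], i + 1L)
      canvas <- pc$canvas; owner <- pc$owner
    }
    list(canvas = canvas, owner = owner)
  }

  active <- rep(TRUE, length(picks))
  cm <- compose(active)
  vis_frac <- vapply(seq_along(picks), function(i) {
    sum(cm$owner == i + 1L) / sum(exemplar_region(picks[[i]]$transformed))
  }, numeric(1))
  drop <- active & vis_frac < config$min_visible_fraction
  if (any(drop)) {
    active[drop] <- FALSE
    if (!any(active)) return(NULL)
    cm <- compose(active)
  }

  annotations <- list()
  trunk_vis <- cm$owner == 1L
  trunk_full <- embed_mask(tt$masks$mask, t_dx, t_dy, w, h)
  t_mask <- if (config$occlusion_policy == "visible") trunk_vis else trunk_full
  if (any(t_mask))
    annotations[[length(annotations) + 1L]] <-
      instance_annotation("TRUNK", t_mask, instance_id = 0L)

  for (i in seq_along(picks)) {
    if (!active[i]) next
    p <- picks[[i]]
    visible <- cm$owner == i + 1L
    full <- embed_mask(exemplar_region(p$transformed), p$offset[1], p$offset[2], w, h)
    leaf_mask <- if (config$occlusion_policy == "visible") visible else full
    if (!any(leaf_mask)) next
    annotations[[length(annotations) + 1L]] <-
      instance_annotation("LEAF", leaf_mask, instance_id = i)
    for (organ in c("midvein", "petiole")) {
      om <- embed_mask(p$transformed[[paste0(organ, "_mask")]],
                       p$offset[1], p$offset[2], w, h)
      om <- if (config$occlusion_policy == "visible") om & visible else om
      if (any(om))
        annotations[[length(annotations) + 1L]] <-
          instance_annotation(toupper(organ), om, instance_id = i)
    }
  }
  if (length(annotations) <= 1) return(NULL)

  provenance <- list(
    seed = seed,
    trunk = list(exemplar = t_idx, scale = t_scale, offset = c(t_dx, t_dy)),
    leaves = lapply(picks, function(p)
      p[c("exemplar", "flip", "angle_deg", "scale", "offset", "kept")]))
  for (i in seq_along(picks)) provenance$leaves[[i]]$kept <- active[i]

  structure(list(image = cm$canvas, annotations = annotations,
                 provenance = provenance, config = config),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cls <- vapply(x$annotations, function(a) a$class, character(1))
  cat(sprintf("<synthetic_scene> %dx%d, %d annotations (%s)\n",
              ncol(x$image), nrow(x$image), length(cls),
              paste(sprintf("%s=%d", names(table(cls)), table(cls)), collapse = ", ")))
  invisible(x)
}

#' Generate a dataset of synthetic scenes
#'
#' Writes `n_images` scenes (per-image seeds drawn from the master seed) in
#' the requested annotation formats plus a manifest CSV recording the
#' train/validation split at `split_ratio` (default 2:1).
#'
#' @param db A [build_database()] result.
#' @param config A [synthesis_config()]; `config$seed` is the master seed.
#' @param n_images Number of scenes.
#' @param out_dir Output directory.
#' @param formats Subset of `c("masks", "yolo")`.
#' @param split_ratio Numeric (train, val) ratio.
#' @return The manifest data frame (invisibly), also written to
#'   `manifest.csv`.
#' @export
generate_dataset <- function(db, config, n_images, out_dir,
                             formats = c("masks", "yolo"),
                             split_ratio = c(2, 1)) {
  stopifnot(n_images >= 1)
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  if ("yolo" %in% formats)
    dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, n_images))
  n_train <- round(n_images * split_ratio[1] / sum(split_ratio))
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    scene <- synthesize_plant(db, config, seed = seeds[i])
    stem <- sprintf("img_%04d", i)
    png::writePNG(scene$image, file.path(out_dir, "images", paste0(stem, ".png")))
    if ("masks" %in% formats)
      write_mask_dataset(scene$annotations, file.path(out_dir, "masks", stem))
    if ("yolo" %in% formats)
      write_yolo_file(lapply(scene$annotations, mask_to_polygon),
                      file.path(out_dir, "labels", paste0(stem, ".txt")))
    rows[[i]] <- data.frame(image = paste0("images/", stem, ".png"),
                            split = if (i <= n_train) "train" else "val",
                            seed = seeds[i],
                            n_annotations = length(scene$annotations))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
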