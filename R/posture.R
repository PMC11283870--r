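# Leaf growth posture digitization: organ matching by IoU, line fitting, and
# horizontal angle computation.
#
# For each segmented leaf region the petiole with the highest
# intersection-over-union against the leaf is selected, then the midvein in
# the same way; a straight line y = kx + b is fitted to the organ's pixels by
# least squares and the horizontal angle is atan(k). Angles are reported in
# degrees in (-90, 90], math convention (positive = pointing above the
# horizontal).

#' Extract per-class instance annotations from an annotation map
#'
#' Builds the instance lists a segmenter trained on this material would
#' output. Leaf regions include the midvein and petiole regions of the leaf
#' (as in the source annotations, where the leaf ROI contains its organs),
#' so organ-to-leaf IoU matching is well-posed; organ instances are their
#' own color components. Association of an organ to its blade uses
#' [parse_annotation_map()]'s overlap-then-adjacency rule, but the returned
#' lists are unordered instance pools - pairing them back up is
#' [match_components()]' job.
#'
#' @param annotation_map RGB array with palette colors.
#' @param palette An [annotation_palette()].
#' @return `list(leaves, petioles, midveins)`, each a list of
#'   [instance_annotation()] objects on the full image grid.
#' @export
annotation_map_to_instances <- function(annotation_map, palette = annotation_palette()) {
  parsed <- parse_annotation_map(annotation_map, annotation_map, palette)
  h <- dim(annotation_map)[1]; w <- dim(annotation_map)[2]
  leaves <- list(); petioles <- list(); midveins <- list()
  for (i in seq_along(parsed$leaves)) {
    ex <- parsed$leaves[[i]]
    dx <- ex$origin[1]; dy <- ex$origin[2]
    leaves[[length(leaves) + 1L]] <-
      instance_annotation("LEAF", embed_mask(exemplar_region(ex), dx, dy, w, h),
                          instance_id = i)
    if (any(ex$petiole_mask))
      petioles[[length(petioles) + 1L]] <-
        instance_annotation("PETIOLE", embed_mask(ex$petiole_mask, dx, dy, w, h),
                            instance_id = i)
    if (any(ex$midvein_mask))
      midveins[[length(midveins) + 1L]] <-
        instance_annotation("MIDVEIN", embed_mask(ex$midvein_mask, dx, dy, w, h),
                            instance_id = i)
  }
  list(leaves = leaves, petioles = petioles, midveins = midveins)
}

# IoU between two annotations, using bbox prefilter for speed.
annotation_iou <- function(a, b) {
  if (a$bbox["x_max"] <= b$bbox["x_min"] || b$bbox["x_max"] <= a$bbox["x_min"] ||
      a$bbox["y_max"] <= b$bbox["y_min"] || b$bbox["y_max"] <= a$bbox["y_min"])
    return(0)
  mask_iou(a$mask, b$mask)
}

#' Match petioles and midveins to leaves by IoU
#'
#' Greedy assignment: leaves are visited in descending area order; each takes
#' the unassigned petiole with the highest IoU against its region, then the
#' unassigned midvein in the same way. Zero-IoU candidates are never
#' assigned, and no organ serves two leaves. Ties on IoU are broken by the
#' smaller candidate index.
#'
#' @param leaves,petioles,midveins Lists of [instance_annotation()] objects on
#'   a common image grid.
#' @return List of `leaf_group` objects: `leaf`, `petiole` (or `NULL`),
#'   `midvein` (or `NULL`), `match_scores`, `leaf_index` (position in the
#'   input list).
#' @export
match_components <- function(leaves, petioles = list(), midveins = list()) {
  if (!length(leaves)) return(list())
  areas <- vapply(leaves, function(a) sum(a$mask), numeric(1))
  order_idx <- order(-areas)
  pet_free <- rep(TRUE, length(petioles))
  mid_free <- rep(TRUE, length(midveins))
  take_best <- function(leaf, candidates, free) {
    best <- 0L; best_iou <- 0
    for (j in seq_along(candidates)) {
      if (!free[j]) next
      v <- annotation_iou(leaf, candidates[[j]])
      if (v > best_iou) { best_iou <- v; best <- j }
    }
    list(idx = best, iou = best_iou)
  }
  groups <- vector("list", length(leaves))
  for (i in order_idx) {
    leaf <- leaves[[i]]
    bp <- take_best(leaf, petioles, pet_free)
    if (bp$idx > 0L) pet_free[bp$idx] <- FALSE
    bm <- take_best(leaf, midveins, mid_free)
    if (bm$idx > 0L) mid_free[bm$idx] <- FALSE
    groups[[i]] <- structure(list(
      leaf = leaf,
      petiole = if (bp$idx > 0L) petioles[[bp$idx]] else NULL,
      midvein = if (bm$idx > 0L) midveins[[bm$idx]] else NULL,
      match_scores = c(petiole = bp$iou, midvein = bm$iou),
      leaf_index = i), class = "leaf_group")
  }
  n_unmatched <- sum(pet_free) + sum(mid_free)
  if (n_unmatched > 0)
    message(n_unmatched, " organ instance(s) left unmatched")
  groups
}

#' Fit a straight line to a pixel point set
#'
#' Least-squares fit of `y = kx + b` in math convention (y up). When the
#' points spread more vertically than horizontally the axes are swapped
#' before fitting (`x = k'y + b'`) and the result is flagged, which keeps the
#' fit well-posed for near-vertical organs such as fully wilted petioles.
#'
#' @param pixels Two-column matrix of (x, y) points (see
#'   [mask_pixels_math()]).
#' @param min_fit_pixels Minimum number of points (default 10).
#' @return A `fitted_line`: `k`, `b`, `n_points`, `axis_swapped`.
#' @export
fit_line <- function(pixels, min_fit_pixels = 10) {
  pixels <- as.matrix(pixels)
  n <- nrow(pixels)
  if (n < min_fit_pixels)
    stop("TOO_FEW_PIXELS: ", n, " < ", min_fit_pixels)
  x <- pixels[, 1]; y <- pixels[, 2]
  x_spread <- diff(range(x)); y_spread <- diff(range(y))
  if (x_spread == 0 && y_spread == 0) stop("degenerate point set: zero spread in both axes")
  swapped <- x_spread < y_spread
  if (swapped) { tmp <- x; x <- y; y <- tmp }
  xm <- mean(x); ym <- mean(y)
  k <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  b <- ym - k * xm
  structure(list(k = k, b = b, n_points = n, axis_swapped = swapped),
            class = "fitted_line")
}

#' Horizontal angle of a fitted line
#'
#' `atan(k)` in degrees for ordinary fits; for axis-swapped fits (line
#' `x = k'y + b'`) the angle is `sign(k') * 90 - atan(k')`, which maps the
#' same geometric line into the reporting interval. Output in (-90, 90].
#'
#' @param line A [fit_line()] result.
#' @return Angle in degrees.
#' @export
horizontal_angle <- function(line) {
  stopifnot(inherits(line, "fitted_line"))
  deg <- atan(line$k) * 180 / pi
  if (!line$axis_swapped) return(deg)
  s <- if (line$k >= 0) 1 else -1
  s * 90 - deg
}

#' Compute leaf postures from matched groups
#'
#' One posture per group: the petiole's horizontal angle (alpha) and the
#' midvein's (beta), both from least-squares line fits on the organ pixels
#' converted to math convention. Groups lacking a petiole or midvein, or
#' whose organ covers fewer than `min_fit_pixels` pixels, are flagged invalid
#' with a reason (`NO_PETIOLE`, `NO_MIDVEIN`, `TOO_FEW_PIXELS`) and carry NA
#' angles.
#'
#' @param groups List of groups from [match_components()].
#' @param min_fit_pixels Minimum organ pixel count for a line fit.
#' @return Data frame: `leaf_index`, `alpha_deg`, `beta_deg`, `valid`,
#'   `reason`.
#' @export
compute_postures <- function(groups, min_fit_pixels = 10) {
  rows <- lapply(groups, function(g) {
    out <- data.frame(leaf_index = g$leaf_index, alpha_deg = NA_real_,
                      beta_deg = NA_real_, valid = FALSE, reason = "OK")
    if (is.null(g$petiole)) { out$reason <- "NO_PETIOLE"; return(out) }
    if (is.null(g$midvein)) { out$reason <- "NO_MIDVEIN"; return(out) }
    h <- g$leaf$image_size[["height"]]
    ang <- tryCatch({
      a <- horizontal_angle(fit_line(mask_pixels_math(g$petiole$mask, h), min_fit_pixels))
      b <- horizontal_angle(fit_line(mask_pixels_math(g$midvein$mask, h), min_fit_pixels))
      c(a, b)
    }, error = function(e) {
      if (grepl("TOO_FEW_PIXELS", conditionMessage(e))) NULL else stop(e)
    })
    if (is.null(ang)) { out$reason <- "TOO_FEW_PIXELS"; return(out) }
    out$alpha_deg <- ang[1]; out$beta_deg <- ang[2]; out$valid <- TRUE
    out
  })
  do.call(rbind, rows)
}

# Signed angular difference on the axial (mod 180 deg) scale, in (-90, 90].
wrap_angle_180 <- function(delta) {
  d <- (delta + 90) %% 180 - 90
  ifelse(d == -90, 90, d)
}

#' Score predicted angles against a reference table
#'
#' Matches rows by `id`, computes signed errors on the axial (mod 180) scale,
#' the mean absolute error and the fraction of errors within +/-5 degrees.
#'
#' @param predicted,reference Data frames with columns `id` and `angle_deg`.
#' @return List: `mae_deg`, `errors` (signed, per matched leaf),
#'   `within_pm5_fraction`, `n`.
#' @export
evaluate_angles <- function(predicted, reference) {
  m <- merge(predicted, reference, by = "id", suffixes = c("_pred", "_ref"))
  if (!nrow(m)) stop("no common ids between predicted and reference tables")
  err <- wrap_angle_180(m$angle_deg_pred - m$angle_deg_ref)
  list(mae_deg = mean(abs(err)), errors = err,
       within_pm5_fraction = mean(abs(err) <= 5), n = nrow(m))
}

#' Per-group posture statistics
#'
#' Summarizes valid postures per irrigation group: mean, sd (0 for singleton
#' groups), median, quartiles and count, for both angles. Groups without
#' valid postures are omitted with a warning.
#'
#' @param postures Data frame with columns `group`, `alpha_deg`, `beta_deg`
#'   and optionally `valid` (rows with `valid == FALSE` are excluded).
#' @return Data frame: `group`, `angle` (`"alpha"`/`"beta"`), `mean`, `sd`,
#'   `median`, `q25`, `q75`, `n`.
#' @export
group_statistics <- function(postures) {
  groups <- unique(postures$group)
  if (!is.null(postures$valid)) postures <- postures[postures$valid, , drop = FALSE]
  rows <- list()
  for (g in groups) {
    sub <- postures[postures$group == g, , drop = FALSE]
    for (angle in c("alpha", "beta")) {
      v <- sub[[paste0(angle, "_deg")]]
      v <- v[is.finite(v)]
      if (!length(v)) next
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, angle = angle, mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else 0,
        median = q[2], q25 = q[1], q75 = q[3], n = length(v))
    }
  }
  missing <- setdiff(groups, unique(vapply(rows, function(r) r$group, character(1))))
  if (length(missing))
    warning("groups with no valid postures omitted: ", paste(missing, collapse = ", "))
  if (!length(rows)) stop("no group has any valid posture")
  do.call(rbind, rows)
}

#' Box-plot of per-group angle distributions
#'
#' @param postures As in [group_statistics()].
#' @param file PNG output path.
#' @param angle `"alpha"` or `"beta"`.
#' @return `file`, invisibly.
#' @export
plot_group_angles <- function(postures, file, angle = c("beta", "alpha")) {
  angle <- match.arg(angle)
  if (!is.null(postures$valid)) postures <- postures[postures$valid, , drop = FALSE]
  grDevices::png(file, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  graphics::boxplot(stats::as.formula(paste0(angle, "_deg ~ group")), data = postures,
                    ylab = sprintf("%s horizontal angle (deg)",
                                   if (angle == "alpha") "petiole" else "midvein"),
                    xlab = "irrigation group")
  invisible(file)
}
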