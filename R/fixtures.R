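# Procedural fixture plants with known ground-truth geometry.
#
# Each fixture leaf is an elliptical blade carrying a straight midvein stripe,
# attached through a straight petiole stripe, drawn on a near-black background
# (emulating imaging against a high-absorbance black cloth) together with a
# palette-coded annotation map and a table of true angles. Angles are given in
# math convention (y up, degrees, positive = above horizontal); rendering
# flips the y axis in one place (the direction vectors below).

#' Specify one fixture leaf
#'
#' @param attachment Numeric (x, y), image pixel coordinates, where the
#'   petiole meets the trunk.
#' @param petiole_angle_deg,midvein_angle_deg True horizontal angles (alpha,
#'   beta) in degrees, math convention, in (-90, 90].
#' @param blade_a,blade_b Blade ellipse semi-axes (along / across the midvein)
#'   in pixels.
#' @param petiole_length Petiole length in pixels. Least-squares line fits on
#'   a stripe of length l and width w attenuate the slope by
#'   (l^2 - w^2) / (l^2 + w^2), so the default 30 px (with 3 px width) keeps
#'   the worst-case (45 degree) recovery error under 1 degree.
#' @param stripe_width Stripe thickness in pixels for midvein and petiole.
#' @return A `leaf_spec` list.
#' @export
leaf_spec <- function(attachment, petiole_angle_deg, midvein_angle_deg,
                      blade_a = 16, blade_b = 10, petiole_length = 30,
                      stripe_width = 3) {
  stopifnot(petiole_angle_deg > -90, petiole_angle_deg <= 90,
            midvein_angle_deg > -90, midvein_angle_deg <= 90,
            blade_a > 0, blade_b > 0, petiole_length > 0, stripe_width >= 1)
  structure(list(attachment = as.numeric(attachment),
                 petiole_angle_deg = petiole_angle_deg,
                 midvein_angle_deg = midvein_angle_deg,
                 blade_a = blade_a, blade_b = blade_b,
                 petiole_length = petiole_length,
                 stripe_width = stripe_width),
            class = "leaf_spec")
}

#' Pixel-center coordinate grids for an image
#'
#' @param width,height Image size in pixels.
#' @return `list(x, y)` of height x width matrices holding the 0-based pixel
#'   center coordinates.
#' @export
pixel_grid <- function(width, height) {
  list(x = matrix(rep(seq_len(width) - 0.5, each = height), height, width),
       y = matrix(rep(seq_len(height) - 0.5, times = width), height, width))
}

# Mask of pixels within dist w/2 of segment p0-p1 (capsule), image coords.
capsule_mask <- function(grid, p0, p1, width) {
  d <- p1 - p0
  len2 <- sum(d^2)
  vx <- grid$x - p0[1]; vy <- grid$y - p0[2]
  t <- if (len2 > 0) pmin(pmax((vx * d[1] + vy * d[2]) / len2, 0), 1) else 0
  dx <- vx - t * d[1]; dy <- vy - t * d[2]
  dx^2 + dy^2 <= (width / 2)^2
}

# Rotated ellipse mask; u is the unit vector of the major axis, image coords.
ellipse_mask_at <- function(grid, center, a, b, u) {
  dx <- grid$x - center[1]; dy <- grid$y - center[2]
  p <- dx * u[1] + dy * u[2]
  q <- -dx * u[2] + dy * u[1]
  (p / a)^2 + (q / b)^2 <= 1
}

# Leaf geometry in image coordinates. The y flip (math -> image) happens here.
leaf_geometry <- function(spec) {
  ua <- c(cos(spec$petiole_angle_deg * pi / 180), -sin(spec$petiole_angle_deg * pi / 180))
  ub <- c(cos(spec$midvein_angle_deg * pi / 180), -sin(spec$midvein_angle_deg * pi / 180))
  if (spec$attachment[3] < 0) { ua[1] <- -ua[1]; ub[1] <- -ub[1] }  # left-side leaf
  att <- spec$attachment[1:2]
  tip <- att + spec$petiole_length * ua            # proximal blade tip
  center <- tip + spec$blade_a * ub
  list(ua = ua, ub = ub, attachment = att, tip = tip, center = center)
}

#' Render a fixture plant with its annotation map and ground truth
#'
#' Draws colored organs on a near-black background plus a palette-coded
#' annotation map. The midvein stripe runs along the blade's major axis
#' (inset from the proximal tip so the blade stays 8-connected around it);
#' the petiole stripe runs from the attachment point to the blade edge and
#' 2 px inside it, so organ-to-blade assignment by overlap succeeds.
#'
#' @param specs List of [leaf_spec()] objects. A third attachment element
#'   of -1 mirrors the leaf to point left.
#' @param image_size Integer (width, height).
#' @param trunk `NULL`, or a list with `x` (column), `width`, and optional
#'   `top`/`bottom` rows for a vertical trunk bar.
#' @param palette An [annotation_palette()].
#' @param noise_sd Gaussian pixel noise added to the raw image.
#' @param seed Seed for the pixel noise.
#' @param overlap_ok Allow leaves to overlap (default FALSE: error).
#' @param blade_color,midvein_color,petiole_color Raw-image organ colors in
#'   [0, 1] (the annotation map always uses the palette colors).
#' @param red_tint Constant added to the raw image's red channel (drought
#'   browning in classification fixtures).
#' @return `list(raw, map, truth)` where `truth` has one row per leaf:
#'   `leaf_id, alpha_deg, beta_deg, center_x, center_y, attachment_x,
#'   attachment_y`.
#' @export
render_fixture_plant <- function(specs, image_size = c(256L, 256L), trunk = NULL,
                                 palette = annotation_palette(), noise_sd = 0.015,
                                 seed = 1L, overlap_ok = FALSE,
                                 blade_color = c(0.10, 0.62, 0.12),
                                 midvein_color = c(0.75, 0.78, 0.20),
                                 petiole_color = c(0.45, 0.30, 0.15),
                                 red_tint = 0) {
  w <- as.integer(image_size[1]); h <- as.integer(image_size[2])
  grid <- pixel_grid(w, h)
  raw <- blank_image(w, h, c(0.03, 0.03, 0.03))
  map <- blank_image(w, h, c(0, 0, 0))
  paint <- function(img, mask, color) {
    for (ch in 1:3) { pl <- img[, , ch]; pl[mask] <- color[ch]; img[, , ch] <- pl }
    img
  }
  if (!is.null(trunk)) {
    top <- trunk$top %||% round(0.08 * h); bottom <- trunk$bottom %||% h
    tw <- trunk$width %||% 6
    tmask <- grid$x >= trunk$x - tw / 2 & grid$x <= trunk$x + tw / 2 &
      grid$y >= top & grid$y <= bottom
    raw <- paint(raw, tmask, c(0.35, 0.22, 0.10))
    map <- paint(map, tmask, palette$colors$TRUNK / 255)
  }
  truth <- vector("list", length(specs))
  prev_regions <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    if (length(spec$attachment) < 3) spec$attachment <- c(spec$attachment, 1)
    g <- leaf_geometry(spec)
    blade <- ellipse_mask_at(grid, g$center, spec$blade_a, spec$blade_b, g$ub)
    mv <- capsule_mask(grid, g$tip + 0.25 * spec$blade_a * g$ub,
                       g$center + 0.75 * spec$blade_a * g$ub, spec$stripe_width) & blade
    # petiole clipped to outside the blade so the green component never splits;
    # blade association relies on the parser's adjacency fallback
    pet <- capsule_mask(grid, g$attachment, g$tip + 2 * g$ua, spec$stripe_width)
    pet <- pet & !mv & !blade
    blade_only <- blade & !mv & !pet
    region <- blade | pet
    if (!overlap_ok) {
      for (pr in prev_regions)
        if (any(region & pr)) stop("fixture leaves ", i, " overlap; adjust the layout")
      prev_regions[[length(prev_regions) + 1L]] <- region
    }
    raw <- paint(raw, blade_only, blade_color)
    raw <- paint(raw, mv, midvein_color)
    raw <- paint(raw, pet, petiole_color)
    map <- paint(map, blade_only, palette$colors$LEAF / 255)
    map <- paint(map, mv, palette$colors$MIDVEIN / 255)
    map <- paint(map, pet, palette$colors$PETIOLE / 255)
    truth[[i]] <- data.frame(leaf_id = i,
                             alpha_deg = spec$petiole_angle_deg,
                             beta_deg = spec$midvein_angle_deg,
                             center_x = g$center[1], center_y = g$center[2],
                             attachment_x = g$attachment[1],
                             attachment_y = g$attachment[2])
  }
  if (red_tint > 0) raw[, , 1] <- raw[, , 1] + red_tint
  if (noise_sd > 0)
    raw <- raw + with_seed(seed, array(stats::rnorm(length(raw), 0, noise_sd), dim(raw)))
  raw <- pmin(pmax(raw, 0), 1)
  list(raw = raw, map = map, truth = do.call(rbind, truth))
}

#' Lay fixture leaves out on a non-overlapping grid
#'
#' Places one leaf per grid cell with the attachment point near the cell
#' center (shifted left so the rightward-pointing leaf stays inside the
#' cell).
#'
#' @param alpha_deg,beta_deg Vectors of true angles (math convention).
#' @param cell Cell edge length in pixels; 128 accommodates the default leaf
#'   geometry at any angle in (-90, 90].
#' @param ncol_grid Number of cells per row.
#' @return `list(specs, image_size)` ready for [render_fixture_plant()].
#' @export
layout_leaf_grid <- function(alpha_deg, beta_deg, cell = 128, ncol_grid = 4) {
  stopifnot(length(alpha_deg) == length(beta_deg))
  n <- length(alpha_deg)
  nrow_grid <- ceiling(n / ncol_grid)
  specs <- lapply(seq_len(n), function(i) {
    gc <- (i - 1) %% ncol_grid
    gr <- (i - 1) %/% ncol_grid
    leaf_spec(attachment = c(gc * cell + cell / 2 - 30, gr * cell + cell / 2),
              petiole_angle_deg = alpha_deg[i], midvein_angle_deg = beta_deg[i])
  })
  list(specs = specs,
       image_size = c(as.integer(ncol_grid * cell), as.integer(nrow_grid * cell)))
}

# Default angle populations per irrigation group (degrees, math convention).
# Chosen to mirror the qualitative ordering severe drought < moderate drought
# < rewatered <= control; the magnitudes are package choices, not measured
# values.
.group_angle_params <- list(
  CK = c(mean = 25, sd = 8),
  MD = c(mean = 5, sd = 8),
  SD = c(mean = -35, sd = 10),
  NW = c(mean = 30, sd = 8),
  MW = c(mean = 15, sd = 8)
)

#' Sample leaf angle populations for an irrigation group
#'
#' Draws petiole and midvein angles independently from the group's normal
#' distribution (clamped to (-85, 85)), encoding the qualitative structure
#' that severe drought droops leaves below moderate drought, which droops
#' below rewatered and control groups.
#'
#' @param group One of `"CK"`, `"MD"`, `"SD"`, `"NW"`, `"MW"` (control,
#'   moderate drought, severe drought, severe + normal rewatering, severe +
#'   moderate rewatering).
#' @param n_leaves Number of leaves.
#' @param seed Integer seed.
#' @param params Optional named list overriding the per-group `(mean, sd)`.
#' @return Data frame with columns `group`, `alpha_deg`, `beta_deg`.
#' @export
sample_drought_population <- function(group = c("CK", "MD", "SD", "NW", "MW"),
                                      n_leaves, seed = 1L, params = NULL) {
  group <- match.arg(group)
  stopifnot(n_leaves >= 1)
  p <- (params %||% .group_angle_params)[[group]]
  with_seed(seed, {
    clamp <- function(v) pmin(pmax(v, -85), 85)
    data.frame(group = group,
               alpha_deg = clamp(stats::rnorm(n_leaves, p["mean"], p["sd"])),
               beta_deg = clamp(stats::rnorm(n_leaves, p["mean"], p["sd"])))
  })
}

#' Render a labeled classification fixture set
#'
#' Small fixture plants whose two label factors are encoded independently:
#' the variety controls blade shape (aspect ratio) and blade green level;
#' the stress level controls the leaf angle distribution and a global red
#' tint (drought browning). Both factors are therefore recoverable from an
#' image, and permuting one never changes statistics of the other.
#'
#' @param n_varieties,n_levels Number of classes per factor.
#' @param n_per_cell Images per (variety, level) cell.
#' @param image_size Integer (width, height).
#' @param seed Integer master seed.
#' @return `list(images = <list of RGB arrays>, labels = <data frame with
#'   variety, stress_level (0-based), plant_id, timepoint>)`.
#' @export
render_classification_dataset <- function(n_varieties = 4, n_levels = 5,
                                          n_per_cell = 20,
                                          image_size = c(112L, 112L), seed = 1L) {
  stopifnot(n_varieties >= 1, n_varieties <= 6, n_levels >= 1, n_levels <= 5)
  # variety drives foliage color in two channels (opposite directions, so the
  # green/blue ratio identifies the variety independently of blade area) plus
  # the blade aspect ratio; stress drives angles and a global red tint only
  variety_green <- seq(0.35, 0.95, length.out = n_varieties)
  variety_blue <- seq(0.60, 0.05, length.out = n_varieties)
  variety_aspect <- seq(0.45, 0.85, length.out = n_varieties)
  level_groups <- c("CK", "NW", "SD", "MW", "MD")[seq_len(n_levels)]
  level_tint <- seq(0, 0.28, length.out = n_levels)
  w <- image_size[1]; h <- image_size[2]
  images <- list(); labels <- list()
  plant <- 0L
  sub_seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                                 n_varieties * n_levels * n_per_cell),
                                      nrow = n_per_cell))
  cell <- 0L
  for (v in seq_len(n_varieties)) for (s in seq_len(n_levels)) {
    cell <- cell + 1L
    for (k in seq_len(n_per_cell)) {
      plant <- plant + 1L
      sd_k <- sub_seeds[k, cell]
      ang <- sample_drought_population(level_groups[s], 4, seed = sd_k)
      side <- rep(c(1, -1), 2)
      specs <- lapply(1:4, function(j) {
        sp <- leaf_spec(attachment = c(w / 2 + side[j] * 2, 0.30 * h + 0.16 * h * (j - 1), side[j]),
                        petiole_angle_deg = ang$alpha_deg[j],
                        midvein_angle_deg = ang$beta_deg[j],
                        blade_a = 11, blade_b = 11 * variety_aspect[v],
                        petiole_length = 12, stripe_width = 2)
        sp
      })
      img <- render_fixture_plant(specs, image_size = image_size,
                                  trunk = list(x = w / 2, width = 4),
                                  noise_sd = 0.02, seed = sd_k, overlap_ok = TRUE,
                                  blade_color = c(0.10, variety_green[v], variety_blue[v]),
                                  red_tint = level_tint[s])$raw
      images[[plant]] <- img
      labels[[plant]] <- data.frame(variety = v - 1L, stress_level = s - 1L,
                                    plant_id = plant, timepoint = 1L)
    }
  }
  list(images = images, labels = do.call(rbind, labels))
}
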