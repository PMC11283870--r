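# Shared test helpers: tiny annotation maps, random masks, and independent
# oracles (pixel bookkeeping, exhaustive assignment, sequential painting).

pal <- annotation_palette()

# Blank RGB array filled with a 0-255 color.
solid_map <- function(width, height, color = c(0, 0, 0)) {
  blank_image(width, height, color / 255)
}

# Paint a 0-255 palette color over mask pixels of an RGB array.
paint_color <- function(img, mask, color) {
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[mask] <- color[ch] / 255
    img[, , ch] <- pl
  }
  img
}

rect_mask <- function(width, height, rows, cols) {
  m <- matrix(FALSE, height, width)
  m[rows, cols] <- TRUE
  m
}

# Random blob: union of 1-3 random filled ellipses (simply connected in most
# draws; always non-empty).
random_blob_mask <- function(width = 48, height = 48) {
  g <- pixel_grid(width, height)
  m <- matrix(FALSE, height, width)
  for (k in seq_len(sample(1:3, 1))) {
    cx <- runif(1, 10, width - 10); cy <- runif(1, 10, height - 10)
    a <- runif(1, 3, 10); b <- runif(1, 3, 10); th <- runif(1, 0, pi)
    u <- c(cos(th), sin(th))
    dx <- g$x - cx; dy <- g$y - cy
    p <- dx * u[1] + dy * u[2]; q <- -dx * u[2] + dy * u[1]
    m <- m | ((p / a)^2 + (q / b)^2 <= 1)
  }
  if (!any(m)) m[round(height / 2), round(width / 2)] <- TRUE
  m
}

# Random convex mask (one ellipse) with area >= min_area.
random_convex_mask <- function(width = 48, height = 48, min_area = 100) {
  repeat {
    g <- pixel_grid(width, height)
    cx <- runif(1, 14, width - 14); cy <- runif(1, 14, height - 14)
    a <- runif(1, 6, 12); b <- runif(1, 6, 12); th <- runif(1, 0, pi)
    u <- c(cos(th), sin(th))
    dx <- g$x - cx; dy <- g$y - cy
    p <- dx * u[1] + dy * u[2]; q <- -dx * u[2] + dy * u[1]
    m <- (p / a)^2 + (q / b)^2 <= 1
    if (sum(m) >= min_area) return(m)
  }
}

# Two-leaf annotation map: disjoint green blobs, each with a yellow stripe
# inside and a red stripe crossing the boundary.
two_leaf_map <- function() {
  img <- solid_map(64, 40)
  blade1 <- rect_mask(64, 40, 5:15, 8:28)
  mv1 <- rect_mask(64, 40, 9:11, 12:24)
  pet1 <- rect_mask(64, 40, 9:11, 2:9)       # crosses into blade1
  blade2 <- rect_mask(64, 40, 22:36, 30:52)
  mv2 <- rect_mask(64, 40, 28:30, 34:48)
  pet2 <- rect_mask(64, 40, 28:30, 53:60)    # touches blade2's right edge
  img <- paint_color(img, blade1 & !mv1 & !pet1, c(0, 255, 0))
  img <- paint_color(img, blade2 & !mv2 & !pet2, c(0, 255, 0))
  img <- paint_color(img, mv1 | mv2, c(255, 255, 0))
  img <- paint_color(img, pet1 | pet2, c(255, 0, 0))
  list(map = img,
       blades = list(blade1 & !mv1 & !pet1, blade2 & !mv2 & !pet2),
       midveins = list(mv1, mv2), petioles = list(pet1, pet2))
}

# Small component database built from fixture plants (with trunks).
make_test_db <- function(seed = 11, n_images = 2) {
  with_seed(seed, {
    pairs <- lapply(seq_len(n_images), function(i) {
      lay <- layout_leaf_grid(runif(4, -60, 60), runif(4, -60, 60))
      fx <- render_fixture_plant(lay$specs, image_size = lay$image_size,
                                 trunk = list(x = 20, width = 8), seed = seed + i)
      list(raw = fx$raw, map = fx$map, id = sprintf("fix_%d", i))
    })
    suppressWarnings(suppressMessages(build_database(pairs)))
  })
}

# Independent painter: rebuild the ownership buffer of a scene from its
# provenance by sequential last-writer-wins pixel painting.
oracle_owner_buffer <- function(db, scene) {
  w <- ncol(scene$image); h <- nrow(scene$image)
  owner <- matrix(0L, h, w)
  paint_seq <- function(owner, mask, off, id) {
    pix <- which(mask, arr.ind = TRUE)
    for (k in seq_len(nrow(pix))) {
      r <- pix[k, 1] + off[2]; c <- pix[k, 2] + off[1]
      if (r >= 1 && r <= h && c >= 1 && c <= w) owner[r, c] <- id
    }
    owner
  }
  pv <- scene$provenance
  tex <- db$trunks[[pv$trunk$exemplar]]
  tt <- plantforge:::transform_raster(tex$patch, list(m = tex$trunk_mask),
                                      tex$attachment_sites, FALSE, 0, pv$trunk$scale)
  owner <- paint_seq(owner, tt$masks$m, pv$trunk$offset, 1L)
  for (i in seq_along(pv$leaves)) {
    L <- pv$leaves[[i]]
    if (!L$kept) next
    tr <- transform_exemplar(db$leaves[[L$exemplar]], L$flip, L$angle_deg, L$scale)
    owner <- paint_seq(owner, plantforge:::exemplar_region(tr), L$offset, i + 1L)
  }
  owner
}

# Check every LEAF/TRUNK annotation of a scene against the oracle buffer.
scene_masks_match_oracle <- function(db, scene) {
  owner <- oracle_owner_buffer(db, scene)
  for (a in scene$annotations) {
    if (a$class == "TRUNK" && !identical(a$mask, owner == 1L)) return(FALSE)
    if (a$class == "LEAF" && !identical(a$mask, owner == a$instance_id + 1L)) return(FALSE)
  }
  TRUE
}

# Exhaustive-assignment oracle for match_components: leaves take organs in
# descending-area order, each choosing the unassigned max-IoU candidate
# (ties to the smaller index), computed by direct search over the IoU matrix.
oracle_greedy_assignment <- function(leaves, candidates) {
  iou <- outer(seq_along(leaves), seq_along(candidates),
               Vectorize(function(i, j) mask_iou(leaves[[i]]$mask, candidates[[j]]$mask)))
  assigned <- rep(NA_integer_, length(leaves))
  free <- rep(TRUE, length(candidates))
  for (i in order(-vapply(leaves, function(l) sum(l$mask), numeric(1)))) {
    best <- 0L; best_v <- 0
    for (j in seq_along(candidates)) {
      if (free[j] && iou[i, j] > best_v) { best_v <- iou[i, j]; best <- j }
    }
    if (best > 0L) { assigned[i] <- best; free[best] <- FALSE }
  }
  assigned
}
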