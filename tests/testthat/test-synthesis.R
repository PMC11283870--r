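# Exemplar transforms and synthetic scene generation.

test_that("identity transform returns a bitwise-equal exemplar", {
  db <- make_test_db(seed = 3)
  ex <- db$leaves[[1]]
  tr <- transform_exemplar(ex, flip = FALSE, angle_deg = 0, scale = 1)
  expect_identical(tr$leaf_mask, ex$leaf_mask)
  expect_identical(tr$midvein_mask, ex$midvein_mask)
  expect_identical(tr$petiole_mask, ex$petiole_mask)
  expect_equal(tr$attachment_point, ex$attachment_point)
})

test_that("rotating a thin horizontal stripe by 90 degrees makes it vertical", {
  patch <- solid_map(24, 8)
  stripe <- rect_mask(24, 8, 4, 3:22)   # 1 x 20 horizontal midvein
  ex <- leaf_exemplar(patch, stripe)
  tr <- transform_exemplar(ex, angle_deg = 90)
  rows <- which(rowSums(tr$leaf_mask) > 0)
  cols <- which(colSums(tr$leaf_mask) > 0)
  expect_lte(length(cols), 2)                       # +/- 1 px wide
  expect_gte(length(rows), 19)
  expect_lte(abs(length(rows) - 20), 1)
})

test_that("attachment point transforms equivariantly over random transforms", {
  db <- make_test_db(seed = 5)
  withr::with_seed(17, {
    for (rep in 1:100) {
      ex <- db$leaves[[sample(length(db$leaves), 1)]]
      flip <- runif(1) < 0.5
      ang <- runif(1, -180, 180)
      sc <- runif(1, 0.6, 1.6)
      tr <- transform_exemplar(ex, flip, ang, sc)
      # forward-map the original attachment point independently
      A <- plantforge:::similarity_matrix(flip, ang, sc)
      h <- dim(ex$patch)[1]; w <- dim(ex$patch)[2]
      ctr <- c(w / 2, h / 2)
      corners <- rbind(c(0, 0), c(w, 0), c(0, h), c(w, h))
      tc <- t(A %*% (t(corners) - ctr))
      expected <- as.vector(A %*% (ex$attachment_point - ctr)) -
        c(min(tc[, 1]), min(tc[, 2]))
      expect_equal(unname(tr$attachment_point), expected, tolerance = 1e-9)
      # transformed point stays on/near the transformed petiole
      expect_true(any(tr$petiole_mask | tr$leaf_mask))
    }
  })
})

test_that("extreme downscaling errors instead of emitting empty exemplars", {
  db <- make_test_db(seed = 3)
  expect_error(transform_exemplar(db$leaves[[1]], scale = 0.001), "empty")
  expect_error(transform_exemplar(db$leaves[[1]], scale = 0), "scale")
})

test_that("same seed gives bitwise-identical scenes, different seeds differ", {
  db <- make_test_db(seed = 11)
  cfg <- synthesis_config(n_leaves_range = c(4, 7), image_size = c(192, 256), seed = 5)
  s1 <- synthesize_plant(db, cfg, seed = 40)
  s2 <- synthesize_plant(db, cfg, seed = 40)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$annotations, s2$annotations)
  s3 <- synthesize_plant(db, cfg, seed = 41)
  expect_false(identical(s1$image, s3$image))
})

test_that("non-overlapping leaves keep their full transformed masks", {
  db <- make_test_db(seed = 11)
  # large canvas, no rotation/scaling, few leaves: overlaps are improbable;
  # find a seed whose scene has disjoint full extents and check exactness
  cfg <- synthesis_config(n_leaves_range = c(5, 5), scale_range = c(1, 1),
                          rotation_range_deg = c(0, 0), flip_probability = 0,
                          image_size = c(640, 640), seed = 1)
  for (seed in 1:20) {
    sc <- synthesize_plant(db, cfg, seed = seed)
    leaves <- Filter(function(a) a$class == "LEAF", sc$annotations)
    if (length(leaves) != 5) next
    pv <- sc$provenance$leaves
    full <- lapply(seq_along(pv), function(i) {
      tr <- transform_exemplar(db$leaves[[pv[[i]]$exemplar]], pv[[i]]$flip,
                               pv[[i]]$angle_deg, pv[[i]]$scale)
      plantforge:::embed_mask(plantforge:::exemplar_region(tr),
                              pv[[i]]$offset[1], pv[[i]]$offset[2], 640, 640)
    })
    acc <- Reduce(`+`, full)
    trunk_full <- Reduce(`|`, lapply(Filter(function(a) a$class == "TRUNK",
                                            sc$annotations), `[[`, "mask"))
    if (max(acc) > 1) next                      # leaves overlap; try next seed
    overlaps_trunk <- any(acc > 0 & trunk_full)
    for (i in seq_along(leaves)) {
      id <- leaves[[i]]$instance_id
      if (!any(full[[id]] & trunk_full))        # trunk drawn first, so leaf wins
        expect_identical(leaves[[i]]$mask, full[[id]])
    }
    succeed("found a disjoint 5-leaf scene and verified mask exactness")
    break
  }
})

test_that("occluded scenes obey the z-buffer: later leaf wins, masks disjoint", {
  db <- make_test_db(seed = 11)
  # single attachment site forces all leaves onto the same mount -> overlap
  db$trunks[[1]]$attachment_sites <-
    db$trunks[[1]]$attachment_sites[1, , drop = FALSE]
  cfg <- synthesis_config(n_leaves_range = c(3, 3), scale_range = c(1, 1),
                          rotation_range_deg = c(-10, 10),
                          min_visible_fraction = 0.01,
                          image_size = c(256, 320), seed = 1)
  sc <- synthesize_plant(db, cfg, seed = 9)
  leaves <- Filter(function(a) a$class == "LEAF", sc$annotations)
  expect_gt(length(leaves), 1)
  # pairwise disjoint
  acc <- Reduce(`+`, lapply(leaves, `[[`, "mask"))
  expect_lte(max(acc), 1)
  # later-pasted leaf's mask equals its full clipped extent
  pv <- sc$provenance$leaves
  kept <- which(vapply(pv, `[[`, logical(1), "kept"))
  last <- max(kept)
  tr <- transform_exemplar(db$leaves[[pv[[last]]$exemplar]], pv[[last]]$flip,
                           pv[[last]]$angle_deg, pv[[last]]$scale)
  full_last <- plantforge:::embed_mask(plantforge:::exemplar_region(tr),
                                       pv[[last]]$offset[1], pv[[last]]$offset[2],
                                       256, 320)
  last_ann <- Filter(function(a) a$instance_id == last, leaves)[[1]]
  expect_identical(last_ann$mask, full_last)
  # full oracle agreement
  expect_true(scene_masks_match_oracle(db, sc))
})

test_that("organ annotations stay within their leaf and share its instance id", {
  db <- make_test_db(seed = 11)
  cfg <- synthesis_config(n_leaves_range = c(6, 10), image_size = c(256, 320), seed = 2)
  sc <- synthesize_plant(db, cfg, seed = 77)
  leaves <- Filter(function(a) a$class == "LEAF", sc$annotations)
  by_id <- stats::setNames(leaves, vapply(leaves, `[[`, integer(1), "instance_id"))
  organs <- Filter(function(a) a$class %in% c("MIDVEIN", "PETIOLE"), sc$annotations)
  expect_gt(length(organs), 0)
  for (o in organs) {
    leaf <- by_id[[as.character(o$instance_id)]]
    expect_false(is.null(leaf))
    expect_true(all(leaf$mask[o$mask]))          # organ pixels inside leaf mask
  }
})

test_that("amodal masks cover the visible masks they occlude", {
  db <- make_test_db(seed = 11)
  db$trunks[[1]]$attachment_sites <-
    db$trunks[[1]]$attachment_sites[1, , drop = FALSE]
  base <- list(n_leaves_range = c(3, 3), min_visible_fraction = 0.01,
               image_size = c(256, 320), seed = 1)
  vis <- do.call(synthesis_config, c(base, occlusion_policy = "visible"))
  amo <- do.call(synthesis_config, c(base, occlusion_policy = "amodal"))
  sv <- synthesize_plant(db, vis, seed = 4)
  sa <- synthesize_plant(db, amo, seed = 4)
  expect_identical(sv$image, sa$image)           # same composite, different masks
  lv <- Filter(function(a) a$class == "LEAF", sv$annotations)
  la <- Filter(function(a) a$class == "LEAF", sa$annotations)
  ids <- vapply(la, `[[`, integer(1), "instance_id")
  for (v in lv) {
    a <- la[[match(v$instance_id, ids)]]
    expect_true(all(a$mask[v$mask]))             # amodal superset of visible
  }
})

test_that("dataset generation writes both formats with a reproducible manifest", {
  db <- make_test_db(seed = 11)
  cfg <- synthesis_config(n_leaves_range = c(3, 5), image_size = c(160, 200), seed = 6)
  dir <- withr::local_tempdir()
  man <- generate_dataset(db, cfg, 6, dir, formats = c("masks", "yolo"))
  expect_equal(sum(man$split == "train"), 4)     # 2:1 split of 6
  expect_equal(sum(man$split == "val"), 2)
  expect_length(list.files(file.path(dir, "images")), 6)
  expect_length(list.files(file.path(dir, "labels")), 6)
  expect_length(list.dirs(file.path(dir, "masks"), recursive = FALSE), 6)
  dir2 <- withr::local_tempdir()
  man2 <- generate_dataset(db, cfg, 6, dir2, formats = c("masks", "yolo"))
  expect_identical(man, man2)
  f <- "images/img_0001.png"
  expect_identical(png::readPNG(file.path(dir, f)), png::readPNG(file.path(dir2, f)))
  # yolo-only: no masks directory
  dir3 <- withr::local_tempdir()
  generate_dataset(db, cfg, 2, dir3, formats = "yolo")
  expect_false(dir.exists(file.path(dir3, "masks")))
  expect_length(list.files(file.path(dir3, "labels")), 2)
})
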