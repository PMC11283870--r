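# Palette parsing, instance annotations, and annotation file formats.

test_that("palette rejects colors that collide under the tolerance", {
  expect_error(annotation_palette(leaf = c(0, 255, 0), midvein = c(0, 230, 0)),
               "not distinguishable")
  expect_silent(annotation_palette(tolerance = 0))
})

test_that("annotation map parsing extracts one exemplar per blade with its organs", {
  tl <- two_leaf_map()
  parsed <- parse_annotation_map(tl$map, tl$map, pal)
  expect_length(parsed$leaves, 2)
  expect_null(parsed$trunk)
  for (ex in parsed$leaves) {
    expect_gt(sum(ex$leaf_mask), 0)
    expect_gt(sum(ex$midvein_mask), 0)
    expect_gt(sum(ex$petiole_mask), 0)
  }
  # class masks are disjoint within an exemplar
  for (ex in parsed$leaves)
    expect_equal(sum(ex$leaf_mask & ex$midvein_mask) +
                 sum(ex$leaf_mask & ex$petiole_mask) +
                 sum(ex$midvein_mask & ex$petiole_mask), 0)
})

test_that("all-background maps yield no exemplars and dim mismatch errors", {
  empty <- solid_map(32, 32)
  parsed <- parse_annotation_map(empty, empty, pal)
  expect_length(parsed$leaves, 0)
  expect_error(parse_annotation_map(solid_map(32, 32), solid_map(32, 31), pal),
               "dimensions differ")
})

test_that("a petiole extending beyond the blade is kept whole, by pixel bookkeeping", {
  # blade rows 3-12, petiole stripe touches the blade and extends below it
  img <- solid_map(24, 24)
  blade <- rect_mask(24, 24, 3:12, 6:18)
  pet <- rect_mask(24, 24, 12:20, 11:13)
  img <- paint_color(img, blade & !pet, c(0, 255, 0))
  img <- paint_color(img, pet, c(255, 0, 0))
  parsed <- parse_annotation_map(img, img, pal)
  expect_length(parsed$leaves, 1)
  ex <- parsed$leaves[[1]]
  # oracle: every red pixel of the map must appear in the exemplar's petiole
  # mask at the same absolute position
  red <- which(pet, arr.ind = TRUE)
  for (k in seq_len(nrow(red))) {
    r <- red[k, 1] - ex$origin[2]; c <- red[k, 2] - ex$origin[1]
    expect_true(ex$petiole_mask[r, c])
  }
  expect_equal(sum(ex$petiole_mask), sum(pet))
})

test_that("organ components touching no blade are discarded with a warning", {
  img <- solid_map(40, 40)
  img <- paint_color(img, rect_mask(40, 40, 3:10, 3:10), c(0, 255, 0))
  img <- paint_color(img, rect_mask(40, 40, 30:32, 30:36), c(255, 0, 0))
  expect_warning(parsed <- parse_annotation_map(img, img, pal), "discarded")
  expect_length(parsed$leaves, 1)
  expect_equal(sum(parsed$leaves[[1]]$petiole_mask), 0)
})

test_that("palette parsing partitions annotated pixels across exemplar class masks", {
  tl <- two_leaf_map()
  parsed <- parse_annotation_map(tl$map, tl$map, pal)
  counts <- matrix(0L, 40, 64)
  for (ex in parsed$leaves) {
    for (m in list(ex$leaf_mask, ex$midvein_mask, ex$petiole_mask)) {
      pix <- which(m, arr.ind = TRUE)
      for (k in seq_len(nrow(pix)))
        counts[pix[k, 1] + ex$origin[2], pix[k, 2] + ex$origin[1]] <-
          counts[pix[k, 1] + ex$origin[2], pix[k, 2] + ex$origin[1]] + 1L
    }
  }
  annotated <- Reduce(`|`, c(tl$blades, tl$midveins, tl$petioles))
  expect_true(all(counts[annotated] == 1L))
  expect_true(all(counts[!annotated] == 0L))
})

test_that("YOLO files round-trip to 1e-6 and report malformed lines", {
  withr::with_seed(7, {
    records <- lapply(1:10, function(i) {
      n <- sample(3:8, 1)
      yolo_seg_record(sample(0:3, 1), round(runif(2 * n), 6))
    })
  })
  path <- withr::local_tempfile(fileext = ".txt")
  write_yolo_file(records, path)
  back <- read_yolo_file(path)
  expect_length(back, 10)
  for (i in 1:10) {
    expect_equal(back[[i]]$class_index, records[[i]]$class_index)
    expect_equal(back[[i]]$coords, records[[i]]$coords, tolerance = 1e-6)
  }
  # empty record list -> empty file
  write_yolo_file(list(), path)
  expect_length(read_yolo_file(path), 0)
  # explicit line parse
  writeLines("0 0.1 0.1 0.5 0.1 0.3 0.6", path)
  rec <- read_yolo_file(path)[[1]]
  expect_equal(component_class_label(rec$class_index), "LEAF")
  expect_length(rec$coords, 6)
  # malformed lines name the line number
  writeLines(c("0 0.1 0.1 0.5 0.1 0.3 0.6", "1 0.2 oops"), path)
  expect_error(read_yolo_file(path), "line 2")
  writeLines("2 0.1 0.2 1.4 0.1 0.3 0.6", path)
  expect_error(read_yolo_file(path), "line 1")
})

test_that("mask datasets round-trip bitwise and validate their index", {
  withr::with_seed(21, {
    anns <- lapply(1:5, function(i)
      instance_annotation(sample(c("LEAF", "MIDVEIN", "PETIOLE"), 1),
                          random_blob_mask(32, 32), instance_id = i))
  })
  dir <- withr::local_tempdir()
  write_mask_dataset(anns, dir)
  back <- read_mask_dataset(dir)
  expect_length(back$annotations, 5)
  for (i in 1:5) {
    expect_identical(back$annotations[[i]]$mask, anns[[i]]$mask)
    expect_equal(back$annotations[[i]]$class, anns[[i]]$class)
    expect_equal(back$annotations[[i]]$bbox, anns[[i]]$bbox)
  }
  expect_error(read_mask_dataset(withr::local_tempdir()), "annotations.json")
  file.remove(file.path(dir, "instance_003.png"))
  expect_error(read_mask_dataset(dir), "instance_003.png")
})

test_that("instance annotations validate masks and compute tight boxes", {
  expect_error(instance_annotation("LEAF", matrix(FALSE, 4, 4)), "foreground")
  ann <- instance_annotation("LEAF", rect_mask(10, 8, 3:5, 4:7))
  expect_equal(unname(ann$bbox), c(3, 2, 7, 5))  # half-open, 0-based
  expect_equal(unname(ann$image_size), c(10, 8))
})
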