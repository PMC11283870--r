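# Posture digitization: matching, line fitting, angles, statistics.

test_that("a leaf containing one petiole and one midvein forms a complete group", {
  leaf <- instance_annotation("LEAF", rect_mask(40, 40, 5:30, 5:30))
  pet <- instance_annotation("PETIOLE", rect_mask(40, 40, 25:28, 6:20))
  mv <- instance_annotation("MIDVEIN", rect_mask(40, 40, 10:12, 8:25))
  g <- suppressMessages(match_components(list(leaf), list(pet), list(mv)))
  expect_length(g, 1)
  expect_false(is.null(g[[1]]$petiole))
  expect_false(is.null(g[[1]]$midvein))
  expect_gt(g[[1]]$match_scores["petiole"], 0)
})

test_that("greedy matching resolves competing petioles like the brute-force rule", {
  # IoU structure [[high, 0], [low, medium]]: leaf1 takes pet1, leaf2 pet2
  leaf1 <- instance_annotation("LEAF", rect_mask(60, 30, 2:11, 2:21))    # 200 px
  leaf2 <- instance_annotation("LEAF", rect_mask(60, 30, 16:24, 2:19))   # 162 px
  pet1 <- instance_annotation("PETIOLE", rect_mask(60, 30, 2:11, 2:11) |
                                rect_mask(60, 30, 16:17, 2:11))          # hits both
  pet2 <- instance_annotation("PETIOLE", rect_mask(60, 30, 16:20, 2:13))
  g <- suppressMessages(match_components(list(leaf1, leaf2), list(pet1, pet2)))
  expect_identical(g[[1]]$petiole, pet1)
  expect_identical(g[[2]]$petiole, pet2)
  # leaf with no overlapping petiole stays petiole-less
  far <- instance_annotation("LEAF", rect_mask(60, 30, 26:29, 25:29))
  g2 <- suppressMessages(match_components(list(far), list(pet2)))
  expect_null(g2[[1]]$petiole)
})

test_that("matching equals the exhaustive oracle on random small scenes", {
  withr::with_seed(99, {
    for (rep in 1:100) {
      n_leaf <- sample(1:6, 1)
      n_pet <- sample(0:6, 1)
      leaves <- lapply(seq_len(n_leaf), function(i)
        instance_annotation("LEAF", random_blob_mask(64, 64)))
      pets <- lapply(seq_len(n_pet), function(i)
        instance_annotation("PETIOLE", random_blob_mask(64, 64)))
      g <- suppressMessages(match_components(leaves, pets))
      got <- vapply(g, function(x) {
        if (is.null(x$petiole)) NA_integer_
        else which(vapply(pets, identical, logical(1), x$petiole))[1]
      }, integer(1))
      expect_identical(got, oracle_greedy_assignment(leaves, pets))
    }
  })
})

test_that("line fits recover exact colinear sets and flag vertical ones", {
  f1 <- fit_line(cbind(0:2, 0:2), min_fit_pixels = 3)
  expect_equal(f1$k, 1); expect_equal(f1$b, 0); expect_false(f1$axis_swapped)
  f2 <- fit_line(cbind(0:2, c(3, 3, 3)), min_fit_pixels = 3)
  expect_equal(f2$k, 0); expect_equal(f2$b, 3)
  f3 <- fit_line(cbind(c(5, 5, 5), 0:2), min_fit_pixels = 3)
  expect_true(f3$axis_swapped)
  expect_equal(horizontal_angle(f3), 90)
  expect_error(fit_line(cbind(1:4, 1:4)), "TOO_FEW_PIXELS")
  expect_error(fit_line(cbind(rep(1, 12), rep(2, 12)), min_fit_pixels = 10),
               "zero spread")
})

test_that("horizontal angles match the arctangent closed form", {
  mk <- function(k, swapped = FALSE)
    structure(list(k = k, b = 0, n_points = 10, axis_swapped = swapped),
              class = "fitted_line")
  expect_equal(horizontal_angle(mk(1)), 45)
  expect_equal(horizontal_angle(mk(0)), 0)
  expect_equal(horizontal_angle(mk(sqrt(3))), 60, tolerance = 1e-9)
  expect_equal(horizontal_angle(mk(-1)), -45)
  # swapped: line x = k'y; direction (k', 1)
  expect_equal(horizontal_angle(mk(0, TRUE)), 90)
  expect_equal(horizontal_angle(mk(1, TRUE)), 45)
  expect_equal(horizontal_angle(mk(-1, TRUE)), -45)
  withr::with_seed(2, {
    for (k in stats::runif(50, -8, 8)) {
      expect_equal(horizontal_angle(mk(k)), atan(k) * 180 / pi, tolerance = 1e-9)
      got <- horizontal_angle(mk(k, TRUE))
      expect_equal(tan(got * pi / 180), 1 / k, tolerance = 1e-6)
      expect_true(got > -90 && got <= 90)
    }
  })
})

test_that("postures recover fixture angles and carry failure reasons", {
  specs <- list(leaf_spec(c(34, 150), 45, 45, blade_a = 20, blade_b = 12),
                leaf_spec(c(194, 150), 45, 45, blade_a = 20, blade_b = 12))
  fx <- render_fixture_plant(specs, image_size = c(320, 160), seed = 3)
  inst <- annotation_map_to_instances(fx$map)
  g <- suppressMessages(match_components(inst$leaves, inst$petioles, inst$midveins))
  post <- compute_postures(g)
  expect_true(all(post$valid))
  expect_equal(post$alpha_deg, c(45, 45), tolerance = 1 / 45)
  expect_equal(post$beta_deg, c(45, 45), tolerance = 1 / 45)
  # a 4-px midvein is too small to fit
  small_mv <- instance_annotation("MIDVEIN", rect_mask(40, 40, 10, 10:13))
  leaf <- instance_annotation("LEAF", rect_mask(40, 40, 5:30, 5:30))
  pet <- instance_annotation("PETIOLE", rect_mask(40, 40, 28:30, 6:26))
  g2 <- suppressMessages(match_components(list(leaf), list(pet), list(small_mv)))
  p2 <- compute_postures(g2, min_fit_pixels = 10)
  expect_false(p2$valid)
  expect_equal(p2$reason, "TOO_FEW_PIXELS")
  g3 <- suppressMessages(match_components(list(leaf), list(), list(small_mv)))
  expect_equal(compute_postures(g3)$reason, "NO_PETIOLE")
  g4 <- suppressMessages(match_components(list(leaf), list(pet), list()))
  expect_equal(compute_postures(g4)$reason, "NO_MIDVEIN")
})

test_that("angle evaluation computes MAE, signed errors and the +/-5 fraction", {
  ev <- evaluate_angles(data.frame(id = 1:2, angle_deg = c(10, 20)),
                        data.frame(id = 1:2, angle_deg = c(12, 18)))
  expect_equal(ev$mae_deg, 2)
  expect_equal(sort(ev$errors), c(-2, 2))
  expect_equal(ev$within_pm5_fraction, 1)
  same <- data.frame(id = 1:5, angle_deg = seq(-60, 60, length.out = 5))
  ev2 <- evaluate_angles(same, same)
  expect_equal(ev2$mae_deg, 0); expect_equal(ev2$within_pm5_fraction, 1)
  ev3 <- evaluate_angles(data.frame(id = 1, angle_deg = 0),
                         data.frame(id = 1, angle_deg = 50))
  expect_equal(ev3$mae_deg, 50); expect_equal(ev3$within_pm5_fraction, 0)
  # axial wrap: 89 vs -89 is a 2-degree error, not 178
  ev4 <- evaluate_angles(data.frame(id = 1, angle_deg = 89),
                         data.frame(id = 1, angle_deg = -89))
  expect_equal(ev4$mae_deg, 2)
  expect_error(evaluate_angles(data.frame(id = 1, angle_deg = 0),
                               data.frame(id = 2, angle_deg = 0)),
               "no common ids")
})

test_that("rotating the scene rotates every recovered angle with it", {
  lay <- layout_leaf_grid(c(-30, 10, 40), c(20, -10, 60), ncol_grid = 3)
  fx <- render_fixture_plant(lay$specs, image_size = lay$image_size, seed = 6)
  inst <- annotation_map_to_instances(fx$map)
  base <- compute_postures(suppressMessages(
    match_components(inst$leaves, inst$petioles, inst$midveins)))
  base <- base[order(base$alpha_deg), ]
  for (theta in c(8, -12)) {
    # rotate all masks together through one pseudo-exemplar
    h <- dim(fx$map)[1]; w <- dim(fx$map)[2]
    all_leaf <- Reduce(`|`, lapply(inst$leaves, `[[`, "mask"))
    all_pet <- Reduce(`|`, lapply(inst$petioles, `[[`, "mask"))
    all_mv <- Reduce(`|`, lapply(inst$midveins, `[[`, "mask"))
    ex <- leaf_exemplar(blank_image(w, h), all_leaf, all_mv, all_pet)
    tr <- transform_exemplar(ex, angle_deg = theta)   # CCW on screen = +theta math
    ri <- annotation_map_to_instances(local({
      img <- blank_image(ncol(tr$leaf_mask), nrow(tr$leaf_mask))
      img <- paint_color(img, tr$leaf_mask & !tr$midvein_mask & !tr$petiole_mask,
                         c(0, 255, 0))
      img <- paint_color(img, tr$midvein_mask, c(255, 255, 0))
      img <- paint_color(img, tr$petiole_mask & !tr$midvein_mask, c(255, 0, 0))
      img
    }))
    rot <- compute_postures(suppressMessages(
      match_components(ri$leaves, ri$petioles, ri$midveins)))
    rot <- rot[order(rot$alpha_deg), ]
    expect_equal(nrow(rot), 3)
    expect_equal(rot$alpha_deg, base$alpha_deg + theta, tolerance = 1.5 / 30)
    expect_equal(rot$beta_deg, base$beta_deg + theta, tolerance = 1.5 / 30)
  }
})

test_that("group statistics summarize valid postures and order the groups", {
  post <- rbind(
    data.frame(group = "CK", alpha_deg = c(20, 30), beta_deg = c(25, 35), valid = TRUE),
    data.frame(group = "SD", alpha_deg = -40, beta_deg = -30, valid = TRUE),
    data.frame(group = "MD", alpha_deg = NA, beta_deg = NA, valid = FALSE))
  expect_warning(st <- group_statistics(post), "MD")
  expect_equal(st$mean[st$group == "CK" & st$angle == "alpha"], 25)
  expect_equal(st$sd[st$group == "SD" & st$angle == "alpha"], 0)   # singleton
  expect_equal(st$n[st$group == "CK" & st$angle == "beta"], 2)
  expect_error(suppressWarnings(group_statistics(
    data.frame(group = "CK", alpha_deg = NA, beta_deg = NA, valid = FALSE))),
    "no group")
})

test_that("the degraded pipeline still recovers angles to a few degrees", {
  rec <- angle_recovery_experiment(n_leaves = 16, degrade = TRUE, seed = 21)
  expect_gte(rec$n_valid, 12)   # heavy degradation may invalidate a few leaves
  expect_lt(rec$alpha$mae_deg, 5)
  expect_lt(rec$beta$mae_deg, 5)
})
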