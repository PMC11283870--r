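# Simulated segmentation degradation and ground-truth angle recovery.

#' Degrade instance annotations like an imperfect segmenter
#'
#' Applies, per instance, a random erosion or dilation with disc radius up to
#' `max_radius`, and truncates petioles by removing up to `truncate_frac_max`
#' of their pixels from the free end (the end farthest from the mask
#' centroid's projection), emulating the incomplete segmentations that drive
#' large angle errors in practice. Instances that would vanish are left
#' untouched.
#'
#' @param instances List of [instance_annotation()] objects.
#' @param max_radius Maximum morphological radius (default 2).
#' @param truncate_frac_max Maximum truncated fraction for petioles.
#' @param seed Integer seed.
#' @return List of degraded annotations (same order).
#' @export
degrade_instances <- function(instances, max_radius = 2, truncate_frac_max = 0.2,
                              seed = 1L) {
  with_seed(seed, lapply(instances, function(ann) {
    mask <- ann$mask
    r <- sample.int(max_radius + 1L, 1) - 1L
    if (r > 0) {
      m2 <- if (stats::runif(1) < 0.5) binary_erode(mask, r) else binary_dilate(mask, r)
      if (any(m2)) mask <- m2
    }
    if (ann$class == "PETIOLE" && truncate_frac_max > 0) {
      frac <- stats::runif(1, 0, truncate_frac_max)
      p <- mask_pixel_centers(mask)
      if (nrow(p) > 3) {
        ctr <- colMeans(p)
        d <- sweep(p, 2, ctr)
        # principal axis via the 2x2 covariance eigenvector
        cv <- stats::cov(d)
        u <- eigen(cv, symmetric = TRUE)$vectors[, 1]
        proj <- d %*% u
        drop_n <- floor(frac * nrow(p))
        if (drop_n > 0) {
          drop_idx <- order(proj, decreasing = TRUE)[seq_len(drop_n)]
          keep <- p[-drop_idx, , drop = FALSE]
          m2 <- matrix(FALSE, nrow(mask), ncol(mask))
          m2[cbind(keep[, 2] + 0.5, keep[, 1] + 0.5)] <- TRUE
          if (any(m2)) mask <- m2
        }
      }
    }
    instance_annotation(ann$class, mask, instance_id = ann$instance_id)
  }))
}

#' Angle recovery experiment on fixture leaves
#'
#' Samples `n_leaves` (petiole, midvein) angle pairs uniformly from
#' `angle_range`, renders them as fixture plants on non-overlapping grids,
#' runs the full posture pipeline (annotation map -> instances -> IoU
#' matching -> line fits -> angles) and scores recovered angles against the
#' ground truth, matching recovered leaves to truth rows by blade centroid
#' proximity.
#'
#' @param n_leaves Total number of fixture leaves.
#' @param angle_range Uniform sampling range in degrees.
#' @param degrade Apply [degrade_instances()] before the posture pipeline?
#' @param seed Integer seed.
#' @param leaves_per_image Grid cells per fixture image.
#' @param min_fit_pixels Passed to [compute_postures()].
#' @return List: `alpha`, `beta` ([evaluate_angles()] results), `postures`,
#'   `truth`, `n_valid`.
#' @export
angle_recovery_experiment <- function(n_leaves = 200, angle_range = c(-80, 80),
                                      degrade = FALSE, seed = 1L,
                                      leaves_per_image = 8, min_fit_pixels = 10) {
  angles <- with_seed(seed, list(
    alpha = stats::runif(n_leaves, angle_range[1], angle_range[2]),
    beta = stats::runif(n_leaves, angle_range[1], angle_range[2])))
  pred_a <- list(); pred_b <- list(); post_all <- list()
  truth_all <- list()
  done <- 0L; img_i <- 0L
  while (done < n_leaves) {
    img_i <- img_i + 1L
    take <- min(leaves_per_image, n_leaves - done)
    idx <- done + seq_len(take)
    lay <- layout_leaf_grid(angles$alpha[idx], angles$beta[idx])
    fx <- render_fixture_plant(lay$specs, image_size = lay$image_size,
                               seed = seed + img_i)
    inst <- annotation_map_to_instances(fx$map)
    if (degrade) {
      inst$petioles <- degrade_instances(inst$petioles, seed = seed + 7L * img_i)
      inst$midveins <- degrade_instances(inst$midveins, seed = seed + 11L * img_i)
      inst$leaves <- degrade_instances(inst$leaves, seed = seed + 13L * img_i)
    }
    groups <- suppressMessages(match_components(inst$leaves, inst$petioles, inst$midveins))
    post <- compute_postures(groups, min_fit_pixels)
    # associate recovered leaves with truth rows by blade centroid
    cents <- t(vapply(groups, function(g) colMeans(mask_pixel_centers(g$leaf$mask)),
                      numeric(2)))
    truth_id <- vapply(seq_len(nrow(post)), function(j) {
      d2 <- (fx$truth$center_x - cents[j, 1])^2 + (fx$truth$center_y - cents[j, 2])^2
      as.integer(idx[which.min(d2)])
    }, integer(1))
    ok <- post$valid
    pred_a[[img_i]] <- data.frame(id = truth_id[ok], angle_deg = post$alpha_deg[ok])
    pred_b[[img_i]] <- data.frame(id = truth_id[ok], angle_deg = post$beta_deg[ok])
    post$id <- truth_id
    post_all[[img_i]] <- post
    truth_all[[img_i]] <- data.frame(id = idx,
                                     alpha_deg = angles$alpha[idx],
                                     beta_deg = angles$beta[idx])
    done <- done + take
  }
  truth <- do.call(rbind, truth_all)
  pa <- do.call(rbind, pred_a)
  pb <- do.call(rbind, pred_b)
  list(alpha = evaluate_angles(pa, data.frame(id = truth$id, angle_deg = truth$alpha_deg)),
       beta = evaluate_angles(pb, data.frame(id = truth$id, angle_deg = truth$beta_deg)),
       postures = do.call(rbind, post_all), truth = truth, n_valid = nrow(pa))
}

#' Group-statistics experiment on drought fixture populations
#'
#' Samples per-group angle populations with [sample_drought_population()],
#' renders and digitizes them through the full posture pipeline, and returns
#' the per-group summary.
#'
#' @param n_per_group Leaves per irrigation group.
#' @param groups Character vector of group names.
#' @param seed Integer seed.
#' @return List: `stats` ([group_statistics()] table), `postures`.
#' @export
group_recovery_experiment <- function(n_per_group = 200,
                                      groups = c("CK", "MD", "SD"),
                                      seed = 1L) {
  all_post <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    pop <- sample_drought_population(g, n_per_group, seed = seed + gi)
    rec <- angle_recovery_from_angles(pop$alpha_deg, pop$beta_deg, seed = seed + 100L * gi)
    rec$group <- g
    all_post[[gi]] <- rec
  }
  postures <- do.call(rbind, all_post)
  list(stats = group_statistics(postures), postures = postures)
}

# Shared helper: run the posture pipeline over arbitrary angle vectors and
# return the posture table (one row per recovered leaf).
angle_recovery_from_angles <- function(alpha_deg, beta_deg, seed = 1L,
                                       leaves_per_image = 8, min_fit_pixels = 10) {
  n <- length(alpha_deg)
  out <- list(); done <- 0L; img_i <- 0L
  while (done < n) {
    img_i <- img_i + 1L
    take <- min(leaves_per_image, n - done)
    idx <- done + seq_len(take)
    lay <- layout_leaf_grid(alpha_deg[idx], beta_deg[idx])
    fx <- render_fixture_plant(lay$specs, image_size = lay$image_size,
                               seed = seed + img_i)
    inst <- annotation_map_to_instances(fx$map)
    groups <- suppressMessages(match_components(inst$leaves, inst$petioles, inst$midveins))
    out[[img_i]] <- compute_postures(groups, min_fit_pixels)
    done <- done + take
  }
  do.call(rbind, out)
}
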