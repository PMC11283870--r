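# Pipeline wiring: fixtures -> build-db -> synthesize -> (external segmenter)
# -> posture -> train/evaluate, with plain-file stage artifacts in a run
# directory.

#' Pipeline configuration
#'
#' A nested list validated before any stage runs; unknown fields are
#' rejected. Every stage derives its RNG stream from the single `seed`.
#'
#' @param out_dir Run directory; each stage writes its artifacts beneath it.
#' @param seed Master seed.
#' @param fixtures List: `kind` (`"posture"` or `"classification"`),
#'   `n_leaves` / `n_per_cell`.
#' @param synthesis A [synthesis_config()].
#' @param n_images Number of synthetic scenes for the synthesize stage.
#' @param posture List: `min_fit_pixels`.
#' @param train A [train_config()] plus `mode`.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "plantforge_run", seed = 1L,
                            fixtures = list(kind = "posture", n_leaves = 24,
                                            n_per_cell = 4),
                            synthesis = synthesis_config(seed = seed),
                            n_images = 6,
                            posture = list(min_fit_pixels = 10),
                            train = list(mode = "multi_task", epochs = 15)) {
  stopifnot(fixtures$kind %in% c("posture", "classification"),
            n_images >= 1, posture$min_fit_pixels >= 1,
            train$mode %in% c("multi_task", "single_task"))
  structure(list(out_dir = out_dir, seed = as.integer(seed), fixtures = fixtures,
                 synthesis = synthesis, n_images = n_images, posture = posture,
                 train = train),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring the [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthesis_config, c(y$synthesis, list(seed = y$seed %||% 1L)))
  args <- y[setdiff(names(y), "synthesis")]
  do.call(pipeline_config, c(args, list(synthesis = syn)))
}

#' Run pipeline stages
#'
#' Executes the requested stages in canonical order
#' (`fixtures`, `build_db`, `synthesize`, `convert`, `posture`, `train`),
#' writing plain-file artifacts under `config$out_dir` and a `run.log` of
#' per-stage counts. Every artifact directory carries a `run.json` stamp with
#' the configuration hash and seed. A stage whose upstream artifact is
#' missing stops with a message naming the stage to run first.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of the stage names above.
#' @return Named list of per-stage artifact paths, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("fixtures", "posture")) {
  stopifnot(inherits(config, "pipeline_config"))
  order_all <- c("fixtures", "build_db", "synthesize", "convert", "posture", "train")
  stages <- match.arg(stages, order_all, several.ok = TRUE)
  stages <- order_all[order_all %in% stages]
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  stamp <- list(config_hash = unname(tools::md5sum(tmp)), seed = config$seed)
  unlink(tmp)
  jsonlite::write_json(stamp, file.path(out, "run.json"), auto_unbox = TRUE)
  artifacts <- list()

  for (stage in stages) {
    if (stage == "fixtures") {
      fd <- file.path(out, "fixtures")
      dir.create(fd, recursive = TRUE, showWarnings = FALSE)
      if (config$fixtures$kind == "posture") {
        angles <- with_seed(config$seed, list(
          a = stats::runif(config$fixtures$n_leaves, -80, 80),
          b = stats::runif(config$fixtures$n_leaves, -80, 80)))
        per <- 8L; done <- 0L; i <- 0L; truth <- list()
        while (done < config$fixtures$n_leaves) {
          i <- i + 1L
          take <- min(per, config$fixtures$n_leaves - done)
          idx <- done + seq_len(take)
          lay <- layout_leaf_grid(angles$a[idx], angles$b[idx])
          fx <- render_fixture_plant(lay$specs, image_size = lay$image_size,
                                     seed = config$seed + i)
          png::writePNG(fx$raw, file.path(fd, sprintf("img_%03d.png", i)))
          png::writePNG(fx$map, file.path(fd, sprintf("map_%03d.png", i)))
          fx$truth$image <- i
          fx$truth$leaf_id <- idx
          truth[[i]] <- fx$truth
          done <- done + take
        }
        utils::write.csv(do.call(rbind, truth), file.path(fd, "truth.csv"),
                         row.names = FALSE)
        log_line("fixtures: %d posture leaves over %d images", done, i)
      } else {
        ds <- render_classification_dataset(n_per_cell = config$fixtures$n_per_cell,
                                            seed = config$seed)
        dir.create(file.path(fd, "images"), showWarnings = FALSE)
        ds$labels$path <- sprintf("images/%04d.png", seq_along(ds$images))
        for (j in seq_along(ds$images))
          png::writePNG(ds$images[[j]], file.path(fd, ds$labels$path[j]))
        utils::write.csv(ds$labels, file.path(fd, "manifest.csv"), row.names = FALSE)
        log_line("fixtures: %d labeled classification images", length(ds$images))
      }
      artifacts$fixtures <- fd
    } else if (stage == "build_db") {
      fd <- file.path(out, "fixtures")
      maps <- list.files(fd, pattern = "^map_.*\\.png$", full.names = TRUE)
      if (!length(maps)) stop("no annotation maps found; run the fixtures stage first")
      pairs <- lapply(maps, function(m) {
        list(raw = png::readPNG(sub("map_", "img_", m)), map = png::readPNG(m),
             id = basename(m))
      })
      db <- suppressWarnings(build_database(pairs))
      if (!length(db$trunks)) {
        # posture fixtures carry no trunk; synthesize one bar trunk exemplar
        trunk <- render_fixture_plant(list(), image_size = c(64L, 256L),
                                      trunk = list(x = 32, width = 8),
                                      noise_sd = 0, seed = config$seed)
        db$trunks <- list(trunk_exemplar(trunk$raw,
                                         palette_match(trunk$map,
                                                       db$palette$colors$TRUNK,
                                                       db$palette$tolerance),
                                         source_id = "synthetic_bar_trunk"))
      }
      save_database(db, file.path(out, "db"))
      log_line("build_db: %d leaves, %d trunks", length(db$leaves), length(db$trunks))
      artifacts$build_db <- file.path(out, "db")
    } else if (stage == "synthesize") {
      dbp <- file.path(out, "db")
      if (!file.exists(file.path(dbp, "db.json")))
        stop("no component database found; run the build_db stage first")
      db <- load_database(dbp)
      man <- generate_dataset(db, config$synthesis, config$n_images,
                              file.path(out, "synthetic"))
      log_line("synthesize: %d scenes (%d train / %d val)", nrow(man),
               sum(man$split == "train"), sum(man$split == "val"))
      artifacts$synthesize <- file.path(out, "synthetic")
    } else if (stage == "convert") {
      sd <- file.path(out, "synthetic", "masks")
      if (!dir.exists(sd)) stop("no mask datasets found; run the synthesize stage first")
      for (d in list.dirs(sd, recursive = FALSE))
        convert_annotations(d, file.path(out, "yolo", basename(d)), "masks", "yolo")
      log_line("convert: %d mask datasets -> YOLO", length(list.dirs(sd, recursive = FALSE)))
      artifacts$convert <- file.path(out, "yolo")
    } else if (stage == "posture") {
      fd <- file.path(out, "fixtures")
      maps <- list.files(fd, pattern = "^map_.*\\.png$", full.names = TRUE)
      if (!length(maps)) stop("no annotation maps found; run the fixtures stage first")
      truth_path <- file.path(fd, "truth.csv")
      truth <- if (file.exists(truth_path)) utils::read.csv(truth_path) else NULL
      posts <- list()
      for (m in maps) {
        inst <- annotation_map_to_instances(png::readPNG(m))
        groups <- suppressMessages(match_components(inst$leaves, inst$petioles,
                                                    inst$midveins))
        post <- compute_postures(groups, config$posture$min_fit_pixels)
        post$image <- as.integer(sub(".*map_(\\d+)\\.png", "\\1", m))
        if (!is.null(truth)) {
          # pair recovered leaves with truth rows by blade centroid
          tr <- truth[truth$image == post$image[1], , drop = FALSE]
          cents <- t(vapply(groups, function(g)
            colMeans(mask_pixel_centers(g$leaf$mask)), numeric(2)))
          post$truth_id <- vapply(seq_len(nrow(post)), function(j) {
            d2 <- (tr$center_x - cents[j, 1])^2 + (tr$center_y - cents[j, 2])^2
            as.integer(tr$leaf_id[which.min(d2)])
          }, integer(1))
        }
        posts[[length(posts) + 1L]] <- post
      }
      postures <- do.call(rbind, posts)
      utils::write.csv(postures, file.path(out, "postures.csv"), row.names = FALSE)
      if (!is.null(truth)) {
        ok <- postures$valid
        ev_a <- evaluate_angles(
          data.frame(id = postures$truth_id[ok], angle_deg = postures$alpha_deg[ok]),
          data.frame(id = truth$leaf_id, angle_deg = truth$alpha_deg))
        ev_b <- evaluate_angles(
          data.frame(id = postures$truth_id[ok], angle_deg = postures$beta_deg[ok]),
          data.frame(id = truth$leaf_id, angle_deg = truth$beta_deg))
        log_line("posture: %d leaves, MAE alpha %.2f deg, MAE beta %.2f deg",
                 sum(ok), ev_a$mae_deg, ev_b$mae_deg)
      } else {
        log_line("posture: %d leaves digitized", nrow(postures))
      }
      artifacts$posture <- file.path(out, "postures.csv")
    } else if (stage == "train") {
      fd <- file.path(out, "fixtures")
      man_path <- file.path(fd, "manifest.csv")
      if (!file.exists(man_path))
        stop("no classification manifest found; run the fixtures (classification) ",
             "stage first")
      labels <- utils::read.csv(man_path)
      images <- lapply(file.path(fd, labels$path), png::readPNG)
      splits <- stratified_split(labels, seed = config$seed)
      bb <- toy_backbone()
      spec <- multitask_head_spec(feature_dim = bb$feature_dim,
                                  n_variety_classes = length(unique(labels$variety)),
                                  n_stress_classes = length(unique(labels$stress_level)))
      model <- build_model(spec, config$train$mode, bb, seed = config$seed)
      tc <- train_config(lr = 5e-3, epochs = config$train$epochs %||% 15,
                         seed = config$seed)
      fit <- train_model(model, images, labels, splits, tc)
      utils::write.csv(fit$history, file.path(out, "history.csv"), row.names = FALSE)
      ev <- evaluate_model(fit$model, images[splits$pred],
                           labels[splits$pred, , drop = FALSE])
      for (task in names(ev))
        utils::write.csv(ev[[task]]$confusion,
                         file.path(out, sprintf("confusion_%s.csv", task)))
      accs <- vapply(ev, function(e) e$accuracy, numeric(1))
      log_line("train: prediction accuracy %s",
               paste(sprintf("%s=%.3f", names(accs), accs), collapse = ", "))
      artifacts$train <- file.path(out, "history.csv")
    }
  }
  invisible(artifacts)
}
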