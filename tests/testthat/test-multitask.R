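# Stratified splitting, fused loss, model contract, training, evaluation.

test_that("stratified splits honor 6:2:2 by largest remainder", {
  lab <- data.frame(variety = rep(0L, 10), plant_id = 1:10)
  sp <- stratified_split(lab, seed = 1)
  expect_equal(lengths(sp), c(train = 6L, val = 2L, pred = 2L))
  lab4 <- data.frame(variety = rep(0:3, each = 20), plant_id = 1:80)
  sp4 <- stratified_split(lab4, seed = 2)
  expect_equal(lengths(sp4), c(train = 48L, val = 16L, pred = 16L))
  for (v in 0:3)
    expect_equal(sum(lab4$variety[sp4$train] == v), 12)
  # disjoint cover / permutation of the input
  expect_equal(sort(unname(unlist(sp4))), 1:80)
  # deterministic under seed
  expect_identical(stratified_split(lab4, seed = 2), sp4)
  expect_false(identical(stratified_split(lab4, seed = 3), sp4))
  expect_error(stratified_split(data.frame(variety = integer(0)), seed = 1),
               class = "error")
})

test_that("per-plant grouping keeps both timepoints in one partition", {
  lab <- data.frame(variety = rep(0:1, each = 20),
                    plant_id = rep(1:20, each = 2),
                    timepoint = rep(1:2, times = 20))
  sp <- stratified_split(lab, seed = 4)
  for (part in sp) {
    ids <- lab$plant_id[part]
    # every plant id present in a partition brings both its rows
    expect_true(all(table(ids) == 2))
  }
})

test_that("fused loss matches closed forms and degenerates to single-task", {
  V <- 4; S <- 5; n <- 6
  zv <- matrix(0, n, V); zs <- matrix(0, n, S)
  vl <- rep(0:3, length.out = n); sl <- rep(0:4, length.out = n)
  expect_equal(fused_loss(zv, zs, vl, sl), log(4) + log(5), tolerance = 1e-6)
  # a huge logit on the true class sends that term to zero
  zv_big <- zv; zv_big[cbind(1:n, vl + 1)] <- 1e4
  expect_equal(fused_loss(zv_big, zs, vl, sl), log(5), tolerance = 1e-6)
  # weight degeneration is exact
  withr::with_seed(5, {
    lv <- matrix(rnorm(n * V), n, V); ls <- matrix(rnorm(n * S), n, S)
  })
  expect_identical(fused_loss(lv, ls, vl, sl, weights = c(1, 0)),
                   plantforge:::cross_entropy(lv, vl))
  expect_identical(fused_loss(lv, ls, vl, sl, weights = c(0, 1)),
                   plantforge:::cross_entropy(ls, sl))
  expect_error(fused_loss(lv, ls, c(4, vl[-1]), sl), "out of range")
})

test_that("model forward obeys the shape contract for both modes", {
  bb <- toy_backbone(3)
  spec <- multitask_head_spec(feature_dim = bb$feature_dim,
                              n_variety_classes = 4, n_stress_classes = 5)
  imgs <- replicate(3, array(runif(24 * 24 * 3), c(24, 24, 3)), simplify = FALSE)
  f <- bb$fn(imgs)
  expect_equal(dim(f), c(3L, bb$feature_dim))
  multi <- build_model(spec, "multi_task", bb, seed = 1)
  fw <- plantforge:::model_forward(multi, f)
  expect_equal(dim(fw$variety), c(3L, 4L))
  expect_equal(dim(fw$stress), c(3L, 5L))
  single <- build_model(spec, "single_task", bb, task = "stress", seed = 1)
  fws <- plantforge:::model_forward(single, f)
  expect_equal(dim(fws$stress), c(3L, 5L))
  expect_null(fws$variety)
  expect_error(build_model(multitask_head_spec(feature_dim = 99), "multi_task", bb),
               "does not match")
})

test_that("confusion statistics behave like the definition on random tables", {
  perfect <- confusion_stats(0:4, 0:4, 5)
  expect_equal(unname(diag(perfect$confusion)), rep(1L, 5))
  expect_equal(perfect$accuracy, 1)
  constant <- confusion_stats(rep(2L, 25), rep(0:4, each = 5), 5)
  expect_equal(constant$accuracy, 0.2)
  withr::with_seed(31, {
    for (rep in 1:20) {
      truth <- rep(0:4, each = 8)                      # balanced classes
      pred <- sample(0:4, 40, replace = TRUE)
      cs <- confusion_stats(pred, truth, 5)
      recalls <- diag(cs$confusion) / rowSums(cs$confusion)
      expect_equal(cs$accuracy, mean(recalls))         # balanced => equal
      expect_equal(cs$accuracy, sum(pred == truth) / 40)
    }
  })
})

test_that("training reduces the loss and is seed-reproducible", {
  ds <- render_classification_dataset(n_varieties = 3, n_levels = 3,
                                      n_per_cell = 6, seed = 13)
  splits <- stratified_split(ds$labels, seed = 13)
  bb <- toy_backbone()
  spec <- multitask_head_spec(feature_dim = bb$feature_dim,
                              n_variety_classes = 3, n_stress_classes = 3)
  model <- build_model(spec, "multi_task", bb, seed = 13)
  cfg <- train_config(lr = 5e-3, epochs = 10, seed = 13)
  fit <- train_model(model, ds$images, ds$labels, splits, cfg)
  expect_equal(nrow(fit$history), 10)
  expect_lt(fit$history$train_loss[10], fit$history$train_loss[1])
  fit2 <- train_model(model, ds$images, ds$labels, splits, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model$params, fit2$model$params)
  # the lr schedule drops by the decay factor after the decay epoch
  cfg2 <- train_config(lr = 5e-3, epochs = 6, lr_decay_epoch = 4, seed = 13)
  h2 <- train_model(model, ds$images, ds$labels, splits, cfg2)$history
  expect_equal(h2$lr[5] / h2$lr[4], 0.1)
})

test_that("multitask accuracy keeps pace with single-task on the stress task", {
  ds <- render_classification_dataset(n_per_cell = 8, seed = 2)
  multi <- single <- numeric(5)
  for (r in 1:5) {
    em <- classification_experiment("multi_task", n_per_cell = 8, epochs = 20,
                                    seed = r, dataset = ds)
    es <- classification_experiment("single_task", task = "stress",
                                    n_per_cell = 8, epochs = 20,
                                    seed = r, dataset = ds)
    multi[r] <- em$val$stress$accuracy
    single[r] <- es$val$stress$accuracy
  }
  expect_gte(mean(multi), mean(single) - 0.02)
})
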