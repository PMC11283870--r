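# Multitask (variety x stress level) classification scaffold.
#
# A pluggable backbone maps images to a shared feature vector; in multitask
# mode two independent one-hidden-layer heads (64 units by default) predict
# the variety and the drought stress level, trained against the fused sum of
# the two softmax cross-entropies. Single-task mode uses one linear output
# layer on the same feature. All labels are 0-based integers.

#' Stratified train/validation/prediction split
#'
#' Splits samples of each stratum (by default each variety) at the given
#' ratios using largest-remainder rounding, so per-stratum counts differ from
#' the exact ratio by less than one sample. When `group_by` names a column
#' (default `plant_id`), all rows of one group go to the same partition,
#' preventing the same plant's repeated timepoints from straddling splits.
#'
#' @param labels Data frame with the stratification columns.
#' @param ratios Numeric (train, val, pred) summing to 1.
#' @param stratify_by Character vector of label columns defining strata.
#' @param group_by Column keeping rows together, or `NULL` to split per row.
#' @param seed Integer seed (shuffling within strata).
#' @return `list(train, val, pred)` of row indices into `labels` - a disjoint
#'   cover.
#' @export
stratified_split <- function(labels, ratios = c(0.6, 0.2, 0.2),
                             stratify_by = "variety", group_by = "plant_id",
                             seed = 1L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-9, length(ratios) == 3, nrow(labels) >= 1)
  if (!is.null(group_by) && !group_by %in% names(labels)) group_by <- NULL
  strata <- interaction(labels[stratify_by], drop = TRUE)
  out <- list(train = integer(0), val = integer(0), pred = integer(0))
  with_seed(seed, {
    for (s in levels(strata)) {
      rows <- which(strata == s)
      if (!length(rows)) stop("empty stratum: ", s)
      units <- if (is.null(group_by)) as.list(rows) else {
        ids <- labels[[group_by]][rows]
        lapply(unique(ids), function(id) rows[ids == id])
      }
      units <- units[sample.int(length(units))]
      n <- length(units)
      exact <- n * ratios
      base <- floor(exact)
      rem <- exact - base
      extra <- n - sum(base)
      if (extra > 0) {
        give <- order(-rem)[seq_len(extra)]
        base[give] <- base[give] + 1
      }
      cuts <- cumsum(base)
      idx <- list(train = seq_len(cuts[1]),
                  val = if (cuts[2] > cuts[1]) (cuts[1] + 1):cuts[2] else integer(0),
                  pred = if (cuts[3] > cuts[2]) (cuts[2] + 1):cuts[3] else integer(0))
      for (part in names(out))
        out[[part]] <- c(out[[part]], unlist(units[idx[[part]]]))
    }
  })
  lapply(out, function(x) unname(sort(x)))
}

# Row-wise stable softmax cross-entropy; labels are 0-based.
cross_entropy <- function(logits, labels0) {
  n <- nrow(logits)
  if (any(labels0 < 0) || any(labels0 >= ncol(logits)))
    stop("label out of range [0, ", ncol(logits), ")")
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  mean(lse - logits[cbind(seq_len(n), labels0 + 1L)])
}

#' Fused cross-entropy loss for the two classification tasks
#'
#' The weighted sum of the variety and stress-level softmax cross-entropies
#' (default equal weights). With weights `(1, 0)` or `(0, 1)` it reduces
#' exactly to the corresponding single-task loss.
#'
#' @param variety_logits,stress_logits n x V and n x S logit matrices.
#' @param variety_label,stress_label Integer vectors, 0-based.
#' @param weights Length-2 numeric task weights.
#' @return Scalar loss.
#' @export
fused_loss <- function(variety_logits, stress_logits, variety_label, stress_label,
                       weights = c(1, 1)) {
  stopifnot(all(is.finite(variety_logits)), all(is.finite(stress_logits)),
            length(weights) == 2)
  weights[1] * cross_entropy(variety_logits, variety_label) +
    weights[2] * cross_entropy(stress_logits, stress_label)
}

#' Head specification for the classification models
#'
#' @param feature_dim Backbone output dimension (1024 for the full-size
#'   backbones; tests use the toy backbone's smaller dimension).
#' @param hidden_units Hidden-layer width of each multitask head (64).
#' @param n_variety_classes,n_stress_classes Class counts.
#' @return A `multitask_head_spec`.
#' @export
multitask_head_spec <- function(feature_dim = 1024, hidden_units = 64,
                                n_variety_classes = 4, n_stress_classes = 5) {
  stopifnot(feature_dim >= 1, hidden_units >= 1,
            n_variety_classes >= 2 || n_stress_classes >= 2)
  structure(list(feature_dim = as.integer(feature_dim),
                 hidden_units = as.integer(hidden_units),
                 n_variety_classes = as.integer(n_variety_classes),
                 n_stress_classes = as.integer(n_stress_classes)),
            class = "multitask_head_spec")
}

#' Toy mean-pooling backbone
#'
#' Average-pools each color channel over a `grid x grid` partition of the
#' image and concatenates the pooled values into a `3 * grid^2` feature
#' vector. Deterministic, training-free, and sufficient for the fixture sets;
#' any function mapping a list of images to an n x feature_dim matrix can be
#' plugged in instead (e.g. features exported from a pretrained CNN).
#'
#' @param grid Pooling grid edge length.
#' @return A `backbone`: `list(fn, feature_dim, name)`.
#' @export
toy_backbone <- function(grid = 4) {
  feature_dim <- as.integer(3 * grid^2)
  fn <- function(images) {
    t(vapply(images, function(img) {
      h <- dim(img)[1]; w <- dim(img)[2]
      rb <- pmin(floor((seq_len(h) - 1) * grid / h) + 1L, grid)
      cb <- pmin(floor((seq_len(w) - 1) * grid / w) + 1L, grid)
      cnt <- outer(tabulate(rb, grid), tabulate(cb, grid))
      unlist(lapply(1:3, function(ch) {
        sums <- t(rowsum(t(rowsum(img[, , ch], rb)), cb))
        as.vector(sums / cnt)
      }), use.names = FALSE)
    }, numeric(feature_dim)))
  }
  structure(list(fn = fn, feature_dim = feature_dim, name = sprintf("toy_pool%d", grid)),
            class = "backbone")
}

#' Build a single-task or multitask classification model
#'
#' In multitask mode the shared backbone feature feeds two independent
#' one-hidden-layer fully connected heads (ReLU hidden layer of
#' `hidden_units` neurons each) emitting variety and stress-level logits. In
#' single-task mode a single linear mapping produces the logits of the chosen
#' task. Parameters are He-initialized from `seed`.
#'
#' @param head_spec A [multitask_head_spec()].
#' @param mode `"multi_task"` or `"single_task"`.
#' @param backbone A [toy_backbone()]-style backbone whose `feature_dim` must
#'   equal `head_spec$feature_dim`.
#' @param task Task of a single-task model: `"stress"` or `"variety"`.
#' @param seed Integer seed for parameter initialization.
#' @return A `plantforge_model`.
#' @export
build_model <- function(head_spec, mode = c("multi_task", "single_task"),
                        backbone = toy_backbone(), task = c("stress", "variety"),
                        seed = 1L) {
  mode <- match.arg(mode); task <- match.arg(task)
  stopifnot(inherits(head_spec, "multitask_head_spec"))
  if (backbone$feature_dim != head_spec$feature_dim)
    stop("backbone feature_dim (", backbone$feature_dim,
         ") does not match head_spec feature_dim (", head_spec$feature_dim, ")")
  d <- head_spec$feature_dim; hdim <- head_spec$hidden_units
  init <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  params <- with_seed(seed, {
    if (mode == "multi_task") {
      list(W1v = init(d, hdim), b1v = numeric(hdim),
           W2v = init(hdim, head_spec$n_variety_classes),
           b2v = numeric(head_spec$n_variety_classes),
           W1s = init(d, hdim), b1s = numeric(hdim),
           W2s = init(hdim, head_spec$n_stress_classes),
           b2s = numeric(head_spec$n_stress_classes))
    } else {
      nc <- if (task == "stress") head_spec$n_stress_classes else head_spec$n_variety_classes
      list(W = init(d, nc), b = numeric(nc))
    }
  })
  structure(list(head_spec = head_spec, mode = mode, task = task,
                 backbone = backbone, params = params,
                 feature_center = NULL, feature_scale = NULL),
            class = "plantforge_model")
}

# Forward pass on a standardized feature matrix. Returns logits (and hidden
# activations when keep_hidden, for backprop).
model_forward <- function(model, features, keep_hidden = FALSE) {
  p <- model$params
  if (model$mode == "multi_task") {
    hv <- pmax(features %*% p$W1v + rep(p$b1v, each = nrow(features)), 0)
    hs <- pmax(features %*% p$W1s + rep(p$b1s, each = nrow(features)), 0)
    out <- list(variety = hv %*% p$W2v + rep(p$b2v, each = nrow(features)),
                stress = hs %*% p$W2s + rep(p$b2s, each = nrow(features)))
    if (keep_hidden) { out$hv <- hv; out$hs <- hs }
    out
  } else {
    logits <- features %*% p$W + rep(p$b, each = nrow(features))
    if (model$task == "stress") list(stress = logits) else list(variety = logits)
  }
}

model_features <- function(model, images) {
  f <- model$backbone$fn(images)
  if (!is.null(model$feature_center))
    f <- sweep(sweep(f, 2, model$feature_center), 2, model$feature_scale, "/")
  f
}

# softmax probabilities minus one-hot labels, divided by n: dL/dlogits.
softmax_grad <- function(logits, labels0) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  p[cbind(seq_len(nrow(p)), labels0 + 1L)] <-
    p[cbind(seq_len(nrow(p)), labels0 + 1L)] - 1
  p / nrow(p)
}

#' Training configuration
#'
#' Defaults follow the standard recipe for this scaffold: initial learning
#' rate 5e-4 decayed by a factor of 10 after 20 epochs, 60 epochs, minibatch
#' size 16, Adam optimizer.
#'
#' @param lr Initial learning rate.
#' @param lr_decay_factor,lr_decay_epoch Multiply `lr` by the factor after
#'   this many epochs.
#' @param epochs,batch_size Training length and minibatch size.
#' @param loss_weights Fused-loss task weights (variety, stress).
#' @param seed Integer seed (shuffling and any stochastic parts).
#' @return A `train_config`.
#' @export
train_config <- function(lr = 5e-4, lr_decay_factor = 0.1, lr_decay_epoch = 20,
                         epochs = 60, batch_size = 16, loss_weights = c(1, 1),
                         seed = 1L) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1, lr_decay_factor > 0)
  structure(list(lr = lr, lr_decay_factor = lr_decay_factor,
                 lr_decay_epoch = lr_decay_epoch, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss_weights = loss_weights,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a classification model
#'
#' Minibatch Adam on the fused cross-entropy (multitask) or the single-task
#' cross-entropy. Backbone features are computed once and standardized with
#' training-set statistics. After every epoch the validation accuracy is
#' recorded and the parameters achieving the highest validation stress
#' accuracy (or the single task's accuracy) are kept as the best model.
#' Deterministic under a fixed seed.
#'
#' @param model A [build_model()] result.
#' @param images List of RGB arrays.
#' @param labels Data frame with 0-based `variety` and `stress_level`.
#' @param splits `list(train, val, ...)` of row indices (see
#'   [stratified_split()]).
#' @param config A [train_config()].
#' @return `list(model, history)`; `history` has one row per epoch with
#'   `train_loss`, `val_variety_acc`, `val_stress_acc`, `lr`.
#' @export
train_model <- function(model, images, labels, splits, config = train_config()) {
  stopifnot(length(splits$train) > 0, length(splits$val) > 0)
  feats_raw <- model$backbone$fn(images)
  ctr <- colMeans(feats_raw[splits$train, , drop = FALSE])
  scl <- pmax(apply(feats_raw[splits$train, , drop = FALSE], 2, stats::sd), 1e-8)
  model$feature_center <- ctr; model$feature_scale <- scl
  feats <- sweep(sweep(feats_raw, 2, ctr), 2, scl, "/")

  vlab <- labels$variety; slab <- labels$stress_level
  p <- model$params
  adam_m <- lapply(p, function(x) x * 0)
  adam_v <- lapply(p, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  wts <- config$loss_weights

  eval_acc <- function(params, idx) {
    model$params <- params
    lg <- model_forward(model, feats[idx, , drop = FALSE])
    acc <- c(variety = NA_real_, stress = NA_real_)
    if (!is.null(lg$variety))
      acc["variety"] <- mean(max.col(lg$variety) - 1L == vlab[idx])
    if (!is.null(lg$stress))
      acc["stress"] <- mean(max.col(lg$stress) - 1L == slab[idx])
    acc
  }

  batch_grads <- function(params, idx) {
    model$params <- params
    f <- feats[idx, , drop = FALSE]
    if (model$mode == "multi_task") {
      fw <- model_forward(model, f, keep_hidden = TRUE)
      loss <- fused_loss(fw$variety, fw$stress, vlab[idx], slab[idx], wts)
      gv <- wts[1] * softmax_grad(fw$variety, vlab[idx])
      gs <- wts[2] * softmax_grad(fw$stress, slab[idx])
      dhv <- (gv %*% t(params$W2v)) * (fw$hv > 0)
      dhs <- (gs %*% t(params$W2s)) * (fw$hs > 0)
      grads <- list(W1v = t(f) %*% dhv, b1v = colSums(dhv),
                    W2v = t(fw$hv) %*% gv, b2v = colSums(gv),
                    W1s = t(f) %*% dhs, b1s = colSums(dhs),
                    W2s = t(fw$hs) %*% gs, b2s = colSums(gs))
    } else {
      fw <- model_forward(model, f)
      lab <- if (model$task == "stress") slab[idx] else vlab[idx]
      logits <- fw[[model$task]]
      loss <- cross_entropy(logits, lab)
      g <- softmax_grad(logits, lab)
      grads <- list(W = t(f) %*% g, b = colSums(g))
    }
    if (!is.finite(loss)) stop("training loss diverged (non-finite)")
    list(loss = loss, grads = grads)
  }

  history <- list()
  best <- list(metric = -Inf, params = p)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$lr * if (epoch > config$lr_decay_epoch) config$lr_decay_factor else 1
      ord <- splits$train[sample.int(length(splits$train))]
      losses <- numeric(0)
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        bg <- batch_grads(p, idx)
        losses <- c(losses, bg$loss)
        step <- step + 1L
        for (nm in names(p)) {
          g <- bg$grads[[nm]]
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
          mhat <- adam_m[[nm]] / (1 - b1^step)
          vhat <- adam_v[[nm]] / (1 - b2^step)
          p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      acc <- eval_acc(p, splits$val)
      metric <- if (!is.na(acc["stress"])) acc["stress"] else acc["variety"]
      # ties go to the later epoch: among equally accurate checkpoints keep
      # the most-trained parameters
      if (metric >= best$metric) best <- list(metric = metric, params = p)
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                     val_variety_acc = unname(acc["variety"]),
                                     val_stress_acc = unname(acc["stress"]), lr = lr)
    }
  })
  model$params <- best$params
  list(model = model, history = do.call(rbind, history))
}

#' Predict class labels
#'
#' @param model A trained [build_model()] result.
#' @param images List of RGB arrays.
#' @return Data frame with the predicted 0-based labels the model emits
#'   (`variety` and/or `stress_level`).
#' @export
predict_labels <- function(model, images) {
  lg <- model_forward(model, model_features(model, images))
  out <- data.frame(row.names = seq_along(images))
  if (!is.null(lg$variety)) out$variety <- max.col(lg$variety) - 1L
  if (!is.null(lg$stress)) out$stress_level <- max.col(lg$stress) - 1L
  out
}

#' Confusion matrix and accuracy for one task
#'
#' @param predicted,truth Integer vectors of 0-based labels.
#' @param n_classes Number of classes.
#' @return List: `confusion` (rows = truth), `confusion_norm` (row
#'   normalized), `accuracy` (= trace / total).
#' @export
confusion_stats <- function(predicted, truth, n_classes) {
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(truth = 0:(n_classes - 1), predicted = 0:(n_classes - 1)))
  for (i in seq_along(truth)) cm[truth[i] + 1L, predicted[i] + 1L] <-
    cm[truth[i] + 1L, predicted[i] + 1L] + 1L
  rs <- rowSums(cm)
  list(confusion = cm,
       confusion_norm = cm / ifelse(rs == 0, 1, rs),
       accuracy = sum(diag(cm)) / length(truth))
}

#' Evaluate a model on a labeled sample set
#'
#' @param model A trained model.
#' @param images List of RGB arrays.
#' @param labels Data frame with 0-based `variety` and `stress_level`.
#' @return Per-task [confusion_stats()] (`variety` and/or `stress`).
#' @export
evaluate_model <- function(model, images, labels) {
  stopifnot(length(images) > 0)
  pred <- predict_labels(model, images)
  out <- list()
  if (!is.null(pred$variety))
    out$variety <- confusion_stats(pred$variety, labels$variety,
                                   model$head_spec$n_variety_classes)
  if (!is.null(pred$stress_level))
    out$stress <- confusion_stats(pred$stress_level, labels$stress_level,
                                  model$head_spec$n_stress_classes)
  out
}

#' Desk-scale classification experiment on fixture plants
#'
#' Renders the labeled fixture set, splits it 6:2:2 stratified by variety,
#' trains the requested model on the toy backbone and evaluates the best
#' checkpoint. Desk-scale runs use a larger learning rate (5e-3) than the
#' full-size default recipe: the toy head on standardized pooled features
#' trains in a few hundred steps, where 5e-4 is calibrated for fine-tuning
#' large pretrained backbones over tens of thousands of steps.
#'
#' @param mode `"multi_task"` or `"single_task"`.
#' @param task Single-task target.
#' @param n_per_cell Images per (variety, stress level) cell.
#' @param epochs Training epochs.
#' @param seed Master seed (data rendering uses `seed`; splitting, model
#'   initialization and training use `seed + 1`).
#' @param dataset Optionally reuse a [render_classification_dataset()] result
#'   to avoid re-rendering.
#' @return List: `fit` (model + history), `val`, `pred` (per-task
#'   [confusion_stats()] on the validation / prediction split), `splits`,
#'   `dataset`.
#' @export
classification_experiment <- function(mode = c("multi_task", "single_task"),
                                      task = c("stress", "variety"),
                                      n_per_cell = 20, epochs = 30, seed = 1L,
                                      dataset = NULL) {
  mode <- match.arg(mode); task <- match.arg(task)
  if (is.null(dataset))
    dataset <- render_classification_dataset(n_per_cell = n_per_cell, seed = seed)
  splits <- stratified_split(dataset$labels, seed = seed + 1L)
  bb <- toy_backbone()
  spec <- multitask_head_spec(feature_dim = bb$feature_dim,
                              n_variety_classes = length(unique(dataset$labels$variety)),
                              n_stress_classes = length(unique(dataset$labels$stress_level)))
  model <- build_model(spec, mode, bb, task = task, seed = seed + 1L)
  fit <- train_model(model, dataset$images, dataset$labels, splits,
                     train_config(lr = 5e-3, epochs = epochs, seed = seed + 1L))
  val <- evaluate_model(fit$model, dataset$images[splits$val],
                        dataset$labels[splits$val, , drop = FALSE])
  pred <- evaluate_model(fit$model, dataset$images[splits$pred],
                         dataset$labels[splits$pred, , drop = FALSE])
  list(fit = fit, val = val, pred = pred, splits = splits, dataset = dataset)
}
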