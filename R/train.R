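#' Training configuration
#'
#' Defaults follow the published per-task optima: stimulus-based tasks use
#' learning rate 1e-3, weight decay 0.4, batch size 64; the
#' Aristotle-illusion vs. Reverse-illusion task uses 3e-4 / 0.4 / 32; the
#' Reverse-illusion occurrence task uses 1e-5 / 0.2 / 16. Optimization is
#' Adam-style stochastic gradient descent with decoupled weight decay
#' (weight decay multiplies the weights directly by `1 - lr * wd` each
#' step and is not added to the gradient); batch-norm scale/shift and
#' biases are exempt from decay. The checkpoint with the best validation
#' accuracy across epochs is kept.
#'
#' @param task Task name (sets defaults) or `NULL`.
#' @param lr Learning rate.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum number of epochs.
#' @param seed Seed for batch shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(task = NULL, lr = NULL, weight_decay = NULL,
                         batch_size = NULL, epochs = 50L, seed = 1L) {
  defaults <- list(
    aristotle_vs_reverse = c(1e-3, 0.4, 64),
    reverse_vs_async = c(1e-3, 0.4, 64),
    aristotle_vs_async = c(1e-3, 0.4, 64),
    aristotle_illusion_vs_reverse_illusion = c(3e-4, 0.4, 32),
    reverse_illusion_vs_no_reverse_illusion = c(1e-5, 0.2, 16)
  )
  def <- if (!is.null(task) && task %in% names(defaults)) defaults[[task]] else
    c(3e-4, 0.4, 32)
  lr <- lr %||% def[1]
  weight_decay <- weight_decay %||% def[2]
  batch_size <- batch_size %||% as.integer(def[3])
  stopifnot(lr >= 0, weight_decay >= 0, batch_size >= 1L, epochs >= 1L)
  structure(list(task = task, lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

# Adam-with-decoupled-weight-decay update state and step, over the named
# parameter tensors of the model. Decay applies to conv/fc weight matrices
# only.
adamw_init <- function(model) {
  st <- list(t = 0, m = list(), v = list())
  for (nm in names(model$layers)) {
    l <- model$layers[[nm]]
    for (f in c("W", "b", "gamma", "beta")) {
      if (!is.null(l[[f]])) {
        key <- paste0(nm, ".", f)
        st$m[[key]] <- l[[f]] * 0
        st$v[[key]] <- l[[f]] * 0
      }
    }
  }
  st
}

adamw_step <- function(model, grads, st, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  gmap <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")
  for (nm in names(grads)) {
    for (f in names(gmap)) {
      gr <- grads[[nm]][[gmap[[f]]]]
      if (is.null(gr)) next
      key <- paste0(nm, ".", f)
      st$m[[key]] <- beta1 * st$m[[key]] + (1 - beta1) * gr
      st$v[[key]] <- beta2 * st$v[[key]] + (1 - beta2) * gr^2
      mhat <- st$m[[key]] / (1 - beta1^st$t)
      vhat <- st$v[[key]] / (1 - beta2^st$t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (f == "W" && wd > 0)
        model$layers[[nm]][[f]] <- model$layers[[nm]][[f]] * (1 - lr * wd)
      model$layers[[nm]][[f]] <- model$layers[[nm]][[f]] - upd
    }
  }
  list(model = model, state = st)
}

#' Train one fold of the SFCN
#'
#' Minimizes softmax cross-entropy over the (already undersampled,
#' balanced) training samples with Adam-style SGD and decoupled weight
#' decay, recording training and validation accuracy each epoch and
#' keeping the weights of the epoch with the best validation accuracy.
#' Validation samples never contribute to a gradient step.
#'
#' @param model An `sfcn_model` (freshly built).
#' @param train_set,val_set Labeled `sample_set`s.
#' @param config A [train_config()].
#' @param verbose Print per-epoch accuracies.
#' @return List with `model` (best checkpoint), `curves` (per-epoch data
#'   frame of train/validation accuracy and mean loss), `best_epoch`.
#' @export
train_fold <- function(model, train_set, val_set, config, verbose = FALSE) {
  stopifnot(inherits(model, "sfcn_model"), inherits(config, "train_config"))
  n <- length(train_set$y)
  if (n == 0L || length(val_set$y) == 0L)
    stop("train_fold: empty training or validation set")
  set.seed(config$seed)
  st <- adamw_init(model)
  best <- list(acc = -Inf, model = model, epoch = 0L)
  curves <- data.frame(epoch = integer(), train_acc = numeric(),
                       val_acc = numeric(), train_loss = numeric())
  bn_names <- names(model$layers)[vapply(model$layers, function(l)
    l$type == "bn", logical(1))]
  for (ep in seq_len(config$epochs)) {
    ord <- sample(n)
    correct <- 0L
    losses <- c()
    # reset BN running stats; each epoch re-estimates population statistics
    # as the cumulative average of its batch statistics (momentum 1/step),
    # so short runs still yield calibrated eval-mode inference
    nb <- 0L
    for (nm in bn_names) {
      model$layers[[nm]]$running_mean[] <- 0
      model$layers[[nm]]$running_var[] <- 0
    }
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      nb <- nb + 1L
      for (nm in bn_names) model$layers[[nm]]$momentum <- 1 / nb
      xb <- train_set$x[, , , idx, drop = FALSE]
      yb <- train_set$y[idx]
      fwd <- sfcn_forward(model, xb, train = TRUE, keep_caches = TRUE)
      model <- fwd$model                     # batch-norm running stats
      ce <- softmax_xent(fwd$scores, yb)
      if (!is.finite(ce$loss))
        stop("train_fold: non-finite loss at epoch ", ep,
             " (lr too high or degenerate inputs)")
      losses <- c(losses, ce$loss)
      correct <- correct + sum(max.col(fwd$scores, ties.method = "first") - 1L == yb)
      if (config$lr > 0) {
        bwd <- sfcn_backward(model, fwd$caches, ce$dscores)
        upd <- adamw_step(model, bwd$grads, st, config$lr, config$weight_decay)
        model <- upd$model
        st <- upd$state
      }
    }
    val_pred <- predict(model, val_set)
    val_acc <- mean(val_pred == val_set$y)
    curves <- rbind(curves, data.frame(epoch = ep, train_acc = correct / n,
                                       val_acc = val_acc,
                                       train_loss = mean(losses)))
    if (val_acc > best$acc) best <- list(acc = val_acc, model = model, epoch = ep)
    if (verbose)
      message(sprintf("epoch %d: train %.3f val %.3f loss %.4f",
                      ep, correct / n, val_acc, mean(losses)))
  }
  list(model = best$model, curves = curves, best_epoch = best$epoch,
       final_model = model)
}

#' Classification metrics from model predictions
#'
#' Scores argmax predictions against labels; the positive class is label 1
#' (the illusion-occurrence class for perception tasks). Precision and
#' recall are defined as 0 when their denominators are 0, and the F1 score
#' is 0 when precision + recall = 0.
#'
#' @param model A trained `sfcn_model`.
#' @param val_set A labeled `sample_set`.
#' @return A `metrics` list: `accuracy`, `precision`, `recall`, `f1`, and
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate <- function(model, val_set) {
  if (is.null(val_set$y) || length(val_set$y) == 0L)
    stop("evaluate: empty validation set")
  pred <- predict(model, val_set)
  metrics_from_predictions(pred, val_set$y)
}

#' @rdname evaluate
#' @param pred,truth Integer 0/1 vectors of predictions and labels.
#' @export
metrics_from_predictions <- function(pred, truth) {
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(accuracy = (tp + tn) / length(truth),
                 precision = precision, recall = recall, f1 = f1,
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "metrics")
}

#' Cross-validated SFCN training
#'
#' Trains one freshly initialized model per fold on the fold's
#' majority-undersampled training samples, evaluates the best checkpoint on
#' the untouched validation samples, and aggregates the metric means across
#' folds. Fold models are retained for saliency analysis.
#'
#' @param set A labeled `sample_set`.
#' @param folds A [make_folds()] split of `set`.
#' @param config A [train_config()].
#' @param model_config An [sfcn_config()]; the grid must match the samples.
#' @param verbose Print progress.
#' @return A `cv_result`: list with `fold_metrics` (data frame),
#'   `mean_metrics`, `models`, `folds`, `curves` (per-fold list), and
#'   `val_predictions` (per-sample argmax labels where the sample was in
#'   validation).
#' @export
cross_validate <- function(set, folds, config, model_config, verbose = FALSE) {
  stopifnot(inherits(folds, "fold_spec"))
  k <- folds$k
  models <- vector("list", k)
  curves <- vector("list", k)
  rows <- list()
  val_pred <- rep(NA_integer_, length(set$y))
  for (f in seq_len(k)) {
    tr_idx <- folds$folds[[f]]$train
    va_idx <- folds$folds[[f]]$val
    us <- undersample_indices(set$y[tr_idx], seed = derive_seed(config$seed,
                                                                paste0("undersample_f", f)))
    tr <- subset_samples(set, tr_idx[us])
    va <- subset_samples(set, va_idx)
    mcfg <- model_config
    mcfg$seed <- derive_seed(config$seed, paste0("init_f", f))
    model <- build_sfcn(mcfg)
    tcfg <- config
    tcfg$seed <- derive_seed(config$seed, paste0("train_f", f))
    fit <- train_fold(model, tr, va, tcfg, verbose = verbose)
    met <- evaluate(fit$model, va)
    rows[[f]] <- data.frame(fold = f, accuracy = met$accuracy,
                            precision = met$precision, recall = met$recall,
                            f1 = met$f1, tp = met$tp, fp = met$fp,
                            fn = met$fn, tn = met$tn,
                            best_epoch = fit$best_epoch)
    models[[f]] <- fit$model
    curves[[f]] <- fit$curves
    val_pred[va_idx] <- predict(fit$model, va)
    if (verbose) message(sprintf("fold %d: accuracy %.3f", f, met$accuracy))
  }
  fold_metrics <- do.call(rbind, rows)
  mean_metrics <- colMeans(fold_metrics[, c("accuracy", "precision",
                                            "recall", "f1")])
  structure(list(fold_metrics = fold_metrics, mean_metrics = mean_metrics,
                 models = models, folds = folds, curves = curves,
                 val_predictions = val_pred, task = set$task),
            class = "cv_result")
}

#' Shuffle the labels of a sample set at the trial level
#'
#' Permutes class labels across trials (both epochs of a trial keep a
#' common label), producing a null dataset in which labels are independent
#' of the imaging data.
#'
#' @param set A labeled `sample_set`.
#' @param seed Integer seed.
#' @return The `sample_set` with permuted labels.
#' @export
shuffle_labels <- function(set, seed = 1L) {
  stopifnot(!is.null(set$y))
  skey <- sample_trial_key(set)
  keys <- unique(skey)
  trial_y <- set$y[match(keys, skey)]
  set.seed(seed)
  perm <- sample(trial_y)
  set$y <- perm[match(skey, keys)]
  set
}
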