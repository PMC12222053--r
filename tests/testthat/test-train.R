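test_that("metrics reproduce confusion-count arithmetic", {
  # TP=3, FP=1, FN=1, TN=5
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  truth <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- metrics_from_predictions(pred, truth)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(3, 1, 1, 5))
  # perfect predictions
  p <- metrics_from_predictions(truth, truth)
  expect_equal(c(p$accuracy, p$precision, p$recall, p$f1), rep(1, 4))
  # constant predictor on a balanced set
  bal <- rep(c(0, 1), 8)
  z <- metrics_from_predictions(rep(1, 16), bal)
  expect_equal(z$accuracy, 0.5)
  expect_equal(z$recall, 1)
  z0 <- metrics_from_predictions(rep(0, 16), bal)
  expect_equal(z0$accuracy, 0.5)
  expect_equal(z0$precision, 0)  # no positive predictions
  expect_equal(z0$f1, 0)
})

test_that("metrics agree with an independent per-sample tally", {
  set.seed(12)
  for (rep in 1:5) {
    truth <- rbinom(40, 1, 0.5)
    pred <- rbinom(40, 1, 0.5)
    m <- metrics_from_predictions(pred, truth)
    expect_equal(m$accuracy, mean(pred == truth))
    tp <- sum(pred & truth)
    expect_equal(m$precision, if (sum(pred)) tp / sum(pred) else 0)
    expect_equal(m$recall, if (sum(truth)) tp / sum(truth) else 0)
  }
  expect_error(evaluate(build_sfcn(sfcn_config(c(8, 8, 8), 2L)),
                        list(x = NULL, y = integer())), "empty")
})

test_that("a zero learning rate leaves the weights untouched", {
  set <- toy_sample_set(n_trials = 4L, effect = 2)
  m <- build_sfcn(sfcn_config(c(6L, 6L, 6L), block_channels = c(2L, 2L),
                              pool = c("max", "none"), seed = 3L))
  cfg <- train_config(lr = 0, epochs = 1L, batch_size = 4L, seed = 1L)
  fit <- train_fold(m, set, set, cfg)
  for (nm in names(m$layers)) {
    for (f in c("W", "b", "gamma", "beta")) {
      if (!is.null(m$layers[[nm]][[f]]))
        expect_equal(fit$final_model$layers[[nm]][[f]], m$layers[[nm]][[f]],
                     label = paste(nm, f))
    }
  }
})

test_that("training separates a strongly planted fixture and loss trends down", {
  set.seed(2)
  tr <- toy_sample_set(n_trials = 24L, effect = 3, seed = 10L)
  va <- toy_sample_set(n_trials = 8L, effect = 3, seed = 11L)
  m <- build_sfcn(sfcn_config(c(6L, 6L, 6L), block_channels = c(4L, 4L),
                              pool = c("max", "none"), seed = 5L))
  cfg <- train_config(lr = 3e-3, weight_decay = 0.1, epochs = 8L,
                      batch_size = 8L, seed = 2L)
  fit <- train_fold(m, tr, va, cfg)
  expect_gte(max(fit$curves$val_acc), 0.9)
  # loss is non-increasing on average: late-epoch mean below early-epoch mean
  expect_lt(mean(tail(fit$curves$train_loss, 3)),
            mean(head(fit$curves$train_loss, 3)))
  # the best checkpoint corresponds to the recorded best epoch
  expect_equal(fit$best_epoch, which.max(fit$curves$val_acc))
})

test_that("training on label-independent data stays at chance", {
  tr <- toy_sample_set(n_trials = 24L, effect = 0, seed = 20L)
  va <- toy_sample_set(n_trials = 16L, effect = 0, seed = 21L)
  m <- build_sfcn(sfcn_config(c(6L, 6L, 6L), block_channels = c(4L, 4L),
                              pool = c("max", "none"), seed = 6L))
  cfg <- train_config(lr = 3e-3, weight_decay = 0.1, epochs = 4L,
                      batch_size = 8L, seed = 3L)
  fit <- train_fold(m, tr, va, cfg)
  acc <- evaluate(fit$model, va)$accuracy
  # 32 validation samples: binomial 99% band around 0.5
  expect_gt(acc, 0.5 - 2.6 * sqrt(0.25 / 32))
  expect_lt(acc, 0.5 + 2.6 * sqrt(0.25 / 32) + 1e-9)
})

test_that("validation samples never drive gradient steps", {
  # the trained weights must be a function of the training set only:
  # replacing the validation set changes nothing in the final weights
  tr <- toy_sample_set(n_trials = 8L, effect = 2, seed = 30L)
  va1 <- toy_sample_set(n_trials = 4L, effect = 2, seed = 31L)
  va2 <- toy_sample_set(n_trials = 4L, effect = 0, seed = 32L)
  m <- build_sfcn(sfcn_config(c(6L, 6L, 6L), block_channels = c(2L, 2L),
                              pool = c("max", "none"), seed = 7L))
  cfg <- train_config(lr = 1e-3, epochs = 2L, batch_size = 4L, seed = 4L)
  f1 <- train_fold(m, tr, va1, cfg)
  f2 <- train_fold(m, tr, va2, cfg)
  expect_equal(f1$final_model$layers$fc$W, f2$final_model$layers$fc$W)
  expect_equal(f1$final_model$layers$b1_conv$W, f2$final_model$layers$b1_conv$W)
})

test_that("cross-validation aggregates fold metrics and is seed-deterministic", {
  set <- toy_sample_set(n_trials = 12L, effect = 3, seed = 40L)
  folds <- make_folds(set, k = 3L, seed = 2L)
  mcfg <- sfcn_config(c(6L, 6L, 6L), block_channels = c(2L, 2L),
                      pool = c("max", "none"))
  tcfg <- train_config(lr = 3e-3, epochs = 2L, batch_size = 4L, seed = 5L)
  cv1 <- cross_validate(set, folds, tcfg, mcfg)
  expect_equal(nrow(cv1$fold_metrics), 3L)
  expect_equal(unname(cv1$mean_metrics["accuracy"]),
               mean(cv1$fold_metrics$accuracy))
  cv2 <- cross_validate(set, folds, tcfg, mcfg)
  expect_equal(cv1$fold_metrics, cv2$fold_metrics)
  expect_equal(cv1$val_predictions, cv2$val_predictions)
  # every sample receives exactly one validation prediction
  expect_false(any(is.na(cv1$val_predictions)))
})

test_that("label shuffling permutes at the trial level", {
  set <- toy_sample_set(n_trials = 10L, seed = 50L)
  sh <- shuffle_labels(set, seed = 8L)
  expect_setequal(sh$y, set$y)
  expect_equal(sum(sh$y), sum(set$y))
  # both epochs of each trial share one label
  skey <- sfcnfmri:::sample_trial_key(sh)
  per_trial <- tapply(sh$y, skey, function(v) length(unique(v)))
  expect_true(all(per_trial == 1L))
})
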