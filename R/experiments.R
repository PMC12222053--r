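#' Configuration of the planted-signal recovery experiment
#'
#' The package's calibration experiment: 12 synthetic subjects, two
#' sessions each, on a 32-cubed grid with a 40-ROI atlas; a percept-class
#' BOLD effect of amplitude 2 (baseline units) is planted in three ROIs,
#' and the Aristotle-illusion vs. Reverse-illusion task is decoded with a
#' three-block, full-resolution SFCN (channels 4/8/8, no pooling, so
#' Grad-CAM lives on the 32-cubed input grid with a ~5 voxel receptive
#' field). Successful recovery means the FDR-significant set of the
#' grand-mean ROI statistic contains the planted ROIs with few false
#' positives — the false positives that do occur are spatial neighbors of
#' planted ROIs inheriting saliency spill.
#'
#' @param seed Global seed of the run.
#' @param n_sessions Sessions per subject (2 matches the emulated design;
#'   1 gives a faster replicate at roughly half the sample count).
#' @param epochs Training epochs per fold.
#' @param grid_shape,n_rois Atlas scale.
#' @return A `run_config` for [run_pipeline()].
#' @export
planted_recovery_config <- function(seed = 1L, n_sessions = 2L, epochs = 10L,
                                    grid_shape = c(32L, 32L, 32L),
                                    n_rois = 40L) {
  atlas <- generate_atlas(grid_shape, n_rois, seed = derive_seed(seed, "atlas"))
  cfg <- default_run_config(
    seed = seed,
    n_subjects = 12L,
    grid_shape = grid_shape,
    n_rois = n_rois,
    planted_rois = select_separated_rois(atlas, 3L),
    amplitude = 2,
    task = "aristotle_illusion_vs_reverse_illusion",
    epochs = epochs,
    k = 5L,
    alternative = "greater")
  cfg$paradigm$n_sessions <- as.integer(n_sessions)
  cfg$model$block_channels <- c(4L, 8L, 8L)
  cfg$model$pool <- c("none", "none", "none")
  cfg$train$lr <- 1e-3
  cfg$train$batch_size <- 8L
  cfg
}

#' Choose mutually distant ROIs for effect planting
#'
#' Greedy selection of `k` ROI labels whose centroids are maximally
#' separated: starts from the pair with the largest centroid distance and
#' repeatedly adds the ROI with the largest minimum distance to the
#' current set. Deterministic given the atlas; planting well-separated
#' effects keeps their saliency spill regions disjoint.
#'
#' @param atlas A `parcellation`.
#' @param k Number of ROIs to select.
#' @return Integer vector of `k` ROI labels, sorted.
#' @export
select_separated_rois <- function(atlas, k = 3L) {
  stopifnot(inherits(atlas, "parcellation"), k >= 1L, k <= atlas$n_rois)
  cent <- t(vapply(seq_len(atlas$n_rois), function(lab)
    colMeans(which(atlas$labels == lab, arr.ind = TRUE)), numeric(3)))
  d <- as.matrix(stats::dist(cent))
  pick <- as.integer(which(d == max(d), arr.ind = TRUE)[1, ])
  while (length(pick) < k) {
    rest <- setdiff(seq_len(atlas$n_rois), pick)
    mind <- vapply(rest, function(r) min(d[r, pick]), numeric(1))
    pick <- c(pick, rest[which.max(mind)])
  }
  sort(as.integer(pick[seq_len(k)]))
}

#' Label-shuffled null control
#'
#' Re-runs the decoding + saliency + ROI-statistics chain on data whose
#' task labels have been permuted at the trial level, so labels are
#' independent of the imaging data. Validation accuracy should sit inside
#' the trial-level binomial band around 0.5 — mirroring the failure of
#' stimulus-based decoding — and the ROI statistic should flag (almost) no
#' regions.
#'
#' @param seed Integer seed.
#' @param n_subjects,grid_shape,n_rois,epochs Scale of the control run
#'   (defaults keep it to about a minute of CPU).
#' @return List with `accuracy` (pooled validation accuracy), `n_trials`,
#'   `n_significant`, `n_rois`, and the underlying `roi_stats` table.
#' @export
shuffled_label_control <- function(seed = 1L, n_subjects = 12L,
                                   grid_shape = c(16L, 16L, 16L),
                                   n_rois = 20L, epochs = 6L) {
  pcfg <- paradigm_config(n_sessions = 1L, seed = derive_seed(seed, "paradigm"))
  ev <- generate_paradigm(pcfg, n_subjects)
  ev <- simulate_behavior(ev, behavior_model(seed = derive_seed(seed, "behavior")))
  atlas <- generate_atlas(grid_shape, n_rois, seed = derive_seed(seed, "atlas"))
  eff <- effect_spec(percept_two = stats::setNames(rep(2, 2), c(2L, 11L)))
  samples <- build_samples(ev, atlas, eff, noise_spec(),
                           seed = derive_seed(seed, "bold"))
  labeled <- assign_task_labels(samples, "aristotle_illusion_vs_reverse_illusion")
  labeled <- shuffle_labels(labeled, seed = derive_seed(seed, "shuffle"))
  folds <- make_folds(labeled, k = 5L, seed = derive_seed(seed, "folds"))
  mcfg <- sfcn_config(grid_shape, block_channels = c(4L, 8L, 8L),
                      pool = c("none", "none", "none"))
  tcfg <- train_config(task = labeled$task, lr = 1e-3, batch_size = 8L,
                       epochs = epochs, seed = derive_seed(seed, "train"))
  cv <- cross_validate(labeled, folds, tcfg, mcfg)
  sal <- gradcam_validation_maps(cv, labeled)
  mat <- subject_roi_matrix(sal$subject_maps, atlas, sal$subjects)
  st <- test_rois(mat, alternative = "greater")
  acc <- mean(cv$val_predictions == labeled$y)
  list(accuracy = acc,
       n_trials = length(unique(sample_trial_key(labeled))),
       n_significant = sum(st$significant),
       n_rois = n_rois,
       roi_stats = st,
       cv = cv)
}
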