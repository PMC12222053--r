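test_that("atlas generation partitions the brain mask into nonempty compact ROIs", {
  atlas <- generate_atlas(c(20L, 20L, 20L), n_rois = 12L, seed = 3L)
  labs <- as.vector(atlas$labels)
  expect_setequal(unique(labs), 0:12)
  counts <- table(labs[labs > 0])
  expect_length(counts, 12L)
  expect_true(all(counts >= 8))
  # background = complement of the mask, mask = union of ROIs (disjoint by
  # construction: each voxel carries exactly one label)
  expect_gt(sum(labs == 0), 0)
  # determinism and seed sensitivity
  expect_identical(atlas$labels, generate_atlas(c(20L, 20L, 20L), 12L, seed = 3L)$labels)
  expect_false(identical(atlas$labels, generate_atlas(c(20L, 20L, 20L), 12L, seed = 4L)$labels))
})

test_that("single-ROI atlas covers the whole mask and over-budget requests error", {
  one <- generate_atlas(c(12L, 12L, 12L), n_rois = 1L, seed = 1L)
  expect_setequal(unique(as.vector(one$labels)), c(0L, 1L))
  expect_error(generate_atlas(c(6L, 6L, 6L), n_rois = 100L), "at least 8")
})

test_that("HRF regressor construction matches a naive convolution oracle", {
  tr <- 3
  h <- hrf_double_gamma(dt = tr)
  u <- sfcnfmri:::epoch_boxcar(c(0, 48, 96), 15, tr, 240)
  fast <- sfcnfmri:::convolve_hrf(u, h, tr)
  slow <- conv_oracle(u, h, tr)
  expect_equal(fast, slow, tolerance = 1e-10)
  # sustained stimulation plateaus at 1 under the kernel normalization
  u_inf <- rep(1, 240)
  plateau <- sfcnfmri:::convolve_hrf(u_inf, h, tr)
  expect_equal(plateau[200], 1, tolerance = 1e-6)
})

test_that("noise-free simulation is exact: baseline, confinement, and amplitude", {
  cfg <- paradigm_config(n_sessions = 1L, seed = 11L)
  ev <- generate_paradigm(cfg, 1L)
  ev$q1_response <- ifelse(ev$condition == "Aristotle", 2L, 1L)
  atlas <- generate_atlas(c(10L, 10L, 10L), 4L, seed = 2L)
  quiet <- noise_spec(white_sd = 0, ar1 = 0, subject_amp_jitter_sd = 0,
                      baseline = 100)
  # zero effects: every voxel sits at baseline for the whole scan
  v0 <- simulate_session(ev, 1, 1, atlas, effect_spec(), quiet, seed = 1L)
  expect_true(all(v0$data == 100))
  expect_equal(dim(v0$data)[4], 240L)
  # amplitude a in ROI 2 for the Aristotle condition: signal equals
  # baseline + a * (boxcar x HRF) inside ROI 2, exactly baseline elsewhere
  a <- 2.5
  eff <- effect_spec(Aristotle = c("2" = a))
  v <- simulate_session(ev, 1, 1, atlas, eff, quiet, seed = 1L)
  sel <- ev$condition == "Aristotle"
  u <- sfcnfmri:::epoch_boxcar(c(ev$epoch1_onset_s[sel], ev$epoch2_onset_s[sel]),
                               15, cfg$tr_s, 240)
  reg <- conv_oracle(u, hrf_double_gamma(dt = cfg$tr_s), cfg$tr_s)
  vox_in <- which(atlas$labels == 2L)[1]
  vox_out <- which(atlas$labels == 1L)[1]
  coord <- arrayInd(vox_in, dim(atlas$labels))
  ts_in <- v$data[coord[1], coord[2], coord[3], ]
  expect_equal(ts_in, 100 + a * reg, tolerance = 1e-9)
  coord2 <- arrayInd(vox_out, dim(atlas$labels))
  expect_true(all(v$data[coord2[1], coord2[2], coord2[3], ] == 100))
  # epoch-window mean exceeds a rest-window mean by a * mean(regressor)
  delay <- 2L
  ep_idx <- round(ev$epoch1_onset_s[sel][1] / 3) + 1L + delay + 0:4
  expect_equal(mean(ts_in[ep_idx]) - 100, a * mean(reg[ep_idx]), tolerance = 1e-9)
})

test_that("simulated volumes are reproducible and effects validate ROI labels", {
  cfg <- paradigm_config(n_sessions = 1L, n_trials_per_condition_per_session = 2L,
                         seed = 3L)
  ev <- simulate_behavior(generate_paradigm(cfg, 1L), behavior_model(seed = 3L))
  atlas <- generate_atlas(c(8L, 8L, 8L), 2L, seed = 1L)
  v1 <- simulate_session(ev, 1, 1, atlas, effect_spec(), noise_spec(), seed = 42L)
  v2 <- simulate_session(ev, 1, 1, atlas, effect_spec(), noise_spec(), seed = 42L)
  expect_identical(v1$data, v2$data)
  expect_error(simulate_session(ev, 1, 1, atlas, effect_spec(percept_two = c("9" = 1)),
                                noise_spec(), seed = 1L), "absent from atlas")
})

test_that("stronger planted amplitudes yield monotonically better decoding", {
  acc_at <- function(amp) {
    pcfg <- paradigm_config(n_sessions = 1L, seed = 61L)
    ev <- simulate_behavior(generate_paradigm(pcfg, 8L), behavior_model(seed = 61L))
    atlas <- generate_atlas(c(16L, 16L, 16L), 8L, seed = 62L)
    eff <- if (amp > 0) effect_spec(percept_two = setNames(rep(amp, 2), c(2L, 6L)))
           else effect_spec()
    s <- build_samples(ev, atlas, eff, noise_spec(), seed = 63L)
    lab <- assign_task_labels(s, "aristotle_illusion_vs_reverse_illusion")
    folds <- make_folds(lab, k = 4L, seed = 64L)
    tr <- undersample_majority(sfcnfmri:::subset_samples(lab, folds$folds[[1]]$train),
                               seed = 65L)
    va <- sfcnfmri:::subset_samples(lab, folds$folds[[1]]$val)
    m <- build_sfcn(sfcn_config(c(16L, 16L, 16L), block_channels = c(4L, 8L, 8L),
                                pool = rep("none", 3), seed = 66L))
    fit <- train_fold(m, tr, va, train_config(lr = 2e-3, epochs = 15L,
                                              batch_size = 8L, seed = 67L))
    evaluate(fit$model, va)$accuracy
  }
  accs <- vapply(c(0, 1, 4), acc_at, numeric(1))
  expect_lte(accs[1], accs[2] + 0.05)
  expect_lte(accs[2], accs[3] + 0.05)
  expect_gte(accs[3], accs[1] + 0.2)
})

test_that("atlas and volumes round-trip through NIfTI", {
  skip_if_not_installed("RNifti")
  atlas <- generate_atlas(c(10L, 10L, 10L), 3L, seed = 7L)
  path <- tempfile(fileext = ".nii.gz")
  write_atlas_nifti(atlas, path)
  back <- read_atlas_nifti(path)
  expect_identical(back$labels, atlas$labels)
  expect_equal(back$n_rois, 3L)
  expect_equal(unname(back$roi_names), unname(atlas$roi_names))
  vpath <- tempfile(fileext = ".nii.gz")
  arr <- array(rnorm(8^3 * 2), dim = c(8, 8, 8, 2))
  write_volume_nifti(arr, vpath, tr_s = 3)
  expect_equal(as.array(RNifti::readNifti(vpath)), arr, tolerance = 1e-6,
               ignore_attr = TRUE)
})
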