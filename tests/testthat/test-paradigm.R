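test_that("default paradigm reproduces the published session arithmetic", {
  cfg <- paradigm_config()
  expect_equal(cfg$trial_cycle_s, 48)
  expect_equal(cfg$n_trials_per_session, 15L)
  expect_equal(cfg$session_duration_s, 720)
  ev <- generate_paradigm(cfg, n_subjects = 1L)
  expect_equal(nrow(ev), 30L)  # 2 sessions x 15 trials
  # total experimental time per participant
  expect_equal(cfg$n_sessions * cfg$session_duration_s, 1440)
  # onsets follow the stim -> Q1 -> stim -> Q2 -> rest cycle
  s1 <- ev[ev$session == 1L, ]
  expect_equal(s1$epoch1_onset_s, (s1$trial - 1) * 48)
  expect_equal(s1$epoch2_onset_s, s1$epoch1_onset_s + 15 + 3)
  # last epoch ends inside the session
  expect_lte(max(s1$epoch2_onset_s) + 15, 720 - 9 + 15)
})

test_that("session duration identity holds for arbitrary configs", {
  for (seed in 1:3) {
    set.seed(seed)
    cfg <- paradigm_config(
      n_sessions = sample(1:3, 1),
      n_trials_per_condition_per_session = sample(1:6, 1),
      stim_duration_s = sample(c(9, 12, 15), 1),
      q1_duration_s = 3, q2_duration_s = 6,
      rest_duration_s = sample(c(6, 9), 1), seed = seed)
    ev <- generate_paradigm(cfg, n_subjects = 2L)
    per_session <- table(ev$subject, ev$session)
    expect_true(all(per_session == cfg$n_trials_per_session))
    expect_equal(cfg$session_duration_s,
                 cfg$n_trials_per_session * cfg$trial_cycle_s)
    # exact condition balance for every subject/session
    tab <- table(ev$condition, paste(ev$subject, ev$session))
    expect_true(all(tab == cfg$n_trials_per_condition_per_session))
  }
})

test_that("paradigm generation handles empty and degenerate cases", {
  cfg0 <- paradigm_config(n_trials_per_condition_per_session = 0L)
  ev0 <- generate_paradigm(cfg0, n_subjects = 2L)
  expect_equal(nrow(ev0), 0L)
  expect_equal(cfg0$session_duration_s, 0)
  expect_error(paradigm_config(stim_duration_s = -1), "positive")
  expect_error(generate_paradigm(paradigm_config(), n_subjects = 0), ">= 1")
})

test_that("paradigm randomization is seeded and condition orders differ", {
  a <- generate_paradigm(paradigm_config(seed = 3L), 2L)
  b <- generate_paradigm(paradigm_config(seed = 3L), 2L)
  c <- generate_paradigm(paradigm_config(seed = 4L), 2L)
  expect_identical(a, b)
  expect_false(identical(a$condition, c$condition))
})

test_that("simulated behavior follows the per-condition response model", {
  ev <- generate_paradigm(paradigm_config(seed = 2L), 5L)
  # degenerate probabilities: every Aristotle trial reports the illusion
  m1 <- behavior_model(p_illusion = c(Aristotle = 1, Reverse = 0.5, Asynchronous = 0),
                       p_nonresponse = c(Aristotle = 0, Reverse = 0, Asynchronous = 0),
                       seed = 1L)
  out <- simulate_behavior(ev, m1)
  expect_true(all(out$q1_response[out$condition == "Aristotle"] == 2L))
  expect_true(all(out$q1_response[out$condition == "Asynchronous"] == 2L))
  # fixed seed reproducibility
  expect_identical(out, simulate_behavior(ev, m1))
  # all non-response leaves rates undefined
  mnr <- behavior_model(p_nonresponse = c(Aristotle = 1, Reverse = 1, Asynchronous = 1))
  nr <- simulate_behavior(ev, mnr)
  expect_true(all(is.na(nr$q1_response)))
  expect_error(summarize_behavior(nr), "undefined")
  # unknown condition
  bad <- ev
  bad$condition[1] <- "Mystery"
  expect_error(simulate_behavior(bad, m1), "unknown condition")
})

test_that("cohort illusion counts match the published ratios within binomial error", {
  # default probabilities are the published response ratios; at 300
  # trials/condition the simulated cohort counts should fall within ~4 SD
  ev <- generate_paradigm(paradigm_config(seed = 8L), 30L)
  out <- simulate_behavior(ev, behavior_model(seed = 9L))
  s <- summarize_behavior(out)$by_condition
  probs <- c(Aristotle = 544 / 596, Reverse = 212 / 594, Asynchronous = 48 / 590)
  for (cc in names(probs)) {
    row <- s[s$condition == cc, ]
    p <- probs[[cc]]
    tol <- 4 * sqrt(p * (1 - p) / row$n_responded)
    expect_lt(abs(row$illusion_rate - p), tol)
  }
})

test_that("illusion-rate estimator is unbiased under the generating probability", {
  cfg <- paradigm_config(n_sessions = 1L, seed = 10L)
  ev <- generate_paradigm(cfg, 4L)
  p_true <- 0.7
  rates <- vapply(1:200, function(i) {
    m <- behavior_model(p_illusion = c(Aristotle = p_true, Reverse = 0.3,
                                       Asynchronous = 0.1),
                        seed = 1000L + i)
    s <- summarize_behavior(simulate_behavior(ev, m))
    s$by_condition$illusion_rate[s$by_condition$condition == "Aristotle"]
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - p_true), 4 * se + 1e-9)
})

test_that("behavior summary computes rates and distances from responded trials", {
  ev <- generate_paradigm(paradigm_config(seed = 1L), 30L)
  ev <- fill_q1_from_counts(ev, cohort_counts)
  s <- summarize_behavior(ev)$by_condition
  # published Aristotle response ratio: 272 illusion / 298 responded trials
  expect_equal(s$illusion_rate[s$condition == "Aristotle"], 272 / 298)
  expect_equal(s$n_responded[s$condition == "Reverse"], 297)
  # all Q1 = 1 under Reverse: illusion rate 1
  ev2 <- generate_paradigm(paradigm_config(seed = 2L), 1L)
  ev2$q1_response <- ifelse(ev2$condition == "Reverse", 1L, 2L)
  for (cc in unique(ev2$condition)) {
    idx <- which(ev2$condition == cc)
    ev2$q2_response[idx] <- rep(c(1L, 4L), length.out = length(idx))
  }
  s2 <- summarize_behavior(ev2)$by_condition
  expect_equal(s2$illusion_rate[s2$condition == "Reverse"], 1)
  # mean perceived distance is the plain mean of Q2 over responses
  expect_equal(unique(s2$mean_perceived_distance), 2.5)
})

test_that("events TSV round-trips through the BIDS-style serialization", {
  ev <- simulate_behavior(generate_paradigm(paradigm_config(seed = 6L), 2L),
                          behavior_model(seed = 6L))
  path <- tempfile(fileext = ".tsv")
  write_events_tsv(ev, path)
  back <- read_events_tsv(path, config = attr(ev, "paradigm_config"))
  expect_equal(as.data.frame(back), as.data.frame(ev))
  # two rows per trial in the long file
  long <- read.table(path, sep = "\t", header = TRUE)
  expect_equal(nrow(long), 2L * nrow(ev))
})
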