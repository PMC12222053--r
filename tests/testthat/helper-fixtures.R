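# Shared fixtures and independent oracles for the test suite.

# Session-level memo so expensive simulated fixtures are built once per
# test run and shared across files.
.fixture_env <- new.env(parent = emptyenv())
cached_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Event table whose Q1 responses reproduce the published cohort response
# counts exactly (trial-level counts; epoch-level counts are twice these).
cohort_counts <- list(
  Aristotle = c(one = 26, two = 272, none = 2),
  Reverse = c(one = 106, two = 191, none = 3),
  Asynchronous = c(one = 24, two = 271, none = 5)
)

published_cohort_events <- function() {
  cached_fixture("cohort_events", function() {
    ev <- generate_paradigm(paradigm_config(seed = 5L), n_subjects = 30L)
    fill_q1_from_counts(ev, cohort_counts)
  })
}

# Small labeled sample set built directly from arrays (no simulation), for
# trainer/fold mechanics.
toy_sample_set <- function(n_trials = 12L, d = c(6L, 6L, 6L), seed = 1L,
                           effect = 0) {
  set.seed(seed)
  n <- 2L * n_trials
  x <- array(rnorm(prod(d) * n), dim = c(d, n))
  y_trial <- rep(0:1, length.out = n_trials)
  y <- rep(y_trial, each = 2L)
  if (effect != 0) x[1:3, 1:3, 1:3, y == 1L] <- x[1:3, 1:3, 1:3, y == 1L] + effect
  meta <- data.frame(subject = rep(seq_len(max(1L, n_trials %/% 4L)),
                                   length.out = n_trials)[rep(seq_len(n_trials), each = 2L)],
                     session = 1L,
                     trial = rep(seq_len(n_trials), each = 2L),
                     epoch = rep(1:2, n_trials),
                     condition = ifelse(y == 1L, "Aristotle", "Reverse"),
                     q1 = ifelse(y == 1L, 2L, 1L))
  structure(list(x = x, y = y, meta = meta, task = "toy",
                 classes = c(neg = "reverse", pos = "aristotle")),
            class = "sample_set")
}

# Reduced-scale planted-recovery replicate (16^3 grid, 20 ROIs, one
# session), cached per seed and shared across test files.
small_recovery_fixture <- function(seed) {
  cached_fixture(paste0("small_recovery_", seed), function() {
    cfg <- planted_recovery_config(seed = seed, n_sessions = 1L, epochs = 8L,
                                   grid_shape = c(16L, 16L, 16L), n_rois = 20L)
    res <- run_pipeline(cfg, out_dir = tempfile(), verbose = FALSE)
    list(cfg = cfg, res = res)
  })
}

# Exhaustive signed-rank enumeration oracle: exact p-value of the
# one-sample Wilcoxon signed-rank test by enumerating all 2^n sign
# assignments of the ranked absolute differences.
wilcoxon_exact_oracle <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Naive O(n^2) discrete convolution oracle (causal, truncated), matching
# the regressor construction used by the BOLD simulator.
conv_oracle <- function(u, h, dt) {
  n <- length(u)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(min(i, length(h)))) acc <- acc + u[i - j + 1] * h[j]
    out[i] <- acc * dt
  }
  out
}
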