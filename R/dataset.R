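#' Extract one 3D sample per stimulation epoch
#'
#' For every stimulation epoch of every trial in the session, averages the
#' volumes falling in the hemodynamically delayed window
#' `[onset + delay, onset + delay + duration)` into a single 3D sample, then
#' z-scores each voxel across the session's samples (a voxel with zero
#' variance maps to 0). The default delay of 2 TRs (6 s) matches the
#' canonical HRF peak.
#'
#' @param vol A `volume4d` from [simulate_session()] (or equivalent).
#' @param events Event table rows for the same subject/session.
#' @param delay_trs Hemodynamic delay of the sampling window, in TRs.
#' @param zscore Z-score voxelwise across the session's samples
#'   (default `TRUE`).
#' @return A `sample_set`: list with `x` (4D array x,y,z,sample) and `meta`
#'   (data frame `subject`, `session`, `trial`, `epoch`, `condition`, `q1`).
#' @export
extract_epoch_samples <- function(vol, events, delay_trs = 2L, zscore = TRUE) {
  stopifnot(inherits(vol, "volume4d"))
  ev <- events[events$subject == vol$subject & events$session == vol$session, ,
               drop = FALSE]
  if (nrow(ev) == 0L) stop("extract_epoch_samples: no events for this session")
  tr <- vol$tr_s
  n_vols <- dim(vol$data)[4]
  d <- dim(vol$data)[1:3]
  n_win <- as.integer(round(ev$epoch_duration_s[1] / tr))
  n_samp <- 2L * nrow(ev)
  x <- array(0, dim = c(d, n_samp))
  meta <- data.frame(subject = integer(n_samp), session = integer(n_samp),
                     trial = integer(n_samp), epoch = integer(n_samp),
                     condition = character(n_samp), q1 = integer(n_samp),
                     stringsAsFactors = FALSE)
  k <- 0L
  for (i in seq_len(nrow(ev))) {
    for (ep in 1:2) {
      onset <- if (ep == 1L) ev$epoch1_onset_s[i] else ev$epoch2_onset_s[i]
      first <- as.integer(round(onset / tr)) + 1L + delay_trs
      idx <- first:(first + n_win - 1L)
      if (max(idx) > n_vols)
        stop("extract_epoch_samples: delayed window of trial ", ev$trial[i],
             " epoch ", ep, " (volumes ", first, "-", max(idx),
             ") exceeds the ", n_vols, "-volume scan")
      k <- k + 1L
      win <- matrix(vol$data[, , , idx, drop = FALSE], nrow = prod(d))
      x[, , , k] <- rowMeans(win)
      meta$subject[k] <- ev$subject[i]; meta$session[k] <- ev$session[i]
      meta$trial[k] <- ev$trial[i]; meta$epoch[k] <- ep
      meta$condition[k] <- ev$condition[i]
      meta$q1[k] <- ev$q1_response[i]
    }
  }
  if (zscore && n_samp > 1L) {
    m <- matrix(x, nrow = prod(d), ncol = n_samp)
    mu <- rowMeans(m)
    sdv <- sqrt(rowMeans((m - mu)^2))
    m <- (m - mu) / ifelse(sdv > 0, sdv, 1)
    m[sdv == 0, ] <- 0
    x <- array(m, dim = c(d, n_samp))
  }
  structure(list(x = x, meta = meta), class = "sample_set")
}

#' Build epoch metadata without imaging data
#'
#' Produces the same per-epoch metadata as [extract_epoch_samples()] but
#' with `x = NULL`; useful for class-size bookkeeping on behavioral tables
#' alone (e.g. replaying published response counts through the task
#' labeler).
#'
#' @param events An event table.
#' @return A `sample_set` with `x = NULL`.
#' @export
epoch_meta <- function(events) {
  meta <- do.call(rbind, lapply(1:2, function(ep) data.frame(
    subject = events$subject, session = events$session, trial = events$trial,
    epoch = ep, condition = events$condition, q1 = events$q1_response,
    stringsAsFactors = FALSE)))
  ord <- order(meta$subject, meta$session, meta$trial, meta$epoch)
  meta <- meta[ord, ]
  rownames(meta) <- NULL
  structure(list(x = NULL, meta = meta), class = "sample_set")
}

#' Concatenate sample sets
#'
#' @param sets List of `sample_set` objects on identical grids.
#' @return One combined `sample_set`.
#' @export
bind_sample_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  meta <- do.call(rbind, lapply(sets, function(s) s$meta))
  rownames(meta) <- NULL
  if (is.null(sets[[1]]$x)) return(structure(list(x = NULL, meta = meta),
                                             class = "sample_set"))
  d <- dim(sets[[1]]$x)[1:3]
  n <- sum(vapply(sets, function(s) dim(s$x)[4], integer(1)))
  x <- array(0, dim = c(d, n))
  k <- 0L
  for (s in sets) {
    ns <- dim(s$x)[4]
    x[, , , k + seq_len(ns)] <- s$x
    k <- k + ns
  }
  structure(list(x = x, meta = meta), class = "sample_set")
}

# Binary task definitions: positive class listed first (label 1). Stimulus
# tasks select by condition; perception tasks by condition + Q1 report.
task_definitions <- function() {
  list(
    aristotle_vs_reverse = list(
      pos = list(condition = "Aristotle"), neg = list(condition = "Reverse")),
    reverse_vs_async = list(
      pos = list(condition = "Reverse"), neg = list(condition = "Asynchronous")),
    aristotle_vs_async = list(
      pos = list(condition = "Aristotle"), neg = list(condition = "Asynchronous")),
    aristotle_illusion_vs_reverse_illusion = list(
      pos = list(condition = "Aristotle", q1 = 2L),
      neg = list(condition = "Reverse", q1 = 1L)),
    reverse_illusion_vs_no_reverse_illusion = list(
      pos = list(condition = "Reverse", q1 = 1L),
      neg = list(condition = "Reverse", q1 = 2L))
  )
}

#' Names of the available binary decoding tasks
#' @return Character vector of task names.
#' @export
task_names <- function() names(task_definitions())

#' Label epoch samples for a binary decoding task
#'
#' Selects the samples belonging to the task's two classes and attaches
#' binary labels (the first-named class of the task is the positive class,
#' label 1; for perception tasks this is the illusion-occurrence class).
#' Epochs of non-responded trials are always excluded.
#'
#' @param set A `sample_set`.
#' @param task One of [task_names()].
#' @return A labeled `sample_set` with fields `y` (0/1 integer vector),
#'   `task`, and `classes` (names of the negative/positive class).
#' @export
assign_task_labels <- function(set, task) {
  stopifnot(inherits(set, "sample_set"))
  defs <- task_definitions()
  if (!task %in% names(defs))
    stop("assign_task_labels: unknown task '", task, "'; available: ",
         paste(names(defs), collapse = ", "))
  def <- defs[[task]]
  match_class <- function(rule) {
    sel <- set$meta$condition == rule$condition & !is.na(set$meta$q1)
    if (!is.null(rule$q1)) sel <- sel & set$meta$q1 == rule$q1
    sel
  }
  pos <- match_class(def$pos)
  neg <- match_class(def$neg)
  keep <- which(pos | neg)
  if (length(keep) == 0L)
    stop("assign_task_labels: no samples match task '", task,
         "' (all trials non-responded or conditions absent)")
  meta <- set$meta[keep, , drop = FALSE]
  rownames(meta) <- NULL
  out <- list(
    x = if (is.null(set$x)) NULL else set$x[, , , keep, drop = FALSE],
    meta = meta,
    y = as.integer(pos[keep]),
    task = task,
    classes = c(neg = paste(unlist(def$neg), collapse = "_q"),
                pos = paste(unlist(def$pos), collapse = "_q"))
  )
  class(out) <- "sample_set"
  out
}

# Unique trial keys of a sample set, in first-appearance order.
trial_keys <- function(set) {
  unique(paste(set$meta$subject, set$meta$session, set$meta$trial, sep = "_"))
}

sample_trial_key <- function(set) {
  paste(set$meta$subject, set$meta$session, set$meta$trial, sep = "_")
}

#' Randomly undersample the majority class
#'
#' Balances a labeled sample set by discarding a random subset of the
#' majority class (without replacement) until both classes have the
#' minority count. Intended for training portions only; validation data
#' keep their raw class ratios.
#'
#' @param set A labeled `sample_set`.
#' @param seed Integer seed.
#' @return The balanced `sample_set` (sample order preserved).
#' @export
undersample_majority <- function(set, seed = 1L) {
  stopifnot(inherits(set, "sample_set"), !is.null(set$y))
  keep <- undersample_indices(set$y, seed)
  subset_samples(set, keep)
}

# Index-level undersampling used internally by cross_validate.
undersample_indices <- function(y, seed = 1L) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("undersample_majority: both classes must be nonempty (have ",
         n0, " / ", n1, ")")
  if (n1 == n0) return(seq_along(y))
  maj <- if (n1 > n0) 1L else 0L
  k <- min(n0, n1)
  set.seed(seed)
  keep_maj <- sort(sample(which(y == maj), k))
  sort(c(which(y != maj), keep_maj))
}

subset_samples <- function(set, idx) {
  out <- set
  out$meta <- set$meta[idx, , drop = FALSE]
  rownames(out$meta) <- NULL
  if (!is.null(set$x)) out$x <- set$x[, , , idx, drop = FALSE]
  if (!is.null(set$y)) out$y <- set$y[idx]
  out
}

#' Trial-grouped k-fold cross-validation split
#'
#' Shuffles the unique trials of a labeled sample set and deals them into
#' `k` folds (earlier folds absorb remainders), guaranteeing that both
#' stimulation epochs of a trial land on the same side of every
#' train/validation split. With the default `k = 5` each fold's validation
#' set holds ~20% of trials (an 8:2 ratio).
#'
#' @param set A labeled `sample_set`.
#' @param k Number of folds.
#' @param seed Integer seed for the trial shuffle.
#' @return A `fold_spec`: list with `k`, `seed`, `trial_fold` (named fold
#'   id per trial key) and per-fold `train` / `val` sample-index vectors.
#' @export
make_folds <- function(set, k = 5L, seed = 1L) {
  stopifnot(inherits(set, "sample_set"), !is.null(set$y))
  keys <- trial_keys(set)
  skey <- sample_trial_key(set)
  if (length(keys) < k)
    stop("make_folds: only ", length(keys), " trials for k = ", k, " folds")
  for (cl in 0:1) {
    ncl <- length(unique(skey[set$y == cl]))
    if (ncl < k)
      stop("make_folds: class ", cl, " has only ", ncl, " trials for k = ", k)
  }
  set.seed(seed)
  shuffled <- sample(keys)
  # contiguous chunks, earlier folds take remainders
  sizes <- rep(length(shuffled) %/% k, k)
  rem <- length(shuffled) %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  fold_of <- rep(seq_len(k), times = sizes)
  trial_fold <- stats::setNames(fold_of, shuffled)
  folds <- lapply(seq_len(k), function(f) {
    val_keys <- names(trial_fold)[trial_fold == f]
    val <- which(skey %in% val_keys)
    list(train = setdiff(seq_along(skey), val), val = val)
  })
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 trial_fold = trial_fold, folds = folds),
            class = "fold_spec")
}

#' Simulate BOLD and extract labeled epoch samples, session by session
#'
#' Streams through every subject/session of the event table: simulates the
#' session volume, extracts its delayed-window epoch samples, and discards
#' the volume — keeping peak memory at one session. Returns the unlabeled
#' pooled sample set; apply [assign_task_labels()] afterwards.
#'
#' @inheritParams simulate_session
#' @param delay_trs Hemodynamic sampling delay in TRs.
#' @param zscore Voxelwise per-session z-scoring flag.
#' @return A `sample_set` covering all epochs of all sessions.
#' @export
build_samples <- function(events, atlas, effects, noise = noise_spec(),
                          seed = 1L, delay_trs = 2L, zscore = TRUE, hrf = NULL) {
  keys <- unique(events[, c("subject", "session")])
  sets <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    vol <- simulate_session(events, keys$subject[i], keys$session[i],
                            atlas, effects, noise, seed, hrf)
    sets[[i]] <- extract_epoch_samples(vol, events, delay_trs, zscore)
  }
  bind_sample_sets(sets)
}
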