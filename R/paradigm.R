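#' Paradigm configuration for the tactile-illusion block design
#'
#' Describes one participant's scanning protocol: trials cycle through a
#' first 15-s stimulation epoch, a 3-s "how many stimuli?" question (Q1),
#' a second 15-s stimulation epoch with the same stimulus, a 6-s perceived
#' distance question (Q2), and a 9-s rest. With the defaults each trial
#' cycle lasts 48 s, a session holds five trials of each of the three
#' stimulation conditions (15 trials, 720 s), and a participant completes
#' two sessions (1,440 s).
#'
#' @param n_sessions Number of scanning sessions per participant.
#' @param n_trials_per_condition_per_session Trials of each condition per
#'   session.
#' @param stim_duration_s Duration of each of the two stimulation epochs
#'   within a trial, in seconds.
#' @param q1_duration_s Duration of the first (number-of-stimuli) question.
#' @param q2_duration_s Duration of the second (perceived-distance) question.
#' @param rest_duration_s Rest period closing each trial cycle.
#' @param tr_s Volume repetition time in seconds.
#' @param conditions Ordered condition names.
#' @param seed Integer seed controlling the per-session randomization of
#'   condition order.
#' @return A `paradigm_config` list; `trial_cycle_s` and `session_duration_s`
#'   are derived fields.
#' @export
#' @examples
#' cfg <- paradigm_config()
#' cfg$session_duration_s  # 720
paradigm_config <- function(n_sessions = 2L,
                            n_trials_per_condition_per_session = 5L,
                            stim_duration_s = 15,
                            q1_duration_s = 3,
                            q2_duration_s = 6,
                            rest_duration_s = 9,
                            tr_s = 3,
                            conditions = c("Aristotle", "Reverse", "Asynchronous"),
                            seed = 1L) {
  if (n_sessions < 1L || n_trials_per_condition_per_session < 0L)
    stop("paradigm_config: counts must be non-negative (n_sessions >= 1)")
  durs <- c(stim_duration_s, q1_duration_s, q2_duration_s, rest_duration_s, tr_s)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("paradigm_config: all durations must be positive and finite")
  if (length(conditions) < 1L || anyDuplicated(conditions))
    stop("paradigm_config: conditions must be distinct names")
  cycle <- 2 * stim_duration_s + q1_duration_s + q2_duration_s + rest_duration_s
  n_trials <- length(conditions) * n_trials_per_condition_per_session
  cfg <- list(
    n_sessions = as.integer(n_sessions),
    n_trials_per_condition_per_session = as.integer(n_trials_per_condition_per_session),
    stim_duration_s = stim_duration_s,
    q1_duration_s = q1_duration_s,
    q2_duration_s = q2_duration_s,
    rest_duration_s = rest_duration_s,
    tr_s = tr_s,
    conditions = conditions,
    seed = as.integer(seed),
    trial_cycle_s = cycle,
    n_trials_per_session = n_trials,
    session_duration_s = n_trials * cycle
  )
  class(cfg) <- "paradigm_config"
  cfg
}

#' Generate the randomized trial timeline for a cohort
#'
#' Lays out, for every subject and session, a fully randomized sequence of
#' trials balanced across conditions, with the onsets of both stimulation
#' epochs of each trial. Response columns are left empty (`NA`) for
#' [simulate_behavior()] to fill.
#'
#' @param config A [paradigm_config()].
#' @param n_subjects Number of participants.
#' @return An event table: one row per trial with columns `subject`,
#'   `session`, `trial`, `condition`, `epoch1_onset_s`, `epoch2_onset_s`,
#'   `epoch_duration_s`, `q1_response`, `q2_response`.
#' @export
#' @examples
#' ev <- generate_paradigm(paradigm_config(), n_subjects = 2)
#' nrow(ev)  # 2 subjects x 2 sessions x 15 trials = 60
generate_paradigm <- function(config, n_subjects = 1L) {
  stopifnot(inherits(config, "paradigm_config"))
  if (n_subjects < 1L) stop("generate_paradigm: n_subjects must be >= 1")
  ntc <- config$n_trials_per_condition_per_session
  nt <- config$n_trials_per_session
  empty <- data.frame(
    subject = integer(), session = integer(), trial = integer(),
    condition = character(),
    epoch1_onset_s = numeric(), epoch2_onset_s = numeric(),
    epoch_duration_s = numeric(),
    q1_response = integer(), q2_response = integer(),
    stringsAsFactors = FALSE
  )
  if (ntc == 0L) {
    attr(empty, "paradigm_config") <- config
    class(empty) <- c("event_table", "data.frame")
    return(empty)
  }
  rows <- vector("list", n_subjects * config$n_sessions)
  i <- 0L
  withr_seed <- config$seed
  set.seed(withr_seed)
  for (s in seq_len(n_subjects)) {
    for (ses in seq_len(config$n_sessions)) {
      conds <- sample(rep(config$conditions, each = ntc))
      onset1 <- (seq_len(nt) - 1) * config$trial_cycle_s
      onset2 <- onset1 + config$stim_duration_s + config$q1_duration_s
      i <- i + 1L
      rows[[i]] <- data.frame(
        subject = s, session = ses, trial = seq_len(nt),
        condition = conds,
        epoch1_onset_s = onset1, epoch2_onset_s = onset2,
        epoch_duration_s = config$stim_duration_s,
        q1_response = NA_integer_, q2_response = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  attr(ev, "paradigm_config") <- config
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Behavioral response model
#'
#' Per-condition probabilities of the illusory percept, of failing to
#' respond, and a categorical distribution over the four-button perceived
#' distance scale. Q1 is coded 1 = "one stimulus felt", 2 = "two stimuli
#' felt"; the illusory percept is Q1 = 2 under Aristotle stimulation and
#' Q1 = 1 under Reverse or Asynchronous stimulation. Default illusion
#' probabilities are the cohort response ratios observed in the source
#' behavioral data (544/596, 212/594, 48/590); default non-response rates
#' are the corresponding observed per-trial rates. Default Q2 distributions
#' order mean perceived distance Aristotle > Asynchronous > Reverse; the
#' individual category weights are free generator parameters.
#'
#' @param p_illusion Named per-condition probability of the illusory Q1
#'   response.
#' @param p_nonresponse Named per-condition probability that a trial has no
#'   response (both questions missed).
#' @param q2_probs Named list of length-4 probability vectors over the
#'   distance buttons 1..4.
#' @param seed Integer seed for [simulate_behavior()].
#' @return A `behavior_model` list.
#' @export
behavior_model <- function(p_illusion = c(Aristotle = 544 / 596,
                                          Reverse = 212 / 594,
                                          Asynchronous = 48 / 590),
                           p_nonresponse = c(Aristotle = 2 / 300,
                                             Reverse = 3 / 300,
                                             Asynchronous = 5 / 300),
                           q2_probs = list(
                             Aristotle = c(0.05, 0.15, 0.35, 0.45),
                             Reverse = c(0.45, 0.35, 0.15, 0.05),
                             Asynchronous = c(0.10, 0.30, 0.40, 0.20)
                           ),
                           seed = 1L) {
  if (any(p_illusion < 0 | p_illusion > 1))
    stop("behavior_model: p_illusion must lie in [0, 1]")
  if (any(p_nonresponse < 0 | p_nonresponse > 1))
    stop("behavior_model: p_nonresponse must lie in [0, 1]")
  for (q in q2_probs) {
    if (length(q) != 4L || any(q < 0) || abs(sum(q) - 1) > 1e-8)
      stop("behavior_model: each q2 distribution must be 4 probabilities summing to 1")
  }
  structure(list(p_illusion = p_illusion, p_nonresponse = p_nonresponse,
                 q2_probs = q2_probs, seed = as.integer(seed)),
            class = "behavior_model")
}

# Illusion indicator for a (condition, Q1) pair: under Aristotle stimulation
# the illusion is feeling two; under Reverse/Asynchronous it is feeling one.
illusory_q1 <- function(condition) {
  ifelse(condition == "Aristotle", 2L, 1L)
}

#' Simulate button responses for an event table
#'
#' Draws, per trial, a non-response indicator, a Q1 percept report from the
#' condition's illusion probability, and a Q2 distance report from the
#' condition's categorical distribution. Both stimulation epochs of a trial
#' share the trial's Q1 label downstream.
#'
#' @param events An event table from [generate_paradigm()] with empty
#'   response columns.
#' @param model A [behavior_model()].
#' @return The event table with `q1_response` and `q2_response` filled
#'   (`NA` for non-response trials).
#' @export
simulate_behavior <- function(events, model) {
  stopifnot(inherits(events, "event_table"), inherits(model, "behavior_model"))
  if (nrow(events) == 0L) return(events)
  unknown <- setdiff(unique(events$condition), names(model$p_illusion))
  if (length(unknown))
    stop("simulate_behavior: unknown condition(s): ", paste(unknown, collapse = ", "))
  set.seed(model$seed)
  n <- nrow(events)
  p_nr <- model$p_nonresponse[events$condition]
  responded <- stats::runif(n) >= p_nr
  p_ill <- model$p_illusion[events$condition]
  ill <- stats::runif(n) < p_ill
  q1_ill <- illusory_q1(events$condition)
  q1 <- ifelse(ill, q1_ill, 3L - q1_ill)
  q2 <- integer(n)
  for (cond in names(model$q2_probs)) {
    sel <- events$condition == cond
    if (any(sel))
      q2[sel] <- sample(1:4, sum(sel), replace = TRUE, prob = model$q2_probs[[cond]])
  }
  events$q1_response <- ifelse(responded, as.integer(q1), NA_integer_)
  events$q2_response <- ifelse(responded, as.integer(q2), NA_integer_)
  events
}

#' Summarize illusion rates and perceived distance
#'
#' The illusion rate of a condition is the proportion of illusion trials
#' among trials with a response; non-response trials are excluded from every
#' denominator. Mean perceived distance averages the Q2 button (1..4) over
#' responded trials.
#'
#' @param events An event table with responses filled.
#' @return A `behavior_summary` list with `by_condition` and `by_subject`
#'   data frames.
#' @export
summarize_behavior <- function(events) {
  stopifnot(inherits(events, "event_table"))
  conds <- unique(events$condition)
  summ_one <- function(df) {
    resp <- df[!is.na(df$q1_response), , drop = FALSE]
    if (nrow(resp) == 0L)
      stop("summarize_behavior: illusion rate undefined (no responded trials) for condition ",
           df$condition[1])
    ill <- resp$q1_response == illusory_q1(resp$condition)
    data.frame(
      condition = df$condition[1],
      n_trials = nrow(df),
      n_responded = nrow(resp),
      illusion_rate = mean(ill),
      mean_perceived_distance = mean(resp$q2_response, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }
  by_cond <- do.call(rbind, lapply(conds, function(cc)
    summ_one(events[events$condition == cc, , drop = FALSE])))
  subj_rows <- list()
  for (s in unique(events$subject)) {
    for (cc in conds) {
      df <- events[events$subject == s & events$condition == cc, , drop = FALSE]
      resp <- df[!is.na(df$q1_response), , drop = FALSE]
      subj_rows[[length(subj_rows) + 1L]] <- data.frame(
        subject = s, condition = cc,
        n_responded = nrow(resp),
        illusion_rate = if (nrow(resp)) mean(resp$q1_response == illusory_q1(resp$condition)) else NA_real_,
        mean_perceived_distance = if (nrow(resp)) mean(resp$q2_response, na.rm = TRUE) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- list(by_condition = by_cond, by_subject = do.call(rbind, subj_rows))
  class(out) <- "behavior_summary"
  out
}

#' Overwrite Q1 responses to match fixed per-condition trial counts
#'
#' Deterministically assigns Q1 = 1 / Q1 = 2 / non-response to the trials of
#' each condition so that the cohort reproduces a printed table of response
#' counts exactly (e.g. when replaying a published behavioral table through
#' the labeling pipeline).
#'
#' @param events An event table.
#' @param counts Named list: for each condition a vector
#'   `c(one = , two = , none = )` of trial counts summing to that
#'   condition's trial total.
#' @return The event table with `q1_response` set accordingly.
#' @export
fill_q1_from_counts <- function(events, counts) {
  stopifnot(inherits(events, "event_table"))
  for (cond in names(counts)) {
    idx <- which(events$condition == cond)
    ct <- counts[[cond]]
    if (sum(ct) != length(idx))
      stop("fill_q1_from_counts: counts for ", cond, " sum to ", sum(ct),
           " but there are ", length(idx), " trials")
    q1 <- rep(c(1L, 2L, NA_integer_), times = c(ct[["one"]], ct[["two"]], ct[["none"]]))
    events$q1_response[idx] <- q1
  }
  events
}

#' Write an event table as a BIDS-style events TSV
#'
#' Emits one row per stimulation epoch (two per trial) with columns `onset`,
#' `duration`, `trial_type`, `subject`, `session`, `trial`, `epoch`,
#' `q1_response`, `q2_response`. Missing responses are written as `n/a`.
#'
#' @param events An event table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  long <- rbind(
    data.frame(onset = events$epoch1_onset_s, duration = events$epoch_duration_s,
               trial_type = events$condition, subject = events$subject,
               session = events$session, trial = events$trial, epoch = 1L,
               q1_response = events$q1_response, q2_response = events$q2_response),
    data.frame(onset = events$epoch2_onset_s, duration = events$epoch_duration_s,
               trial_type = events$condition, subject = events$subject,
               session = events$session, trial = events$trial, epoch = 2L,
               q1_response = events$q1_response, q2_response = events$q2_response)
  )
  long <- long[order(long$subject, long$session, long$trial, long$epoch), ]
  long$q1_response <- ifelse(is.na(long$q1_response), "n/a", long$q1_response)
  long$q2_response <- ifelse(is.na(long$q2_response), "n/a", long$q2_response)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events TSV written by [write_events_tsv()]
#'
#' @param path File path.
#' @param config Optional [paradigm_config()] to attach.
#' @return An event table (one row per trial).
#' @export
read_events_tsv <- function(path, config = NULL) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            na.strings = "n/a", stringsAsFactors = FALSE)
  e1 <- long[long$epoch == 1L, ]
  e2 <- long[long$epoch == 2L, ]
  key <- function(d) paste(d$subject, d$session, d$trial)
  e2 <- e2[match(key(e1), key(e2)), ]
  ev <- data.frame(
    subject = e1$subject, session = e1$session, trial = e1$trial,
    condition = e1$trial_type,
    epoch1_onset_s = e1$onset, epoch2_onset_s = e2$onset,
    epoch_duration_s = e1$duration,
    q1_response = as.integer(e1$q1_response),
    q2_response = as.integer(e1$q2_response),
    stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$subject, ev$session, ev$trial), ]
  rownames(ev) <- NULL
  if (!is.null(config)) attr(ev, "paradigm_config") <- config
  class(ev) <- c("event_table", "data.frame")
  ev
}
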