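#' Generate a synthetic parcellation atlas
#'
#' Partitions an ellipsoidal "brain" mask inscribed in the voxel grid into
#' `n_rois` compact regions by seeded Voronoi growth: `n_rois` seed voxels
#' are drawn uniformly from the mask and every mask voxel joins its nearest
#' seed. Voxels outside the mask are background (label 0). The result is a
#' synthetic stand-in for an anatomical parcellation such as AAL; any
#' user-supplied integer-labeled NIfTI can be used instead via
#' [read_atlas_nifti()].
#'
#' @param grid_shape Integer vector of three voxel extents.
#' @param n_rois Number of regions.
#' @param seed Integer seed.
#' @return A `parcellation`: list with `labels` (3D integer array),
#'   `roi_names` (named character vector `roi_1` ...), `affine` (4x4),
#'   `n_rois`.
#' @export
#' @examples
#' atlas <- generate_atlas(c(16, 16, 16), n_rois = 8, seed = 1)
#' table(atlas$labels)["0"]  # background voxels
generate_atlas <- function(grid_shape = c(32L, 32L, 32L), n_rois = 40L, seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L), n_rois >= 1L)
  d <- as.integer(grid_shape)
  ctr <- (d + 1) / 2
  semi <- 0.45 * d
  gx <- (seq_len(d[1]) - ctr[1]) / semi[1]
  gy <- (seq_len(d[2]) - ctr[2]) / semi[2]
  gz <- (seq_len(d[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
  mask <- r2 <= 1
  vox <- which(mask)
  if (length(vox) < 8L * n_rois)
    stop("generate_atlas: mask holds ", length(vox),
         " voxels; need at least 8 per ROI for ", n_rois, " ROIs")
  set.seed(seed)
  seeds <- sample(vox, n_rois)
  coord <- function(v) {
    v0 <- v - 1L
    x <- v0 %% d[1]
    y <- (v0 %/% d[1]) %% d[2]
    z <- v0 %/% (d[1] * d[2])
    cbind(x, y, z)
  }
  vc <- coord(vox)
  sc <- coord(seeds)
  # nearest seed per mask voxel; ties broken by lowest seed index
  best_lab <- integer(length(vox))
  best_d2 <- rep(Inf, length(vox))
  for (k in seq_len(n_rois)) {
    d2 <- (vc[, 1] - sc[k, 1])^2 + (vc[, 2] - sc[k, 2])^2 + (vc[, 3] - sc[k, 3])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_lab[upd] <- k
  }
  labels <- array(0L, dim = d)
  labels[vox] <- best_lab
  structure(list(
    labels = labels,
    roi_names = stats::setNames(paste0("roi_", seq_len(n_rois)), seq_len(n_rois)),
    affine = diag(4),
    n_rois = as.integer(n_rois)
  ), class = "parcellation")
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-convention shape: response gamma peaking near 6 s minus an undershoot
#' gamma peaking near 16 s at 1/6 amplitude. The returned kernel is sampled
#' at `dt` and normalized so that a sustained boxcar convolved with it
#' plateaus at 1 (i.e. the kernel sums to `1/dt`), making effect amplitudes
#' directly interpretable as steady-state signal change.
#'
#' @param dt Sampling interval in seconds (typically the TR).
#' @param duration_s Kernel length in seconds.
#' @param peak_delay,undershoot_delay Gamma shape parameters (seconds).
#' @param ratio Undershoot amplitude relative to the peak.
#' @return Numeric kernel vector.
#' @export
hrf_double_gamma <- function(dt = 3, duration_s = 32, peak_delay = 6,
                             undershoot_delay = 16, ratio = 1 / 6) {
  t <- seq(0, duration_s, by = dt)
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
  h / (sum(h) * dt)
}

#' Declare ROI-confined activation effects
#'
#' Each row ties an activation class to an atlas ROI and a BOLD amplitude
#' (steady-state fractional signal change in the same arbitrary units as the
#' baseline). Classes are either condition names (`"Aristotle"`,
#' `"Reverse"`, `"Asynchronous"`), keyed on the stimulus applied, or the
#' percept classes `"percept_one"` / `"percept_two"`, keyed on the trial's
#' simulated Q1 report.
#'
#' @param ... Named arguments, one per class, each a named numeric vector of
#'   amplitudes keyed by ROI label, e.g.
#'   `effect_spec(percept_two = c("3" = 2, "7" = 2))`.
#' @return An `effect_spec` data frame with columns `class`, `roi`,
#'   `amplitude`.
#' @export
effect_spec <- function(...) {
  args <- list(...)
  if (length(args) && is.null(names(args)))
    stop("effect_spec: arguments must be named by activation class")
  rows <- lapply(names(args), function(cl) {
    amp <- args[[cl]]
    if (is.null(names(amp))) stop("effect_spec: amplitudes must be named by ROI label")
    data.frame(class = cl, roi = as.integer(names(amp)),
               amplitude = as.numeric(amp), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(), roi = integer(), amplitude = numeric())
  if (any(!is.finite(out$amplitude))) stop("effect_spec: amplitudes must be finite")
  class(out) <- c("effect_spec", "data.frame")
  out
}

#' Noise model for synthetic BOLD
#'
#' @param white_sd Standard deviation of the white innovation.
#' @param ar1 Temporal AR(1) coefficient in `[0, 1)`.
#' @param subject_amp_jitter_sd SD of a per-subject multiplicative jitter
#'   `(1 + e)` applied to all effect amplitudes.
#' @param baseline Constant baseline signal level.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(white_sd = 1.0, ar1 = 0.3,
                       subject_amp_jitter_sd = 0.1, baseline = 100) {
  stopifnot(white_sd >= 0, ar1 >= 0, ar1 < 1, subject_amp_jitter_sd >= 0)
  structure(list(white_sd = white_sd, ar1 = ar1,
                 subject_amp_jitter_sd = subject_amp_jitter_sd,
                 baseline = baseline), class = "noise_spec")
}

# Boxcar indicator of the given epochs sampled at the TR grid of a session.
epoch_boxcar <- function(onsets, duration, tr, n_vols) {
  t_grid <- (seq_len(n_vols) - 1) * tr
  u <- numeric(n_vols)
  for (on in onsets) u[t_grid >= on & t_grid < on + duration] <- 1
  u
}

# Discrete causal convolution of regressor u with kernel h (truncated to
# length(u)), scaled by dt so amplitudes keep their steady-state meaning.
convolve_hrf <- function(u, h, dt) {
  n <- length(u)
  full <- stats::convolve(c(u, numeric(length(h))), rev(h), type = "open")
  full[seq_len(n)] * dt
}

#' Simulate one session's 4D BOLD volume
#'
#' Voxel time series are
#' `baseline + sum_class amplitude * (epoch boxcar x HRF)` restricted to the
#' class's ROIs, plus AR(1)-filtered Gaussian noise. Condition classes use
#' the epochs of trials with that stimulus; percept classes use the epochs
#' of responded trials whose simulated Q1 report matches (`percept_one`:
#' Q1 = 1, `percept_two`: Q1 = 2).
#'
#' @param events Event table rows (any subset; filtered to
#'   `subject`/`session`).
#' @param subject,session Identifiers selecting the session to simulate.
#' @param atlas A `parcellation`.
#' @param effects An [effect_spec()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed (noise and jitter).
#' @param hrf HRF kernel sampled at the TR; defaults to
#'   [hrf_double_gamma()].
#' @return A `volume4d`: list with `data` (4D array x,y,z,t), `tr_s`,
#'   `subject`, `session`, `affine`.
#' @export
simulate_session <- function(events, subject, session, atlas, effects,
                             noise = noise_spec(), seed = 1L, hrf = NULL) {
  stopifnot(inherits(atlas, "parcellation"), inherits(effects, "effect_spec"),
            inherits(noise, "noise_spec"))
  cfg <- attr(events, "paradigm_config")
  if (is.null(cfg)) stop("simulate_session: events lack a paradigm_config attribute")
  ev <- events[events$subject == subject & events$session == session, , drop = FALSE]
  if (nrow(ev) == 0L) stop("simulate_session: no events for subject ", subject,
                           " session ", session)
  tr <- cfg$tr_s
  n_vols <- as.integer(round(cfg$session_duration_s / tr))
  d <- dim(atlas$labels)
  V <- prod(d)
  if (is.null(hrf)) hrf <- hrf_double_gamma(dt = tr)
  bad <- setdiff(unique(effects$roi), seq_len(atlas$n_rois))
  if (length(bad))
    stop("simulate_session: effect references ROI(s) absent from atlas: ",
         paste(bad, collapse = ", "))
  if (max(ev$epoch2_onset_s + ev$epoch_duration_s) > cfg$session_duration_s + 1e-9)
    stop("simulate_session: event timing exceeds the scan length")

  # per-subject amplitude jitter, derived from seed + subject only so the
  # same subject keeps its gain across sessions
  set.seed(derive_seed(seed, paste0("jitter_subject_", subject)))
  gain <- 1 + stats::rnorm(1L, 0, noise$subject_amp_jitter_sd)

  sig <- matrix(0, nrow = V, ncol = n_vols)
  for (cl in unique(effects$class)) {
    sel <- switch(cl,
      percept_one = !is.na(ev$q1_response) & ev$q1_response == 1L,
      percept_two = !is.na(ev$q1_response) & ev$q1_response == 2L,
      ev$condition == cl)
    if (!any(sel)) next
    onsets <- c(ev$epoch1_onset_s[sel], ev$epoch2_onset_s[sel])
    u <- epoch_boxcar(onsets, ev$epoch_duration_s[1], tr, n_vols)
    reg <- convolve_hrf(u, hrf, tr)
    for (i in which(effects$class == cl)) {
      vox <- which(atlas$labels == effects$roi[i])
      amp <- effects$amplitude[i] * gain
      sig[vox, ] <- sig[vox, ] + amp * rep(reg, each = length(vox))
    }
  }
  set.seed(derive_seed(seed, paste0("noise_s", subject, "_ses", session)))
  if (noise$white_sd > 0) {
    eps <- matrix(stats::rnorm(V * n_vols, 0, noise$white_sd), nrow = n_vols)
    if (noise$ar1 > 0) {
      eps <- stats::filter(eps, noise$ar1, method = "recursive")
      eps <- matrix(as.numeric(eps), nrow = n_vols)
    }
    sig <- sig + t(eps)
  }
  vol <- array(noise$baseline + sig, dim = c(d, n_vols))
  structure(list(data = vol, tr_s = tr, subject = subject, session = session,
                 affine = atlas$affine),
            class = "volume4d")
}

#' Simulate BOLD volumes for every subject/session in an event table
#'
#' Convenience wrapper over [simulate_session()]; intended for small,
#' desk-scale configurations (the full 4D arrays for every session are held
#' in memory). Pipelines stream sessions one at a time instead via
#' [build_samples()].
#'
#' @inheritParams simulate_session
#' @return Named list of `volume4d` objects, names `s<subject>_ses<session>`.
#' @export
simulate_bold <- function(events, atlas, effects, noise = noise_spec(),
                          seed = 1L, hrf = NULL) {
  keys <- unique(events[, c("subject", "session")])
  out <- vector("list", nrow(keys))
  names(out) <- paste0("s", keys$subject, "_ses", keys$session)
  for (i in seq_len(nrow(keys))) {
    out[[i]] <- simulate_session(events, keys$subject[i], keys$session[i],
                                 atlas, effects, noise, seed, hrf)
  }
  out
}

#' Write / read a parcellation as NIfTI with a ROI-name sidecar TSV
#'
#' @param atlas A `parcellation`.
#' @param path Output path (`.nii` or `.nii.gz`); the sidecar is written
#'   next to it with extension `.tsv`.
#' @return `path`, invisibly.
#' @export
write_atlas_nifti <- function(atlas, path) {
  img <- RNifti::asNifti(atlas$labels)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".tsv", path)
  utils::write.table(
    data.frame(label = seq_len(atlas$n_rois), name = unname(atlas$roi_names)),
    side, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas_nifti
#' @export
read_atlas_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(round(as.array(img))), dim = dim(img))
  labs <- sort(setdiff(unique(as.vector(labels)), 0L))
  side <- sub("\\.nii(\\.gz)?$", ".tsv", path)
  nm <- if (file.exists(side)) {
    tab <- utils::read.table(side, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    stats::setNames(tab$name, tab$label)
  } else stats::setNames(paste0("roi_", labs), labs)
  structure(list(labels = labels, roi_names = nm,
                 affine = RNifti::xform(img), n_rois = length(labs)),
            class = "parcellation")
}

#' Write a 4D volume (or 3D map) as NIfTI
#'
#' @param x A `volume4d`, or a plain 3D/4D array.
#' @param path Output path.
#' @param tr_s Optional repetition time stored in the header.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path, tr_s = NULL) {
  arr <- if (inherits(x, "volume4d")) x$data else x
  if (inherits(x, "volume4d") && is.null(tr_s)) tr_s <- x$tr_s
  img <- RNifti::asNifti(arr)
  if (!is.null(tr_s)) RNifti::pixdim(img)[4] <- tr_s
  RNifti::writeNifti(img, path)
  invisible(path)
}
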