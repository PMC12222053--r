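#' Per-ROI mean of a 3D map
#'
#' Averages the map over the voxels of each atlas label (> 0); background
#' voxels are excluded.
#'
#' @param map 3D numeric array on the atlas grid.
#' @param atlas A `parcellation`.
#' @return Named numeric vector of ROI means (names = ROI labels).
#' @export
roi_means <- function(map, atlas) {
  stopifnot(inherits(atlas, "parcellation"))
  if (!identical(dim(map), dim(atlas$labels)))
    stop("roi_means: map grid ", paste(dim(map), collapse = "x"),
         " does not match atlas grid ", paste(dim(atlas$labels), collapse = "x"))
  lab <- as.vector(atlas$labels)
  keep <- lab > 0L
  sums <- rowsum(as.vector(map)[keep], lab[keep])
  cnts <- rowsum(rep(1, sum(keep)), lab[keep])
  out <- numeric(atlas$n_rois)
  names(out) <- as.character(seq_len(atlas$n_rois))
  out[rownames(sums)] <- sums / cnts
  out
}

#' Subjects-by-ROI saliency matrix
#'
#' Applies [roi_means()] to each subject's mean saliency map.
#'
#' @param subject_maps 4D array (x, y, z, subject).
#' @param atlas A `parcellation`.
#' @param subjects Optional subject ids for row names.
#' @return Matrix (subjects x ROIs) of mean saliency values.
#' @export
subject_roi_matrix <- function(subject_maps, atlas, subjects = NULL) {
  n <- dim(subject_maps)[4]
  m <- t(vapply(seq_len(n),
                function(i) roi_means(subject_maps[, , , i, drop = TRUE], atlas),
                numeric(atlas$n_rois)))
  rownames(m) <- as.character(subjects %||% seq_len(n))
  m
}

#' Grand mean saliency
#'
#' The arithmetic mean over every (subject, ROI) entry of the matrix — the
#' single reference value against which each ROI's subject means are
#' tested.
#'
#' @param matrix Subjects-by-ROIs matrix.
#' @return Scalar grand mean.
#' @export
grand_mean <- function(matrix) {
  if (length(matrix) == 0L) stop("grand_mean: empty matrix")
  mean(matrix)
}

#' Wilcoxon signed-rank tests of ROI saliency against the grand mean
#'
#' For each ROI, performs a one-sample Wilcoxon signed-rank test of the
#' subjects' ROI means against the fixed grand mean (zero differences are
#' discarded by the classical convention; an ROI whose differences are all
#' zero is reported with p = 1 and flagged untestable). The exact null
#' distribution is used for up to 25 nonzero differences without ties,
#' otherwise the normal approximation. P-values are adjusted across ROIs
#' with the Benjamini-Hochberg step-up procedure and ROIs with `q < alpha`
#' are flagged significant.
#'
#' @param matrix Subjects-by-ROIs saliency matrix.
#' @param grand Scalar reference; defaults to [grand_mean()] of `matrix`.
#' @param alpha FDR threshold.
#' @param alternative `"two.sided"` (default), `"greater"` (ROIs elevated
#'   above the grand mean), or `"less"`.
#' @return An `roi_stats_table` data frame: `roi`, `name`, `mean_saliency`,
#'   `statistic`, `p`, `q`, `significant`, `n_zero_dropped`, `testable`;
#'   the grand mean is stored in `attr(, "grand_mean")`.
#' @export
test_rois <- function(matrix, grand = NULL, alpha = 0.05,
                      alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (nrow(matrix) < 2L)
    stop("test_rois: need at least 2 subjects")
  grand <- grand %||% grand_mean(matrix)
  K <- ncol(matrix)
  labs <- colnames(matrix) %||% as.character(seq_len(K))
  p <- numeric(K); stat <- numeric(K); nz <- integer(K); testable <- logical(K)
  for (j in seq_len(K)) {
    d <- matrix[, j] - grand
    zeros <- sum(d == 0)
    d <- d[d != 0]
    nz[j] <- zeros
    if (length(d) == 0L) {
      p[j] <- 1; stat[j] <- NA_real_; testable[j] <- FALSE
      next
    }
    testable[j] <- TRUE
    exact <- length(d) <= 25L && !anyDuplicated(abs(d))
    wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = exact,
                                              correct = !exact,
                                              alternative = alternative))
    p[j] <- wt$p.value
    stat[j] <- unname(wt$statistic)
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(roi = seq_len(K), name = labs,
                    mean_saliency = colMeans(matrix),
                    statistic = stat, p = p, q = q,
                    significant = q < alpha & testable,
                    n_zero_dropped = nz, testable = testable,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "grand_mean") <- grand
  attr(out, "alternative") <- alternative
  attr(out, "alpha") <- alpha
  class(out) <- c("roi_stats_table", "data.frame")
  out
}

#' Subject-wise saliency summaries for significant ROIs
#'
#' For every significant ROI, collects the per-subject saliency values with
#' their mean and standard error (`SD / sqrt(n)`, `NA` for a single
#' subject), plus each subject's whole-matrix mean saliency — the
#' narrow-distribution baseline the per-ROI values are compared against.
#'
#' @param matrix Subjects-by-ROIs saliency matrix.
#' @param stats_table An `roi_stats_table` from [test_rois()] (or an
#'   integer vector of significant ROI indices).
#' @return A `subject_saliency_summary` list: `per_roi` (data frame with
#'   `roi`, `name`, `mean`, `se`, `n`), `values` (subjects x significant
#'   ROIs matrix), `subject_means`, `grand_mean`. Empty (with a message
#'   attribute) when no ROI is significant.
#' @export
subject_saliency_summary <- function(matrix, stats_table) {
  if (inherits(stats_table, "roi_stats_table")) {
    sig <- which(stats_table$significant)
    nms <- stats_table$name[sig]
    gm <- attr(stats_table, "grand_mean")
  } else {
    sig <- as.integer(stats_table)
    nms <- colnames(matrix)[sig] %||% as.character(sig)
    gm <- grand_mean(matrix)
  }
  subject_means <- rowMeans(matrix)
  if (length(sig) == 0L) {
    out <- list(per_roi = data.frame(), values = NULL,
                subject_means = subject_means, grand_mean = gm)
    attr(out, "message") <- "no significant ROIs"
    class(out) <- "subject_saliency_summary"
    return(out)
  }
  vals <- matrix[, sig, drop = FALSE]
  colnames(vals) <- nms
  n <- nrow(vals)
  per_roi <- data.frame(
    roi = sig, name = nms,
    mean = colMeans(vals),
    se = if (n > 1) apply(vals, 2, stats::sd) / sqrt(n) else NA_real_,
    n = n, stringsAsFactors = FALSE)
  rownames(per_roi) <- NULL
  out <- list(per_roi = per_roi, values = vals,
              subject_means = subject_means, grand_mean = gm)
  class(out) <- "subject_saliency_summary"
  out
}

#' Scatter plot of subject-wise saliency per significant ROI
#'
#' One column of gray subject dots per significant ROI with the group mean
#' (red) and standard-error bars overlaid, and a dashed horizontal line at
#' the grand mean.
#'
#' @param summary A [subject_saliency_summary()].
#' @param path Output PNG path.
#' @param main Title.
#' @return `path`, invisibly.
#' @export
write_subject_saliency_png <- function(summary, path, main = "subject saliency") {
  if (is.null(summary$values)) {
    grDevices::png(path, width = 480, height = 320)
    graphics::plot.new(); graphics::title(main = paste(main, "(no significant ROIs)"))
    grDevices::dev.off()
    return(invisible(path))
  }
  vals <- summary$values
  k <- ncol(vals)
  grDevices::png(path, width = max(480, 120 * k), height = 420)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(NULL, xlim = c(0.5, k + 0.5),
                 ylim = range(c(vals, summary$grand_mean)),
                 xaxt = "n", xlab = "", ylab = "mean saliency", main = main)
  graphics::axis(1, at = seq_len(k), labels = colnames(vals), las = 2,
                 cex.axis = 0.8)
  for (j in seq_len(k)) {
    graphics::points(jitter(rep(j, nrow(vals)), amount = 0.08), vals[, j],
                     col = "gray50", pch = 16, cex = 0.7)
    m <- summary$per_roi$mean[j]; se <- summary$per_roi$se[j]
    graphics::points(j, m, col = "red", pch = 1, cex = 1.4, lwd = 2)
    if (is.finite(se))
      graphics::arrows(j, m - se, j, m + se, angle = 90, code = 3,
                       length = 0.05)
  }
  graphics::abline(h = summary$grand_mean, lty = 2)
  invisible(path)
}
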