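#' Grad-CAM saliency for SFCN classifiers
#'
#' Computes, for each sample, the gradient-weighted class activation map
#' `L = ReLU(sum_k alpha_k A_k)`, where `A_k` are the feature maps of the
#' last convolutional layer (post-ReLU) and each channel weight
#' `alpha_k` is the spatial global mean of the gradient of the target class
#' score (pre-softmax) with respect to `A_k`. Maps are nonnegative by
#' construction and are returned both at feature resolution and trilinearly
#' upsampled to the input grid.
#'
#' @param model A trained `sfcn_model`.
#' @param samples Array `(x, y, z, n)` or a `sample_set`.
#' @param target `"label"` (default) uses the provided true labels,
#'   `"predicted"` the argmax class; alternatively an integer vector of
#'   0-based class indices.
#' @param labels Integer labels, required when `target = "label"` and
#'   `samples` is a bare array.
#' @param layer Layer whose activations are used; defaults to the model's
#'   last convolutional feature layer.
#' @return A `gradcam_result`: list with `maps` (array x,y,z,n at input
#'   resolution), `feature_maps` (array at feature resolution), `alpha`
#'   (n x channels), `target_class`.
#' @export
gradcam <- function(model, samples, target = "label", labels = NULL,
                    layer = NULL) {
  stopifnot(inherits(model, "sfcn_model"))
  x <- if (inherits(samples, "sample_set")) samples$x else samples
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (is.null(labels) && inherits(samples, "sample_set")) labels <- samples$y
  layer <- layer %||% model$gradcam_layer
  if (!layer %in% names(model$layers))
    stop("gradcam: unknown layer '", layer, "'; available: ",
         paste(names(model$layers), collapse = ", "))
  N <- dim(x)[4]
  fwd <- sfcn_forward(model, x, train = FALSE, keep_caches = TRUE)
  n_classes <- ncol(fwd$scores)
  cls <- if (is.numeric(target)) {
    as.integer(rep_len(target, N))
  } else if (identical(target, "predicted")) {
    max.col(fwd$scores, ties.method = "first") - 1L
  } else {
    if (is.null(labels)) stop("gradcam: target = 'label' needs labels")
    as.integer(labels)
  }
  dscores <- matrix(0, nrow = N, ncol = n_classes)
  dscores[cbind(seq_len(N), cls + 1L)] <- 1
  bwd <- sfcn_backward(model, fwd$caches, dscores, capture = layer)
  A <- fwd$caches[[layer]]$out            # V x C x N cube
  dA <- bwd$captured
  d_feat <- model$dims[[sub("relu$", "conv", layer)]] %||% model$dims[["gap"]]
  V <- dim(A)[1]; C <- dim(A)[2]
  alpha <- t(colMeans(dA))                # N x C (spatial global mean)
  Lfeat <- array(0, dim = c(d_feat, N))
  d_in <- model$config$input_shape
  maps <- array(0, dim = c(d_in, N))
  for (n in seq_len(N)) {
    L <- pmax(matrix(A[, , n], ncol = C) %*% alpha[n, ], 0)
    Lfeat[, , , n] <- array(L, dim = d_feat)
    maps[, , , n] <- upsample_trilinear(array(L, dim = d_feat), d_in)
  }
  structure(list(maps = maps, feature_maps = Lfeat, alpha = alpha,
                 target_class = cls, layer = layer),
            class = "gradcam_result")
}

#' Trilinear upsampling of a 3D map
#'
#' Interpolates with corner-aligned coordinates (output corners map to
#' input corners), so upsampling to the same shape is the identity, a
#' constant map stays constant, and nonnegativity is preserved.
#'
#' @param map 3D numeric array.
#' @param target_shape Integer vector of three output extents, each at
#'   least the corresponding input extent.
#' @return The interpolated 3D array.
#' @export
upsample_trilinear <- function(map, target_shape) {
  d_in <- dim(map)
  stopifnot(length(d_in) == 3L, length(target_shape) == 3L)
  if (any(target_shape < 1L) || any(target_shape < d_in))
    stop("upsample_trilinear: target shape must be >= map shape in every axis")
  if (all(target_shape == d_in)) return(map)
  pos <- lapply(1:3, function(a) {
    if (target_shape[a] == 1L) rep(1, 1)
    else if (d_in[a] == 1L) rep(1, target_shape[a])
    else (seq_len(target_shape[a]) - 1) * (d_in[a] - 1) / (target_shape[a] - 1) + 1
  })
  lo <- lapply(1:3, function(a) pmin(as.integer(floor(pos[[a]])), d_in[a] - (d_in[a] > 1)))
  fr <- lapply(1:3, function(a) pos[[a]] - lo[[a]])
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, d_in[a]))
  out <- array(0, dim = target_shape)
  # gather eight corners with outer-product weights, vectorized per axis
  wx0 <- 1 - fr[[1]]; wy0 <- 1 - fr[[2]]; wz0 <- 1 - fr[[3]]
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    ix <- if (cx == 0) lo[[1]] else hi[[1]]
    iy <- if (cy == 0) lo[[2]] else hi[[2]]
    iz <- if (cz == 0) lo[[3]] else hi[[3]]
    wx <- if (cx == 0) wx0 else fr[[1]]
    wy <- if (cy == 0) wy0 else fr[[2]]
    wz <- if (cz == 0) wz0 else fr[[3]]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * map[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Voxelwise mean of aligned 3D maps
#'
#' @param maps A list of 3D arrays of identical shape, or a 4D array whose
#'   last dimension indexes maps.
#' @return The voxelwise arithmetic mean (3D array).
#' @export
average_maps <- function(maps) {
  if (is.list(maps)) {
    if (length(maps) == 0L) stop("average_maps: empty map list")
    d <- dim(maps[[1]])
    stopifnot(all(vapply(maps, function(m) identical(dim(m), d), logical(1))))
    out <- Reduce(`+`, maps) / length(maps)
    return(out)
  }
  d <- dim(maps)
  if (length(d) != 4L || d[4] == 0L) stop("average_maps: need a nonempty 4D array")
  array(rowMeans(matrix(maps, ncol = d[4])), dim = d[1:3])
}

#' Validation-set Grad-CAM maps across cross-validation folds
#'
#' For each fold, computes Grad-CAM maps of that fold's validation samples
#' with the fold's trained model, then pools: per-subject mean maps (all of
#' a subject's validation samples across folds) and the overall mean map.
#'
#' @param cv A `cv_result` from [cross_validate()].
#' @param set The labeled `sample_set` the folds refer to.
#' @param target Passed to [gradcam()].
#' @return List with `mean_map` (3D), `subject_maps` (4D array, last axis =
#'   subject), `subjects`, and `sample_maps` (4D, aligned with `set`).
#' @export
gradcam_validation_maps <- function(cv, set, target = "label") {
  d_in <- dim(set$x)[1:3]
  n <- dim(set$x)[4]
  sample_maps <- array(NA_real_, dim = c(d_in, n))
  for (f in seq_len(cv$folds$k)) {
    va <- cv$folds$folds[[f]]$val
    res <- gradcam(cv$models[[f]], subset_samples(set, va), target = target)
    sample_maps[, , , va] <- res$maps
  }
  subjects <- sort(unique(set$meta$subject))
  subject_maps <- array(0, dim = c(d_in, length(subjects)))
  for (i in seq_along(subjects)) {
    idx <- which(set$meta$subject == subjects[i])
    subject_maps[, , , i] <- average_maps(sample_maps[, , , idx, drop = FALSE])
  }
  list(mean_map = average_maps(sample_maps),
       subject_maps = subject_maps, subjects = subjects,
       sample_maps = sample_maps)
}

#' Write orthogonal-slice PNG of a 3D map
#'
#' Renders the three mid-volume orthogonal slices of a saliency map (or any
#' 3D array) side by side; intensities are min-max scaled for display only.
#'
#' @param map 3D array.
#' @param path Output PNG path.
#' @param main Plot title.
#' @return `path`, invisibly.
#' @export
write_ortho_png <- function(map, path, main = "saliency") {
  d <- dim(map)
  rng <- range(map)
  disp <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
  grDevices::png(path, width = 900, height = 320)
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  cols <- grDevices::hcl.colors(64, "inferno")
  graphics::image(disp[ceiling(d[1] / 2), , ], col = cols, axes = FALSE,
                  main = paste(main, "- sagittal"))
  graphics::image(disp[, ceiling(d[2] / 2), ], col = cols, axes = FALSE,
                  main = paste(main, "- coronal"))
  graphics::image(disp[, , ceiling(d[3] / 2)], col = cols, axes = FALSE,
                  main = paste(main, "- axial"))
  invisible(path)
}
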