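#' SFCN architecture configuration
#'
#' The simple fully convolutional network (SFCN) is a lightweight 3D CNN:
#' a chain of feature blocks, each a 3x3x3 convolution (stride 1, zero
#' padding) followed by batch normalization, ReLU, and optionally a 2x2x2
#' max pooling, and a final block whose 1x1x1 convolution feeds a global
#' average pooling and a fully connected layer producing the class scores.
#'
#' By default a block max-pools while every spatial axis would stay at
#' least 3 voxels after halving; later blocks keep the resolution. On a
#' 96-voxel axis this reproduces the published five-pooling layout; on the
#' desk-scale 32-voxel grid the first three blocks pool, leaving 4x4x4
#' feature maps at the last convolutional layer so that Grad-CAM retains
#' usable spatial extent.
#'
#' @param input_shape Spatial extents of the input volumes.
#' @param block_channels Output channels per block. The scaled-down default
#'   `c(8, 16, 32, 32, 32, 16)` targets desk-scale grids; a full-scale
#'   variant would use `c(32, 64, 128, 256, 256, 64)`.
#' @param in_channels Input channels (1 for a single BOLD sample).
#' @param n_classes Number of output classes.
#' @param pool Character vector, one of `"max"`/`"none"` per block
#'   (the final block never max-pools; its pooling is the global average).
#'   `NULL` selects the default rule above.
#' @param batch_norm Use batch normalization after each convolution.
#' @param dropout Dropout rate applied between global pooling and the fully
#'   connected layer during training.
#' @param seed Seed for weight initialization.
#' @return An `sfcn_config` list.
#' @export
sfcn_config <- function(input_shape = c(32L, 32L, 32L),
                        block_channels = c(8L, 16L, 32L, 32L, 32L, 16L),
                        in_channels = 1L,
                        n_classes = 2L,
                        pool = NULL,
                        batch_norm = TRUE,
                        dropout = 0,
                        seed = 1L) {
  B <- length(block_channels)
  stopifnot(B >= 1L, length(input_shape) == 3L, all(input_shape >= 1L),
            n_classes >= 2L, dropout >= 0, dropout < 1)
  if (is.null(pool)) {
    pool <- character(B)
    ext <- as.integer(input_shape)
    for (i in seq_len(B)) {
      can <- i < B && all(ext %% 2L == 0L) && all(ext %/% 2L >= 3L)
      pool[i] <- if (can) "max" else "none"
      if (can) ext <- ext %/% 2L
    }
  }
  stopifnot(length(pool) == B, all(pool %in% c("max", "none")))
  structure(list(input_shape = as.integer(input_shape),
                 block_channels = as.integer(block_channels),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 pool = pool, batch_norm = batch_norm,
                 dropout = dropout, seed = as.integer(seed)),
            class = "sfcn_config")
}

new_conv_layer <- function(in_ch, out_ch, k, bias = TRUE, seed = NULL) {
  fan_in <- in_ch * k^3
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(stats::rnorm(out_ch * fan_in, 0, sqrt(2 / fan_in)),
              nrow = out_ch, ncol = fan_in)
  list(type = "conv", W = W, b = if (bias) numeric(out_ch) else NULL,
       k = as.integer(k), pad = as.integer((k - 1) / 2),
       in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
}

new_bn_layer <- function(ch) {
  list(type = "bn", gamma = rep(1, ch), beta = numeric(ch),
       running_mean = numeric(ch), running_var = rep(1, ch),
       eps = 1e-5, momentum = 0.1)
}

new_fc_layer <- function(in_dim, out_dim) {
  W <- matrix(stats::rnorm(out_dim * in_dim, 0, sqrt(2 / in_dim)),
              nrow = out_dim, ncol = in_dim)
  list(type = "fc", W = W, b = numeric(out_dim))
}

#' Build an SFCN model
#'
#' Instantiates the layer stack described by an [sfcn_config()] with
#' He-initialized weights. The model records the name of its last
#' convolutional feature layer (`model$gradcam_layer`), the saliency target
#' for [gradcam()].
#'
#' @param config An [sfcn_config()].
#' @return An `sfcn_model`: list with `config`, `layers` (named), `dims`
#'   (spatial extents entering each layer), `gradcam_layer`.
#' @export
build_sfcn <- function(config) {
  stopifnot(inherits(config, "sfcn_config"))
  B <- length(config$block_channels)
  set.seed(config$seed)
  layers <- list()
  dims <- list()
  ext <- config$input_shape
  in_ch <- config$in_channels
  for (i in seq_len(B)) {
    k <- if (i == B) 1L else 3L
    out_ch <- config$block_channels[i]
    nm <- paste0("b", i, "_")
    dims[[paste0(nm, "conv")]] <- ext
    layers[[paste0(nm, "conv")]] <- new_conv_layer(in_ch, out_ch, k)
    if (config$batch_norm) {
      dims[[paste0(nm, "bn")]] <- ext
      layers[[paste0(nm, "bn")]] <- new_bn_layer(out_ch)
    }
    dims[[paste0(nm, "relu")]] <- ext
    layers[[paste0(nm, "relu")]] <- list(type = "relu")
    if (config$pool[i] == "max") {
      if (any(ext %% 2L != 0L) || any(ext %/% 2L < 1L))
        stop("build_sfcn: spatial extent ", paste(ext, collapse = "x"),
             " cannot be halved at block ", i,
             "; use fewer pooling blocks or a larger input grid")
      dims[[paste0(nm, "pool")]] <- ext
      layers[[paste0(nm, "pool")]] <- list(type = "maxpool")
      ext <- ext %/% 2L
    }
    in_ch <- out_ch
  }
  if (any(ext < 1L))
    stop("build_sfcn: pooling chain exhausted the input grid; ",
         "use fewer blocks or a larger grid")
  dims[["gap"]] <- ext
  layers[["gap"]] <- list(type = "gap")
  if (config$dropout > 0) layers[["dropout"]] <- list(type = "dropout",
                                                      rate = config$dropout)
  layers[["fc"]] <- new_fc_layer(in_ch, config$n_classes)
  structure(list(config = config, layers = layers, dims = dims,
                 gradcam_layer = paste0("b", B, "_relu")),
            class = "sfcn_model")
}

#' Count trainable parameters
#'
#' Sums the scalar entries of every trainable tensor (convolution and fully
#' connected weights and biases, batch-norm scales and shifts); running
#' statistics are not counted.
#'
#' @param model An `sfcn_model`, or any list with a `layers` field.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  n <- 0L
  for (l in model$layers) {
    for (f in c("W", "b", "gamma", "beta")) {
      if (!is.null(l[[f]])) n <- n + length(l[[f]])
    }
  }
  n
}

# Forward pass. x: array (dx, dy, dz, N) single-channel input (or cube
# (V, Cin, N)). Returns list(scores = N x n_classes, caches) when
# keep_caches, else just scores.
sfcn_forward <- function(model, x, train = FALSE, keep_caches = FALSE) {
  d0 <- model$config$input_shape
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  N <- dim(x)[4]
  X <- array(x, dim = c(prod(d0), model$config$in_channels, N))
  caches <- list()
  nms <- names(model$layers)
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    nm <- nms[i]
    if (l$type == "conv") {
      dd <- model$dims[[nm]]
      if (keep_caches) caches[[nm]] <- list(X = X, dims = dd)
      X <- conv3d_fw_cpp(X, dd, l$W, l$b, l$k, l$pad)
    } else if (l$type == "bn") {
      V <- dim(X)[1]; C <- dim(X)[2]
      # per-channel moments over voxels and batch; broadcasting relies on
      # the (V, C, N) layout recycling a length-V*C vector across N
      if (train) {
        mu <- rowMeans(colMeans(X))
        va <- rowMeans(colMeans(X * X)) - mu^2
        model$layers[[i]]$running_mean <-
          (1 - l$momentum) * l$running_mean + l$momentum * mu
        model$layers[[i]]$running_var <-
          (1 - l$momentum) * l$running_var + l$momentum * va
      } else {
        mu <- l$running_mean
        va <- l$running_var
      }
      istd <- 1 / sqrt(va + l$eps)
      xhat <- (X - rep(mu, each = V)) * rep(istd, each = V)
      X <- xhat * rep(l$gamma, each = V) + rep(l$beta, each = V)
      if (keep_caches) caches[[nm]] <- list(xhat = xhat, istd = istd)
    } else if (l$type == "relu") {
      X <- pmax(X, 0)
      if (keep_caches) caches[[nm]] <- list(out = X)
    } else if (l$type == "maxpool") {
      dd <- model$dims[[nm]]
      mp <- maxpool3d_fw_cpp(X, dd)
      if (keep_caches) caches[[nm]] <- list(idx = mp$idx, Vin = dim(X)[1])
      X <- mp$Y
    } else if (l$type == "gap") {
      if (keep_caches) caches[[nm]] <- list(V = dim(X)[1], C = dim(X)[2])
      X <- t(colMeans(X))           # N x C
    } else if (l$type == "dropout") {
      if (train && l$rate > 0) {
        mask <- array(stats::rbinom(length(X), 1L, 1 - l$rate) / (1 - l$rate),
                      dim = dim(X))
        X <- X * mask
        if (keep_caches) caches[[nm]] <- list(mask = mask)
      } else if (keep_caches) caches[[nm]] <- list(mask = NULL)
    } else if (l$type == "fc") {
      if (keep_caches) caches[[nm]] <- list(A = X)
      X <- X %*% t(l$W) + matrix(l$b, nrow = nrow(X), ncol = length(l$b),
                                 byrow = TRUE)
    }
  }
  if (keep_caches) list(scores = X, caches = caches, model = model) else X
}

# Backward pass from dscores (N x n_classes). Returns list(grads = named
# list of parameter gradients, captured = gradient at the output of
# `capture` layer if requested, dinput = gradient at the network input when
# `want_dinput`).
sfcn_backward <- function(model, caches, dscores, capture = NULL,
                          want_dinput = FALSE) {
  nms <- names(model$layers)
  grads <- list()
  g <- dscores
  captured <- NULL
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    nm <- nms[i]
    if (!is.null(capture) && nm == capture) captured <- g
    if (l$type == "fc") {
      A <- caches[[nm]]$A
      grads[[nm]] <- list(dW = t(g) %*% A, db = colSums(g))
      g <- g %*% l$W                       # N x C
    } else if (l$type == "dropout") {
      if (!is.null(caches[[nm]]$mask)) g <- g * caches[[nm]]$mask
    } else if (l$type == "gap") {
      V <- caches[[nm]]$V
      g <- array(rep(t(g) / V, each = V),
                 dim = c(V, caches[[nm]]$C, nrow(g)))
    } else if (l$type == "maxpool") {
      g <- maxpool3d_bw_cpp(caches[[nm]]$idx, g, caches[[nm]]$Vin)
    } else if (l$type == "relu") {
      g <- g * (caches[[nm]]$out > 0)
    } else if (l$type == "bn") {
      xhat <- caches[[nm]]$xhat
      istd <- caches[[nm]]$istd
      V <- dim(g)[1]; C <- dim(g)[2]; N <- dim(g)[3]
      m <- V * N
      dgamma <- rowSums(colSums(g * xhat))
      dbeta <- rowSums(colSums(g))
      # with dxhat = g * gamma: sum(dxhat) = gamma * dbeta and
      # sum(dxhat * xhat) = gamma * dgamma, folded back via recycling
      g <- rep(istd * l$gamma / m, each = V) *
        (m * g - rep(dbeta, each = V) - xhat * rep(dgamma, each = V))
      grads[[nm]] <- list(dgamma = dgamma, dbeta = dbeta)
    } else if (l$type == "conv") {
      cc <- caches[[nm]]
      need_dx <- i > 1L || want_dinput
      bw <- conv3d_bw_cpp(cc$X, cc$dims, l$W, g, l$k, l$pad, need_dx)
      grads[[nm]] <- list(dW = bw$dW, db = bw$db)
      g <- if (need_dx) bw$dX else NULL
    }
  }
  list(grads = grads, captured = captured, dinput = g)
}

# Recalibrate batch-norm population statistics: forward passes over the
# given samples in training mode, replacing each BN layer's running mean
# and variance with the cumulative average of the per-batch statistics.
# Needed for reliable eval-mode inference after short training runs, where
# the momentum-based running estimates have not yet converged.
calibrate_bn <- function(model, x, batch_size = 32L) {
  if (!model$config$batch_norm) return(model)
  n <- dim(x)[4]
  nb <- 0L
  for (nm in names(model$layers)) {
    if (model$layers[[nm]]$type == "bn") {
      model$layers[[nm]]$running_mean[] <- 0
      model$layers[[nm]]$running_var[] <- 0
    }
  }
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    nb <- nb + 1L
    for (nm in names(model$layers)) {
      if (model$layers[[nm]]$type == "bn")
        model$layers[[nm]]$momentum <- 1 / nb
    }
    fwd <- sfcn_forward(model, x[, , , idx, drop = FALSE], train = TRUE,
                        keep_caches = TRUE)
    model <- fwd$model
  }
  for (nm in names(model$layers)) {
    if (model$layers[[nm]]$type == "bn") model$layers[[nm]]$momentum <- 0.1
  }
  model
}

# Softmax cross-entropy loss and gradient for integer labels y in {0, 1,
# ...}; returns mean loss over the batch and dscores.
softmax_xent <- function(scores, y) {
  n <- nrow(scores)
  s <- scores - apply(scores, 1, max)
  es <- exp(s)
  p <- es / rowSums(es)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dscores <- p
  dscores[idx] <- dscores[idx] - 1
  list(loss = loss, dscores = dscores / n, prob = p)
}

#' Predict class labels with a trained SFCN
#'
#' @param object An `sfcn_model`.
#' @param newdata Array of samples `(x, y, z, n)` or a `sample_set`.
#' @param type `"class"` for argmax labels (0-based), `"score"` for raw
#'   class scores.
#' @param ... Unused.
#' @return Integer labels or a score matrix.
#' @export
predict.sfcn_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "sample_set")) newdata$x else newdata
  scores <- sfcn_forward(object, x, train = FALSE)
  if (type == "score") return(scores)
  max.col(scores, ties.method = "first") - 1L
}
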