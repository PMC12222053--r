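# Builds a minimal SFCN (one 1x1x1 conv block, no pooling or batch-norm)
# whose post-ReLU feature maps A feed straight into gap -> fc, so the
# class score is y_c = sum_k W_fc[c, k] * mean_v(A_k) and Grad-CAM has a
# closed form: alpha_k = W_fc[c, k] / V.
toy_cam_model <- function(channels = 1L, seed = 3L) {
  cfg <- sfcn_config(c(4L, 4L, 4L), block_channels = channels,
                     pool = "none", batch_norm = FALSE, seed = seed)
  build_sfcn(cfg)
}

# Independent finite-difference oracle for alpha: perturbs the feature
# maps and re-evaluates the analytic tail y(A) = fc(gap(A)).
alpha_fd_oracle <- function(model, A, target_class, eps = 1e-6) {
  W <- model$layers$fc$W
  b <- model$layers$fc$b
  y_of <- function(Acube) (t(colMeans(Acube)) %*% t(W) + b)[1, target_class + 1L]
  V <- dim(A)[1]; C <- dim(A)[2]
  grad <- matrix(0, V, C)
  for (k in seq_len(C)) for (v in seq_len(V)) {
    Ap <- A; Ap[v, k, 1] <- A[v, k, 1] + eps
    Am <- A; Am[v, k, 1] <- A[v, k, 1] - eps
    grad[v, k] <- (y_of(Ap) - y_of(Am)) / (2 * eps)
  }
  colMeans(grad)
}

test_that("Grad-CAM weights match the finite-difference oracle on a toy network", {
  m <- toy_cam_model(channels = 3L)
  set.seed(8)
  x <- array(rnorm(4^3), dim = c(4, 4, 4, 1))
  for (cls in 0:1) {
    res <- gradcam(m, x, target = cls)
    fwd <- sfcnfmri:::sfcn_forward(m, x, keep_caches = TRUE)
    A <- fwd$caches[[m$gradcam_layer]]$out
    alpha_fd <- alpha_fd_oracle(m, A, cls)
    expect_lt(max(abs(res$alpha[1, ] - alpha_fd)),
              1e-4 * max(1, max(abs(alpha_fd))))
    # and the map is the ReLU'd weighted activation sum
    L <- pmax(A[, , 1] %*% alpha_fd, 0)
    expect_equal(as.vector(res$feature_maps), as.vector(L), tolerance = 1e-6)
  }
})

test_that("Grad-CAM of a positively weighted single channel is proportional to its activation", {
  m <- toy_cam_model(channels = 1L)
  w <- 2.7
  m$layers$fc$W <- matrix(c(w, -w), nrow = 2L)   # class 0 weight w > 0
  m$layers$fc$b <- c(0, 0)
  set.seed(2)
  x <- array(rnorm(4^3), dim = c(4, 4, 4, 1))
  fwd <- sfcnfmri:::sfcn_forward(m, x, keep_caches = TRUE)
  A <- fwd$caches[[m$gradcam_layer]]$out[, 1, 1]
  res <- gradcam(m, x, target = 0L)
  V <- length(A)
  expect_equal(res$alpha[1, 1], w / V, tolerance = 1e-10)
  expect_equal(as.vector(res$feature_maps), (w / V) * A, tolerance = 1e-10)
})

test_that("non-positive channel gradients annihilate the map", {
  m <- toy_cam_model(channels = 2L)
  m$layers$fc$W <- matrix(c(-1, -2, 1, 2), nrow = 2L, byrow = TRUE)
  set.seed(3)
  x <- array(rnorm(4^3), dim = c(4, 4, 4, 1))
  res <- gradcam(m, x, target = 0L)   # all alpha < 0, A >= 0
  expect_true(all(res$maps == 0))
})

test_that("duplicating a feature channel halves its weight but preserves the map", {
  m <- toy_cam_model(channels = 2L, seed = 5L)
  set.seed(4)
  x <- array(rnorm(4^3), dim = c(4, 4, 4, 1))
  base <- gradcam(m, x, target = 0L)
  m2 <- m
  cw <- m$layers$b1_conv$W
  m2$layers$b1_conv$W <- cw[c(1, 2, 1, 2), , drop = FALSE]
  m2$layers$b1_conv$b <- m$layers$b1_conv$b[c(1, 2, 1, 2)]
  fw <- m$layers$fc$W
  m2$layers$fc$W <- cbind(fw / 2, fw / 2)[, c(1, 2, 1, 2)]
  dup <- gradcam(m2, x, target = 0L)
  expect_equal(dup$alpha[1, ], rep(base$alpha[1, ] / 2, 2), tolerance = 1e-10)
  expect_equal(dup$maps, base$maps, tolerance = 1e-10)
})

test_that("maps ignore batch composition and target the requested scores", {
  cfg <- sfcn_config(c(8L, 8L, 8L), block_channels = c(3L, 4L), seed = 9L)
  m <- build_sfcn(cfg)
  set.seed(6)
  x <- array(rnorm(8^3 * 5), dim = c(8, 8, 8, 5))
  m <- sfcnfmri:::calibrate_bn(m, x, 2L)
  y <- c(0L, 1L, 1L, 0L, 1L)
  all_maps <- gradcam(m, x, target = y)$maps
  perm <- c(3L, 1L, 5L, 2L, 4L)
  perm_maps <- gradcam(m, x[, , , perm], target = y[perm])$maps
  expect_equal(perm_maps, all_maps[, , , perm], tolerance = 1e-10)
  expect_error(gradcam(m, x, target = y, layer = "b9_relu"), "available")
})

test_that("trilinear upsampling is exact on constants, identity shapes, and ramps", {
  const <- array(3.3, dim = c(3, 3, 3))
  up <- upsample_trilinear(const, c(7, 9, 11))
  expect_true(all(abs(up - 3.3) < 1e-12))
  m <- array(rnorm(27), dim = c(3, 3, 3))
  expect_identical(upsample_trilinear(m, c(3, 3, 3)), m)
  # linear ramp along x: interpolation reproduces the closed-form line
  ramp <- array(rep(seq(0, 1, length.out = 5), times = 9), dim = c(5, 3, 3))
  up2 <- upsample_trilinear(ramp, c(9, 3, 3))
  expect_equal(up2[, 1, 1], seq(0, 1, length.out = 9), tolerance = 1e-12)
  expect_true(all(up2 >= 0))
  expect_error(upsample_trilinear(m, c(2, 3, 3)), ">=")
})

test_that("mean saliency concentrates inside planted ROIs beyond their volume share", {
  fix <- small_recovery_fixture(31L)
  planted <- fix$cfg$effects$planted_rois
  atlas <- fix$res$atlas
  mm <- fix$res$saliency$mean_map
  mask <- atlas$labels %in% planted
  mass_frac <- sum(mm[mask]) / sum(mm)
  vol_frac <- sum(mask) / sum(atlas$labels > 0)
  expect_gt(mass_frac, vol_frac)
})

test_that("map averaging is the voxelwise mean and commutes with order", {
  z <- array(0, dim = c(2, 2, 2))
  c2 <- array(2 * 1.5, dim = c(2, 2, 2))
  expect_equal(average_maps(list(z, c2)), array(1.5, dim = c(2, 2, 2)))
  single <- array(rnorm(8), dim = c(2, 2, 2))
  expect_identical(average_maps(list(single)), single)
  set.seed(7)
  maps <- lapply(1:4, function(i) array(rnorm(8), dim = c(2, 2, 2)))
  expect_equal(average_maps(maps), average_maps(rev(maps)), tolerance = 1e-12)
  expect_error(average_maps(list()), "empty")
})
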