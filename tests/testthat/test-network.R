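cfg0 <- model_config()

test_that("configuration invariants are enforced", {
  expect_error(model_config(tap_channels = c(32, 64, 64, 32)), "fused_channels")
  expect_error(model_config(attention_reduction = 128), "channel count")
  expect_error(new_channel_attention(8, 16), "exceeds the channel count")
})

test_that("the instantiated network has 25 counted conv/deconv layers and 224 fused channels", {
  m <- new_base_model(cfg0, seed = 1L)
  lc <- count_layers(m)
  expect_identical(lc$total, 25L)
  expect_identical(lc$n_deconv, 6L)
  expect_identical(sum(lc$table$stride == 2), 3L) # three downsampling stages
  set.seed(1)
  x <- array(rnorm(2 * 16^3), c(2, 16, 16, 16))
  f <- base_forward(m, x)
  expect_identical(dim(f), c(224L, 16L, 16L, 16L))
  expect_true(all(is.finite(f)))
  expect_error(base_forward(m, array(0, c(2, 12, 12, 12))), "divisible")
})

test_that("channel attention gates as sigmoid bottleneck scaling", {
  set.seed(2)
  ca <- new_channel_attention(8L, 2L)
  x <- array(rnorm(8 * 4^3), c(8, 4, 4, 4))
  # zero weights -> every gate is sigmoid(0) = 0.5
  for (p in list(ca$fc1$w, ca$fc1$b, ca$fc2$w, ca$fc2$b)) p$v[] <- 0
  expect_equal(channel_attention(x, ca), 0.5 * x, ignore_attr = TRUE)
  # multiplicative gating: zero in, zero out; gates bounded below 1
  ca2 <- new_channel_attention(8L, 2L)
  expect_true(all(channel_attention(array(0, dim(x)), ca2) == 0))
  out <- channel_attention(x, ca2)
  expect_true(all(abs(out) <= abs(x)))
  s <- attr(out, "scales")
  expect_true(all(s > 0 & s < 1))
})

test_that("spatial attention follows the affinity formulation", {
  set.seed(3)
  sa <- new_spatial_attention(6L)
  x <- array(rnorm(6 * 4^3), c(6, 4, 4, 4))
  # omega initialises to 0 -> identity
  out <- spatial_attention(x, sa)
  expect_equal(out, x, ignore_attr = TRUE)
  E <- attr(out, "affinity")
  expect_equal(dim(E), c(64L, 64L))
  expect_lt(max(abs(rowSums(E) - 1)), 1e-5)
  # zero A/B weights -> uniform affinity -> context is the spatial mean of C
  sa$wa$w$v[] <- 0; sa$wa$b$v[] <- 0
  sa$wb$w$v[] <- 0; sa$wb$b$v[] <- 0
  sa$omega$v <- 1
  out2 <- spatial_attention(x, sa)
  E2 <- attr(out2, "affinity")
  expect_lt(max(abs(E2 - 1 / 64)), 1e-12)
  Cmat <- matrix(sa$wc$w$v %*% matrix(x, nrow = 6) + sa$wc$b$v, nrow = 6)
  expect_equal(out2 - x, array(rep(rowMeans(Cmat), 64), dim(x)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("spatial attention pools oversized grids and recovers Eq-form behaviour within the limit", {
  set.seed(4)
  sa <- new_spatial_attention(3L)
  x <- array(rnorm(3 * 8^3), c(3, 8, 8, 8))
  out <- spatial_attention(x, sa, pool_max = 64L) # forces factor-2 pooling
  expect_equal(dim(attr(out, "affinity")), c(64L, 64L))
  expect_lt(max(abs(rowSums(attr(out, "affinity")) - 1)), 1e-5)
  # within the limit the full-resolution affinity is used
  out2 <- spatial_attention(x, sa, pool_max = 512L)
  expect_equal(dim(attr(out2, "affinity")), c(512L, 512L))
})

test_that("SCA-VoxRes is a residual unit: zero transform weights give the identity", {
  set.seed(5)
  blk <- new_sca_voxres(6L, reduction = 2L)
  for (p in list(blk$conv1$w, blk$conv1$b, blk$conv2$w, blk$conv2$b)) p$v[] <- 0
  x <- array(rnorm(6 * 4^3), c(6, 4, 4, 4))
  expect_equal(sca_voxres(x, blk), x) # BN inference mode, omega = 0
  blk2 <- new_sca_voxres(6L, reduction = 2L)
  y <- sca_voxres(x, blk2)
  expect_identical(dim(y), dim(x))
  # the transform branch is active, and dropping the skip changes the output
  transform_only <- y - x
  expect_gt(max(abs(transform_only)), 0)
  expect_gt(max(abs(y - transform_only)), 0)
  expect_error(sca_voxres(array(0, c(4, 4, 4, 4)), blk2), "channel mismatch")
})

test_that("disabling attention makes the network independent of SCA parameters", {
  cfg_off <- model_config(attention_on = FALSE)
  m <- new_base_model(cfg_off, seed = 6L)
  set.seed(6)
  x <- array(rnorm(2 * 16^3), c(2, 16, 16, 16))
  y1 <- model_forward(m, x)
  for (b in m$blocks) {
    b$sca$spatial$wa$w$v[] <- 99
    b$sca$channel$fc1$w$v[] <- -99
    b$sca$spatial$omega$v <- 5
  }
  y2 <- model_forward(m, x)
  expect_identical(y1, y2)
  # with attention on, the same perturbation changes the output
  m2 <- new_base_model(model_config(), seed = 6L)
  z1 <- model_forward(m2, x)
  m2$blocks[[1]]$sca$spatial$omega$v <- 5
  z2 <- model_forward(m2, x)
  expect_gt(max(abs(z1 - z2)), 0)
})

test_that("segmentation head emits voxelwise class probabilities", {
  m <- new_base_model(cfg0, seed = 7L)
  set.seed(7)
  x <- array(rnorm(2 * 16^3), c(2, 16, 16, 16))
  p <- model_forward(m, x)
  expect_identical(dim(p), c(2L, 16L, 16L, 16L))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(apply(p, 2:4, sum) - 1)), 1e-6)
  m$head$w$v[] <- 0
  m$head$b$v[] <- 0
  p0 <- segment_head(m, base_forward(m, x))
  expect_true(all(abs(p0 - 0.5) < 1e-12))
})

test_that("two-path fusion concatenates 448 channels and respects path independence", {
  cfg <- model_config()
  tp <- new_two_path_model(cfg, seed = 8L)
  expect_identical(ncol(tp$fusion_head$w$v), 448L)
  set.seed(8)
  xf <- array(rnorm(2 * 16^3), c(2, 16, 16, 16))
  xt <- array(rnorm(2 * 16^3), c(2, 16, 16, 16))
  p <- two_path_forward(tp, xf, xt)
  expect_identical(dim(p), c(2L, 16L, 16L, 16L))
  expect_lt(max(abs(apply(p, 2:4, sum) - 1)), 1e-6)
  expect_error(two_path_forward(tp, xf, array(0, c(2, 8, 8, 8))), "identical shapes")
  # zero the T1 path -> output is a function of FLAIR only
  for (p2 in scavox:::collect_params(tp$path_t1)) p2$v[] <- 0
  y1 <- two_path_forward(tp, xf, xt)
  y2 <- two_path_forward(tp, xf, array(rnorm(2 * 16^3), c(2, 16, 16, 16)))
  expect_equal(y1, y2, tolerance = 1e-12)
})

test_that("stem convolutions are translation-consistent on interior voxels", {
  set.seed(9)
  w <- scavox:::ad_param(matrix(rnorm(4 * 2 * 27, 0, 0.3), 4))
  b <- scavox:::ad_param(rnorm(4))
  big <- array(rnorm(2 * 12^3), c(2, 12, 12, 12))
  crop <- big[, 3:10, 3:10, 3:10, drop = FALSE]
  fb <- scavox:::op_conv3(NULL, scavox:::ad_node(NULL, big), w, b, 1L, 1L, 3L)$v
  fc <- scavox:::op_conv3(NULL, scavox:::ad_node(NULL, crop), w, b, 1L, 1L, 3L)$v
  # interior of the crop (1 voxel in from its border) matches the big response
  expect_equal(fc[, 2:7, 2:7, 2:7], fb[, 4:9, 4:9, 4:9], tolerance = 1e-12)
})

test_that("checkpoint save/load round-trips weights, BN state and forward output", {
  m <- new_base_model(cfg0, seed = 10L)
  set.seed(10)
  x <- array(rnorm(2 * 16^3), c(2, 16, 16, 16))
  # move BN running stats off their initial values
  invisible(scavox:::fwd_model(NULL, m, list(x), training = TRUE))
  y <- model_forward(m, x)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(model_forward(m2, x), y)
  # saving what was loaded is a fixed point
  path2 <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m2, path2)
  expect_identical(readRDS(path)$values, readRDS(path2)$values)
  expect_identical(readRDS(path)$bn, readRDS(path2)$bn)
})
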