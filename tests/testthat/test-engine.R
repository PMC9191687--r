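test_that("the learning-rate schedule decays exponentially from 1e-4", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 1e-4)
  expect_equal(lr_schedule(10, cfg), 1e-4 * 0.95^10, tolerance = 1e-12)
  expect_equal(lr_schedule(10, cfg), 5.987e-5, tolerance = 1e-3)
  expect_true(all(diff(lr_schedule(0:20, cfg)) < 0))
  flat <- train_config(decay_rate = 1)
  expect_equal(lr_schedule(0:5, flat), rep(1e-4, 6))
  expect_error(lr_schedule(-1, cfg), ">= 0")
})

test_that("ground-truth fusion implements union, intersection and single-rater modes", {
  a <- array(0L, c(4, 4, 4)); a[1, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 4)); b[4, 4, 4] <- 1L
  u <- fuse_ground_truth(lesion_mask(a), lesion_mask(b), "union")
  expect_identical(sum(u$data), 2L)
  i <- fuse_ground_truth(lesion_mask(a), lesion_mask(a), "intersection")
  expect_identical(i$data, a)
  expect_identical(fuse_ground_truth(a, b, "rater2")$data, b)
  expect_error(fuse_ground_truth(a, b, "majority"), "unknown")
  # union dominates each rater on phantom masks
  ph <- test_phantom(shape = 24L, n_lesions = 1L, seed = 6L)
  u2 <- fuse_ground_truth(ph$rater1, ph$rater2, "union")
  expect_true(all(u2$data >= ph$rater1$data))
  expect_true(all(u2$data >= ph$rater2$data))
})

test_that("a short training run logs both losses, checkpoints, and tracks the best epoch", {
  ph <- test_phantom(shape = 32L, n_lesions = 2L, seed = 7L)
  v4 <- build_volume4d(ph$flair)
  ckpt <- withr::local_tempfile(fileext = ".ckpt")
  cfg <- train_config(lr0 = 1e-3, epochs = 2L, batch_size = 1L,
                      patches_per_epoch = 3L, patch_size = 16L, seed = 7L,
                      val_patches = 2L, checkpoint_path = ckpt)
  m <- new_base_model(model_config(), seed = 7L)
  m <- train(m, list(list(vol4d = v4, rater1 = ph$rater1,
                          rater2 = ph$rater2)), cfg)
  log <- attr(m, "log")
  expect_identical(nrow(log), 2L)
  expect_true(all(is.finite(log$train_loss)))
  expect_true(all(is.finite(log$val_loss)))
  expect_identical(attr(log, "best_epoch"), which.min(log$val_loss))
  expect_true(file.exists(ckpt))
  # the checkpointed model reproduces the best validation loss
  m2 <- load_checkpoint(ckpt)
  expect_s3_class(m2, "base_model")
})

test_that("training is reproducible given the seed", {
  ph <- test_phantom(shape = 32L, n_lesions = 2L, seed = 8L)
  v4 <- build_volume4d(ph$flair)
  cfg <- train_config(lr0 = 1e-3, epochs = 1L, batch_size = 1L,
                      patches_per_epoch = 2L, patch_size = 16L, seed = 9L,
                      val_patches = 2L)
  run <- function() {
    m <- new_base_model(model_config(), seed = 9L)
    m <- train(m, list(list(vol4d = v4, mask = ph$truth)), cfg)
    attr(m, "log")
  }
  expect_identical(run()$train_loss, run()$train_loss)
})

test_that("optimisation on a single repeated patch drives the loss down", {
  ph <- test_phantom(shape = 32L, n_lesions = 2L, seed = 10L)
  v4 <- build_volume4d(ph$flair)
  spec <- patch_spec(16L, lesion_fraction = 1, seed = 11L)
  ctr <- sample_centers(ph$truth, 1L, spec)
  p <- extract_patch(v4, ctr[1, ], spec, label_mask = ph$truth)
  g <- scavox:::one_hot(p$label)
  m <- new_base_model(model_config(), seed = 11L)
  params <- scavox:::collect_params(m)
  opt <- scavox:::adam_state()
  lp <- loss_params()
  losses <- numeric(50)
  for (s in 1:50) {
    scavox:::ad_zero_grad(params)
    tape <- scavox:::ad_tape()
    pr <- scavox:::fwd_model(tape, m, list(p$data), training = TRUE)
    l <- scavox:::op_focal_tversky(tape, pr, g, lp)
    losses[s] <- l$v
    scavox:::ad_backward(tape, l)
    scavox:::adam_step(params, opt, 1e-3)
  }
  expect_lt(mean(losses[46:50]), 0.25 * mean(losses[1:5]))
})

test_that("tiled inference stitches to the input shape and a zero head predicts nothing", {
  ph <- test_phantom(shape = 24L, n_lesions = 1L, seed = 12L)
  v4 <- build_volume4d(ph$flair)
  m <- new_base_model(model_config(), seed = 12L)
  m$head$w$v[] <- 0
  m$head$b$v[] <- 0
  res <- predict_volume(m, v4, patch_size = 16L)
  expect_identical(dim(res$prob), c(24L, 24L, 24L))
  expect_identical(dim(res$mask$data), c(24L, 24L, 24L))
  expect_true(all(abs(res$prob - 0.5) < 1e-12))
  expect_identical(sum(res$mask$data), 0L) # strict > 0.5 thresholding
})

test_that("stitching the tiles of a label volume reproduces it exactly", {
  ph <- test_phantom(shape = 24L, n_lesions = 1L, seed = 13L)
  lbl <- ph$truth$data * 1
  ch <- array(0, c(2, dim(lbl)))
  ch[1, , , ] <- lbl
  ch[2, , , ] <- lbl
  tiles <- tile_volume(volume4d(ch), patch_spec(16L))
  back <- stitch_tiles(lapply(tiles, function(t) t$data[1, , , , drop = FALSE]),
                       lapply(tiles, `[[`, "origin"),
                       attr(tiles, "orig_dim"), attr(tiles, "padded_dim"),
                       attr(tiles, "tile_size"))
  expect_equal(back[1, , , ], lbl)
})
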