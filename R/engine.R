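#' Training configuration
#'
#' @param lr0 Initial Adam learning rate (default 1e-4).
#' @param decay_rate Per-epoch exponential decay factor in (0, 1].
#' @param epochs Number of epochs (>= 1, default 100).
#' @param batch_size Patches per optimizer step.
#' @param patches_per_epoch Training patches sampled per epoch.
#' @param patch_size Training patch extent (must be divisible by 8).
#' @param lesion_fraction Fraction of lesion-centred patches (default 0.6).
#' @param seed RNG seed for sampling and initialisation.
#' @param val_patches Number of (fixed) validation patches.
#' @param checkpoint_path Where the best-on-validation weights are saved;
#'   `NULL` disables checkpointing.
#' @param ground_truth_fusion How two rater masks combine into the training
#'   target: `"union"` (logical-or, the default), `"intersection"`,
#'   `"rater1"` or `"rater2"`.
#' @param threshold Probability threshold binarising the lesion class at
#'   inference (default 0.5).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-4, decay_rate = 0.95, epochs = 100L,
                         batch_size = 4L, patches_per_epoch = 32L,
                         patch_size = c(80L, 80L, 80L), lesion_fraction = 0.6,
                         seed = 1L, val_patches = 8L, checkpoint_path = NULL,
                         ground_truth_fusion = c("union", "intersection",
                                                 "rater1", "rater2"),
                         threshold = 0.5, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_eps = 1e-8) {
  if (lr0 <= 0) stop("`lr0` must be > 0")
  if (decay_rate <= 0 || decay_rate > 1) stop("`decay_rate` must be in (0, 1]")
  if (epochs < 1) stop("`epochs` must be >= 1")
  if (length(patch_size) == 1L) patch_size <- rep(patch_size, 3)
  structure(list(lr0 = lr0, decay_rate = decay_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patches_per_epoch = as.integer(patches_per_epoch),
                 patch_size = as.integer(patch_size),
                 lesion_fraction = lesion_fraction, seed = as.integer(seed),
                 val_patches = as.integer(val_patches),
                 checkpoint_path = checkpoint_path,
                 ground_truth_fusion = match.arg(ground_truth_fusion),
                 threshold = threshold, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_eps = adam_eps),
            class = "train_config")
}

#' Exponentially decayed learning rate
#'
#' `lr = lr0 * decay_rate^epoch` with `epoch` counted from 0.
#'
#' @param epoch Epoch index (>= 0).
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  if (any(epoch < 0)) stop("`epoch` must be >= 0")
  cfg$lr0 * cfg$decay_rate^epoch
}

#' Fuse two rater masks into one training target
#'
#' @param r1,r2 Congruent [lesion_mask()]s (or binary arrays).
#' @param mode `"union"` (logical-or), `"intersection"`, `"rater1"` or
#'   `"rater2"`.
#' @return A [lesion_mask()].
#' @export
fuse_ground_truth <- function(r1, r2, mode = "union") {
  r1 <- as_lesion_mask(r1)
  r2 <- as_lesion_mask(r2)
  if (!identical(dim(r1$data), dim(r2$data))) {
    stop("rater masks have different shapes")
  }
  d <- switch(mode,
    union = pmax(r1$data, r2$data),
    intersection = r1$data * r2$data,
    rater1 = r1$data,
    rater2 = r2$data,
    stop("unknown ground-truth fusion mode: ", mode)
  )
  lesion_mask(array(d, dim(r1$data)), affine = r1$affine)
}

# Resolve the target mask of one training case (list with vol4d and either
# `mask` or rater1/rater2).
case_target <- function(case, mode) {
  if (!is.null(case$mask)) return(as_lesion_mask(case$mask))
  if (is.null(case$rater1) || is.null(case$rater2)) {
    stop("each case needs `mask` or both `rater1` and `rater2`")
  }
  fuse_ground_truth(case$rater1, case$rater2, mode)
}

# Draw one (input, one-hot label) training example.
draw_example <- function(case, target, cfg) {
  spec <- patch_spec(cfg$patch_size, cfg$lesion_fraction)
  frac <- if (sum(target$data) > 0) cfg$lesion_fraction else 0
  center <- sample_centers(target, 1L,
                           patch_spec(cfg$patch_size,
                                      if (stats::runif(1) < frac) 1 else 0))
  p <- extract_patch(case$vol4d, center[1, ], spec, label_mask = target)
  inputs <- list(p$data)
  if (!is.null(case$vol4d_t1)) {
    p2 <- extract_patch(case$vol4d_t1, center[1, ], spec)
    inputs <- c(inputs, list(p2$data))
  }
  list(inputs = inputs, g = one_hot(p$label))
}

#' Train a segmentation model
#'
#' Per epoch, lesion-biased patches are sampled from the training cases and
#' optimised with Adam on the Focal Tversky loss at the exponentially
#' decayed learning rate; a fixed set of validation patches is scored after
#' each epoch and the best-on-validation weights are checkpointed.
#'
#' @param model A [new_base_model()] or [new_two_path_model()].
#' @param volumes List of training cases; each case is a list with `vol4d`
#'   (and `vol4d_t1` for the two-path model) plus either `mask` or `rater1`
#'   and `rater2`.
#' @param cfg A [train_config()].
#' @param val_volumes Validation cases (same structure); defaults to
#'   `volumes` (useful for overfitting sanity checks).
#' @param loss A [loss_params()].
#' @param verbose Print one line per epoch.
#' @return The trained model, with attribute `"log"` (a tibble of per-epoch
#'   learning rate, training loss and validation loss, plus `"best_epoch"`).
#' @export
train <- function(model, volumes, cfg = train_config(), val_volumes = volumes,
                  loss = loss_params(), verbose = FALSE) {
  if (length(volumes) < 1 || length(val_volumes) < 1) {
    stop("need at least one training and one validation volume")
  }
  targets <- lapply(volumes, case_target, mode = cfg$ground_truth_fusion)
  val_targets <- lapply(val_volumes, case_target,
                        mode = cfg$ground_truth_fusion)
  params <- collect_params(model)
  opt <- adam_state()

  val_set <- withr::with_seed(cfg$seed + 1L, {
    lapply(seq_len(cfg$val_patches), function(i) {
      j <- ((i - 1L) %% length(val_volumes)) + 1L
      draw_example(val_volumes[[j]], val_targets[[j]], cfg)
    })
  })
  val_loss <- function() {
    mean(vapply(val_set, function(ex) {
      pr <- fwd_model(NULL, model, ex$inputs, training = FALSE)
      focal_tversky_loss(pr$v, ex$g, loss)
    }, numeric(1)))
  }

  log_lr <- log_train <- log_val <- numeric(cfg$epochs)
  best <- Inf
  best_epoch <- NA_integer_
  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_schedule(epoch - 1L, cfg)
      losses <- numeric(0)
      done <- 0L
      while (done < cfg$patches_per_epoch) {
        nb <- min(cfg$batch_size, cfg$patches_per_epoch - done)
        ad_zero_grad(params)
        for (b in seq_len(nb)) {
          j <- sample.int(length(volumes), 1L)
          ex <- draw_example(volumes[[j]], targets[[j]], cfg)
          tape <- ad_tape()
          pr <- fwd_model(tape, model, ex$inputs, training = TRUE)
          l <- op_focal_tversky(tape, pr, ex$g, loss)
          if (!is.finite(l$v)) {
            stop("non-finite loss at epoch ", epoch, " (value ", l$v,
                 "); lower the learning rate")
          }
          losses <- c(losses, l$v)
          ad_backward(tape, l, seed_grad = 1 / nb)
        }
        adam_step(params, opt, lr, cfg$adam_beta1, cfg$adam_beta2,
                  cfg$adam_eps)
        done <- done + nb
      }
      vl <- val_loss()
      log_lr[epoch] <- lr
      log_train[epoch] <- mean(losses)
      log_val[epoch] <- vl
      if (vl < best) {
        best <- vl
        best_epoch <- epoch
        if (!is.null(cfg$checkpoint_path)) {
          save_checkpoint(model, cfg$checkpoint_path, optimizer = opt)
        }
      }
      if (verbose) {
        message(sprintf("epoch %3d  lr %.3e  train %.4f  val %.4f%s",
                        epoch, lr, mean(losses), vl,
                        if (epoch == best_epoch) "  *" else ""))
      }
    }
  })
  log <- tibble::tibble(epoch = seq_len(cfg$epochs), lr = log_lr,
                        train_loss = log_train, val_loss = log_val)
  attr(log, "best_epoch") <- best_epoch
  attr(model, "log") <- log
  model
}

#' Whole-volume inference by tiling and stitching
#'
#' Divides the preprocessed volume into non-overlapping tiles (zero-padded
#' to a full grid), forward-passes each tile, stitches the probability maps
#' back at the recorded origins, strips the padding and thresholds the
#' lesion-class probability.
#'
#' @param model A trained model.
#' @param vol4d Preprocessed [volume4d()] (FLAIR path).
#' @param vol4d_t1 Second-modality [volume4d()] (two-path model only).
#' @param patch_size Tile extent (divisible by 8).
#' @param threshold Lesion-probability threshold (default 0.5).
#' @return A list with `mask` (a [lesion_mask()]) and `prob` (the 3D
#'   lesion-probability array), both shaped like the input volume.
#' @export
predict_volume <- function(model, vol4d, vol4d_t1 = NULL,
                           patch_size = c(80L, 80L, 80L), threshold = 0.5) {
  if (length(patch_size) == 1L) patch_size <- rep(patch_size, 3)
  check_divisible(as.integer(patch_size), 8L)
  two_path <- inherits(model, "two_path_model")
  if (two_path && is.null(vol4d_t1)) {
    stop("a two-path model needs `vol4d_t1`")
  }
  spec <- patch_spec(patch_size)
  tiles <- tile_volume(vol4d, spec)
  tiles_t1 <- if (two_path) tile_volume(vol4d_t1, spec)
  probs <- lapply(seq_along(tiles), function(i) {
    inputs <- list(tiles[[i]]$data)
    if (two_path) inputs <- c(inputs, list(tiles_t1[[i]]$data))
    fwd_model(NULL, model, inputs, training = FALSE)$v
  })
  origins <- lapply(tiles, `[[`, "origin")
  stitched <- stitch_tiles(probs, origins, attr(tiles, "orig_dim"),
                           attr(tiles, "padded_dim"), attr(tiles, "tile_size"))
  lesion_prob <- stitched[2, , , ]
  dim(lesion_prob) <- attr(tiles, "orig_dim")
  mask <- lesion_mask(array(as.integer(lesion_prob > threshold),
                            dim(lesion_prob)), affine = vol4d$affine)
  list(mask = mask, prob = lesion_prob)
}
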