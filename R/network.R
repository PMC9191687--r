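#' Network architecture configuration
#'
#' Hyperparameters of the single-path SCA-VoxRes segmentation network: a
#' 17-convolution trunk (two stem convolutions, three stride-2 downsampling
#' convolutions and six residual SCA-VoxRes modules of two convolutions
#' each), four multi-scale taps upsampled to full resolution and fused into
#' a 224-channel feature map, and a 1x1x1 segmentation head. Including the
#' six upsampling deconvolutions, the full-resolution tap projection and the
#' head, the network has exactly 25 convolution/deconvolution layers; the
#' 1x1x1 convolutions inside the spatial-attention blocks are attention
#' arithmetic and are not counted.
#'
#' @param in_channels Input channels (2: enhanced intensity + edge map).
#' @param stem_channels Channels of the two full-resolution stem
#'   convolutions (32).
#' @param body_channels Channels of the residual body (64).
#' @param n_voxres Number of SCA-VoxRes residual modules (fixed at 6).
#' @param n_downsamples Number of stride-2 convolutions (fixed at 3).
#' @param tap_channels Channels of the four tapped feature streams; must sum
#'   to `fused_channels`.
#' @param fused_channels Channels of the fused multi-scale feature map (224).
#' @param kernel Trunk convolution kernel extent (3).
#' @param attention_reduction Channel-attention bottleneck ratio (>= 1).
#' @param attention_pool_max Maximum spatial-attention grid size N; larger
#'   grids are average-pooled before the affinity matrix is formed and the
#'   aggregated context is nearest-neighbour upsampled back. Whenever the
#'   grid is already within the limit the attention is exact.
#' @param n_classes Output classes (2: background, lesion).
#' @param attention_on If `FALSE` the SCA blocks are bypassed, giving the
#'   attention-free VoxRes ablation baseline.
#' @param sca_order Composition order inside the SCA block.
#' @return An object of class `model_config`.
#' @export
model_config <- function(in_channels = 2L, stem_channels = 32L,
                         body_channels = 64L, n_voxres = 6L,
                         n_downsamples = 3L,
                         tap_channels = c(32L, 64L, 64L, 64L),
                         fused_channels = 224L, kernel = 3L,
                         attention_reduction = 8L,
                         attention_pool_max = 4096L, n_classes = 2L,
                         attention_on = TRUE,
                         sca_order = c("spatial_first", "channel_first")) {
  if (sum(tap_channels) != fused_channels) {
    stop("sum(tap_channels) must equal fused_channels")
  }
  if (n_voxres != 6L) stop("the architecture uses exactly 6 SCA-VoxRes modules")
  if (n_downsamples != 3L) stop("the architecture uses exactly 3 stride-2 convolutions")
  if (attention_reduction < 1) stop("`attention_reduction` must be >= 1")
  if (attention_reduction > body_channels) {
    stop("`attention_reduction` cannot exceed the channel count")
  }
  structure(list(
    in_channels = as.integer(in_channels),
    stem_channels = as.integer(stem_channels),
    body_channels = as.integer(body_channels),
    n_voxres = as.integer(n_voxres),
    n_downsamples = as.integer(n_downsamples),
    tap_channels = as.integer(tap_channels),
    fused_channels = as.integer(fused_channels),
    kernel = as.integer(kernel),
    attention_reduction = as.integer(attention_reduction),
    attention_pool_max = as.integer(attention_pool_max),
    n_classes = as.integer(n_classes),
    attention_on = isTRUE(attention_on),
    sca_order = match.arg(sca_order)
  ), class = "model_config")
}

# ---- parameter constructors -------------------------------------------------

he_sd <- function(fan_in) sqrt(2 / fan_in)

new_conv3_params <- function(cin, cout, kernel = 3L) {
  k3 <- kernel^3
  list(w = ad_param(matrix(stats::rnorm(cout * cin * k3, 0, he_sd(cin * k3)),
                           nrow = cout)),
       b = ad_param(rep(0, cout)))
}

new_conv1_params <- function(cin, cout) {
  list(w = ad_param(matrix(stats::rnorm(cout * cin, 0, he_sd(cin)), nrow = cout)),
       b = ad_param(rep(0, cout)))
}

new_deconv2_params <- function(cin, cout) {
  list(w = ad_param(matrix(stats::rnorm(cout * 8 * cin, 0, he_sd(cin)),
                           nrow = cout * 8)),
       b = ad_param(rep(0, cout)))
}

new_fc_params <- function(nin, nout) {
  list(w = ad_param(matrix(stats::rnorm(nout * nin, 0, he_sd(nin)), nrow = nout)),
       b = ad_param(rep(0, nout)))
}

# ---- attention blocks -------------------------------------------------------

#' Create a channel-attention block
#'
#' Global average pool, a two-layer bottleneck (`C -> C/r -> C`, ReLU then
#' sigmoid), producing a per-channel gate in (0, 1) that rescales the input.
#'
#' @param channels Feature channels C.
#' @param reduction Bottleneck ratio r (<= C).
#' @return A `channel_attention` block holding its parameters.
#' @export
new_channel_attention <- function(channels, reduction = 8L) {
  if (reduction > channels) {
    stop("`reduction` (", reduction, ") exceeds the channel count (", channels, ")")
  }
  hidden <- max(1L, channels %/% as.integer(reduction))
  structure(list(fc1 = new_fc_params(channels, hidden),
                 fc2 = new_fc_params(hidden, channels),
                 channels = channels),
            class = "channel_attention")
}

fwd_channel_attention <- function(tape, x, ca) {
  s <- op_gap(tape, x)
  s <- op_fc(tape, s, ca$fc1$w, ca$fc1$b)
  s <- op_relu(tape, s)
  s <- op_fc(tape, s, ca$fc2$w, ca$fc2$b)
  s <- op_sigmoid(tape, s)
  list(out = op_scale_ch(tape, x, s), scales = s)
}

#' Apply channel attention to a feature map
#'
#' @param x A `(C, D, H, W)` array.
#' @param ca A [new_channel_attention()] block.
#' @return The gated array, with attribute `"scales"` (the per-channel gate).
#' @export
channel_attention <- function(x, ca) {
  r <- fwd_channel_attention(NULL, ad_node(NULL, x), ca)
  out <- r$out$v
  attr(out, "scales") <- r$scales$v
  out
}

#' Create a spatial-attention block
#'
#' Three 1x1x1 convolutions produce maps A, B, C; the affinity
#' `E = rowwise-softmax(B %*% t(A))` (an N x N row-stochastic matrix over the
#' spatial grid) aggregates C, and the output is
#' `O_j = omega * sum_i E_ij C_i + F_j` with `omega` a learnable scalar
#' initialised to 0, so the block starts as the identity.
#'
#' @param channels Feature channels C.
#' @return A `spatial_attention` block holding its parameters.
#' @export
new_spatial_attention <- function(channels) {
  structure(list(wa = new_conv1_params(channels, channels),
                 wb = new_conv1_params(channels, channels),
                 wc = new_conv1_params(channels, channels),
                 omega = ad_param(0),
                 channels = channels),
            class = "spatial_attention")
}

attention_pool_factor <- function(sp, pool_max) {
  f <- 1L
  while (prod(sp %/% f) > pool_max) {
    f2 <- f * 2L
    if (any(sp %% f2 != 0L)) {
      stop("spatial grid ", paste(sp, collapse = "x"), " cannot be pooled ",
           "below attention_pool_max = ", pool_max)
    }
    f <- f2
  }
  f
}

fwd_spatial_attention <- function(tape, x, sa, pool_max = 4096L) {
  dm <- dim(x$v)
  C <- dm[1]
  sp <- dm[-1]
  A <- op_conv1(tape, x, sa$wa$w, sa$wa$b)
  B <- op_conv1(tape, x, sa$wb$w, sa$wb$b)
  Cm <- op_conv1(tape, x, sa$wc$w, sa$wc$b)
  f <- attention_pool_factor(sp, pool_max)
  A <- op_avgpool(tape, A, f)
  B <- op_avgpool(tape, B, f)
  Cm <- op_avgpool(tape, Cm, f)
  spp <- sp %/% f
  Np <- prod(spp)
  Amat <- op_transpose(tape, op_reshape(tape, A, c(C, Np))) # N x C
  Bmat <- op_transpose(tape, op_reshape(tape, B, c(C, Np)))
  Cmat <- op_transpose(tape, op_reshape(tape, Cm, c(C, Np)))
  E <- op_rowsoftmax(tape, op_matmul_nt(tape, Bmat, Amat))
  ctx <- op_matmul(tape, E, Cmat) # N x C
  ctx <- op_reshape(tape, op_transpose(tape, ctx), c(C, spp))
  ctx <- op_upnearest(tape, ctx, f)
  list(out = op_add(tape, op_wscale(tape, ctx, sa$omega), x), affinity = E)
}

#' Apply spatial attention to a feature map
#'
#' @param x A `(C, D, H, W)` array.
#' @param sa A [new_spatial_attention()] block.
#' @param pool_max Maximum affinity grid size (see [model_config()]).
#' @return The attended array, with attribute `"affinity"` (the
#'   row-stochastic E matrix actually used).
#' @export
spatial_attention <- function(x, sa, pool_max = 4096L) {
  r <- fwd_spatial_attention(NULL, ad_node(NULL, x), sa, pool_max)
  out <- r$out$v
  attr(out, "affinity") <- r$affinity$v
  out
}

#' Create an SCA (spatial-channel attention) block
#'
#' @param channels Feature channels.
#' @param reduction Channel-attention bottleneck ratio.
#' @param order Composition order (default spatial then channel attention).
#' @return An `sca_module` block.
#' @export
new_sca_module <- function(channels, reduction = 8L,
                           order = c("spatial_first", "channel_first")) {
  structure(list(spatial = new_spatial_attention(channels),
                 channel = new_channel_attention(channels, reduction),
                 order = match.arg(order)),
            class = "sca_module")
}

fwd_sca <- function(tape, x, sca, cfg) {
  if (!cfg$attention_on) return(x)
  if (identical(sca$order, "spatial_first")) {
    h <- fwd_spatial_attention(tape, x, sca$spatial, cfg$attention_pool_max)$out
    fwd_channel_attention(tape, h, sca$channel)$out
  } else {
    h <- fwd_channel_attention(tape, x, sca$channel)$out
    fwd_spatial_attention(tape, h, sca$spatial, cfg$attention_pool_max)$out
  }
}

#' Apply an SCA block to a feature map
#'
#' @param x A `(C, D, H, W)` array.
#' @param sca A [new_sca_module()] block.
#' @param cfg A [model_config()] (supplies pooling limit, order, ablation
#'   flag).
#' @return The attended array (same shape as `x`).
#' @export
sca_module <- function(x, sca, cfg = model_config()) {
  fwd_sca(NULL, ad_node(NULL, x), sca, cfg)$v
}

#' Create an SCA-VoxRes residual module
#'
#' Two conv(3x3x3)+BN+ReLU layers whose output passes through an SCA block
#' before the residual addition:
#' `F + SCA(ReLU(BN(conv(ReLU(BN(conv(F)))))))`.
#'
#' @param channels Feature channels (input = output).
#' @param reduction Channel-attention bottleneck ratio.
#' @param kernel Convolution kernel extent.
#' @param order SCA composition order.
#' @return An `sca_voxres` block.
#' @export
new_sca_voxres <- function(channels, reduction = 8L, kernel = 3L,
                           order = "spatial_first") {
  structure(list(conv1 = new_conv3_params(channels, channels, kernel),
                 bn1 = new_bn(channels),
                 conv2 = new_conv3_params(channels, channels, kernel),
                 bn2 = new_bn(channels),
                 sca = new_sca_module(channels, reduction, order),
                 kernel = kernel),
            class = "sca_voxres")
}

fwd_sca_voxres <- function(tape, x, blk, cfg, training = FALSE) {
  pad <- blk$kernel %/% 2L
  h <- op_conv3(tape, x, blk$conv1$w, blk$conv1$b, stride = 1L, pad = pad,
                kernel = blk$kernel)
  h <- op_relu(tape, op_bn(tape, h, blk$bn1, training))
  h <- op_conv3(tape, h, blk$conv2$w, blk$conv2$b, stride = 1L, pad = pad,
                kernel = blk$kernel)
  h <- op_relu(tape, op_bn(tape, h, blk$bn2, training))
  h <- fwd_sca(tape, h, blk$sca, cfg)
  op_add(tape, x, h)
}

#' Apply an SCA-VoxRes module to a feature map
#'
#' @param x A `(C, D, H, W)` array with C matching the block's channels.
#' @param blk A [new_sca_voxres()] block.
#' @param cfg A [model_config()].
#' @param training Use batch statistics (`TRUE`) or running statistics.
#' @return Array of the same shape as `x`.
#' @export
sca_voxres <- function(x, blk, cfg = model_config(), training = FALSE) {
  if (dim(x)[1] != length(blk$conv1$b$v)) {
    stop("channel mismatch: input has ", dim(x)[1], " channels, block expects ",
         length(blk$conv1$b$v))
  }
  fwd_sca_voxres(NULL, ad_node(NULL, x), blk, cfg, training)$v
}

# ---- full models ------------------------------------------------------------

#' Instantiate the single-path base model
#'
#' Trunk: conv(32)+BN+ReLU, conv(32)+ReLU [tap 1], then three repetitions of
#' stride-2 conv(64)+BN+ReLU followed by two SCA-VoxRes modules [taps 2-4 at
#' 1/2, 1/4, 1/8 resolution]. The full-resolution tap passes through a 1x1x1
#' projection; the three coarse taps are upsampled with 1, 2, 3 kernel-2
#' stride-2 deconvolutions; all four streams concatenate to 224 channels.
#' A 1x1x1 convolution + voxelwise softmax forms the segmentation head.
#'
#' @param cfg A [model_config()].
#' @param seed Optional seed for weight initialisation.
#' @return An object of class `base_model`.
#' @export
new_base_model <- function(cfg = model_config(), seed = NULL) {
  build <- function() {
    sc <- cfg$stem_channels
    bc <- cfg$body_channels
    k <- cfg$kernel
    m <- list(
      cfg = cfg,
      stem1 = new_conv3_params(cfg$in_channels, sc, k),
      bn1 = new_bn(sc),
      stem2 = new_conv3_params(sc, sc, k),
      down = lapply(1:3, function(i) {
        cin <- if (i == 1) sc else bc
        list(conv = new_conv3_params(cin, bc, k), bn = new_bn(bc))
      }),
      blocks = lapply(1:6, function(i) {
        new_sca_voxres(bc, cfg$attention_reduction, k, cfg$sca_order)
      }),
      tap0_proj = new_conv1_params(sc, cfg$tap_channels[1]),
      up1 = list(new_deconv2_params(bc, cfg$tap_channels[2])),
      up2 = list(new_deconv2_params(bc, bc),
                 new_deconv2_params(bc, cfg$tap_channels[3])),
      up3 = list(new_deconv2_params(bc, bc), new_deconv2_params(bc, bc),
                 new_deconv2_params(bc, cfg$tap_channels[4])),
      head = new_conv1_params(cfg$fused_channels, cfg$n_classes)
    )
    m$layer_table <- base_layer_table(cfg)
    class(m) <- "base_model"
    m
  }
  if (!is.null(seed)) withr::with_seed(seed, build()) else build()
}

base_layer_table <- function(cfg) {
  tibble::tibble(
    name = c("stem1", "stem2", "down1", "block1.conv1", "block1.conv2",
             "block2.conv1", "block2.conv2", "down2", "block3.conv1",
             "block3.conv2", "block4.conv1", "block4.conv2", "down3",
             "block5.conv1", "block5.conv2", "block6.conv1", "block6.conv2",
             "tap0_proj", "up1.1", "up2.1", "up2.2", "up3.1", "up3.2",
             "up3.3", "head"),
    kind = c(rep("conv", 17), "conv", rep("deconv", 6), "conv"),
    stride = c(1, 1, 2, 1, 1, 1, 1, 2, 1, 1, 1, 1, 2, 1, 1, 1, 1,
               rep(1, 8)),
    counted = TRUE
  )
}

#' Layer count of an instantiated network
#'
#' Counts the volumetric convolution/deconvolution layers of the trunk,
#' upsampling paths and segmentation head under the documented rule (1x1x1
#' convolutions inside attention blocks are excluded).
#'
#' @param model A [new_base_model()] or [new_two_path_model()].
#' @return A list with `n_conv`, `n_deconv`, `total` and the layer table.
#' @export
count_layers <- function(model) {
  tab <- if (inherits(model, "two_path_model")) {
    rbind(model$path_flair$layer_table, model$path_t1$layer_table,
          tibble::tibble(name = "fusion_head", kind = "conv", stride = 1,
                         counted = TRUE))
  } else {
    model$layer_table
  }
  list(n_conv = sum(tab$kind == "conv" & tab$counted),
       n_deconv = sum(tab$kind == "deconv" & tab$counted),
       total = sum(tab$counted),
       table = tab)
}

# Recursively collect ad_param stores (and, separately, BN state envs).
collect_params <- function(x, path = "") {
  if (inherits(x, "ad_param")) {
    out <- list(x)
    names(out) <- path
    return(out)
  }
  if (is.environment(x)) {
    l <- as.list(x)
    x <- l[sort(names(l))] # deterministic traversal order
  }
  if (!is.list(x)) return(list())
  nms <- names(x) %||% rep("", length(x))
  nms[nms == ""] <- as.character(which(nms == ""))
  out <- list()
  for (i in seq_along(x)) {
    if (nms[i] %in% c("cfg", "layer_table", "running_mean", "running_var",
                      "momentum", "eps", "kernel", "channels", "order")) next
    out <- c(out, collect_params(x[[i]], paste0(path, ".", nms[i])))
  }
  out
}

collect_bn <- function(x, path = "") {
  if (is.environment(x) && !inherits(x, "ad_param")) {
    out <- list(x)
    names(out) <- path
    return(out)
  }
  if (!is.list(x) || inherits(x, "ad_param")) return(list())
  nms <- names(x) %||% rep("", length(x))
  nms[nms == ""] <- as.character(which(nms == ""))
  out <- list()
  for (i in seq_along(x)) {
    if (nms[i] %in% c("cfg", "layer_table")) next
    it <- x[[i]]
    if (is.environment(it) && !inherits(it, "ad_param")) {
      o <- list(it)
      names(o) <- paste0(path, ".", nms[i])
      out <- c(out, o)
    } else if (is.list(it)) {
      out <- c(out, collect_bn(it, paste0(path, ".", nms[i])))
    }
  }
  out
}

#' Number of learnable parameters
#'
#' @param model A model or attention block.
#' @return Integer count of scalar parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$v), numeric(1)))
}

check_divisible <- function(sp, by = 8L) {
  if (any(sp %% by != 0L)) {
    stop("spatial dims (", paste(sp, collapse = "x"), ") must be divisible ",
         "by ", by, " (three stride-2 stages); pad or crop the patch")
  }
}

fwd_base <- function(tape, model, x, training = FALSE) {
  cfg <- model$cfg
  pad <- cfg$kernel %/% 2L
  h <- op_conv3(tape, x, model$stem1$w, model$stem1$b, 1L, pad, cfg$kernel)
  h <- op_relu(tape, op_bn(tape, h, model$bn1, training))
  t0 <- op_relu(tape, op_conv3(tape, h, model$stem2$w, model$stem2$b, 1L, pad,
                               cfg$kernel))
  h <- op_conv3(tape, t0, model$down[[1]]$conv$w, model$down[[1]]$conv$b, 2L,
                pad, cfg$kernel)
  h <- op_relu(tape, op_bn(tape, h, model$down[[1]]$bn, training))
  h <- fwd_sca_voxres(tape, h, model$blocks[[1]], cfg, training)
  t1 <- fwd_sca_voxres(tape, h, model$blocks[[2]], cfg, training)
  h <- op_conv3(tape, t1, model$down[[2]]$conv$w, model$down[[2]]$conv$b, 2L,
                pad, cfg$kernel)
  h <- op_relu(tape, op_bn(tape, h, model$down[[2]]$bn, training))
  h <- fwd_sca_voxres(tape, h, model$blocks[[3]], cfg, training)
  t2 <- fwd_sca_voxres(tape, h, model$blocks[[4]], cfg, training)
  h <- op_conv3(tape, t2, model$down[[3]]$conv$w, model$down[[3]]$conv$b, 2L,
                pad, cfg$kernel)
  h <- op_relu(tape, op_bn(tape, h, model$down[[3]]$bn, training))
  h <- fwd_sca_voxres(tape, h, model$blocks[[5]], cfg, training)
  t3 <- fwd_sca_voxres(tape, h, model$blocks[[6]], cfg, training)
  u0 <- op_conv1(tape, t0, model$tap0_proj$w, model$tap0_proj$b)
  u1 <- op_deconv2(tape, t1, model$up1[[1]]$w, model$up1[[1]]$b,
                   cfg$tap_channels[2])
  u2 <- op_deconv2(tape, t2, model$up2[[1]]$w, model$up2[[1]]$b,
                   cfg$body_channels)
  u2 <- op_deconv2(tape, u2, model$up2[[2]]$w, model$up2[[2]]$b,
                   cfg$tap_channels[3])
  u3 <- op_deconv2(tape, t3, model$up3[[1]]$w, model$up3[[1]]$b,
                   cfg$body_channels)
  u3 <- op_deconv2(tape, u3, model$up3[[2]]$w, model$up3[[2]]$b,
                   cfg$body_channels)
  u3 <- op_deconv2(tape, u3, model$up3[[3]]$w, model$up3[[3]]$b,
                   cfg$tap_channels[4])
  op_concat_ch(tape, list(u0, u1, u2, u3))
}

#' Fused multi-scale features of the base model
#'
#' Runs the trunk and upsampling paths, returning the full-resolution fused
#' feature map (224 channels for the default configuration).
#'
#' @param model A [new_base_model()].
#' @param x Input array `(in_channels, D, H, W)` with spatial dims divisible
#'   by 8.
#' @param training Use batch statistics in BN layers.
#' @return Array `(fused_channels, D, H, W)`.
#' @export
base_forward <- function(model, x, training = FALSE) {
  check_divisible(dim(x)[-1], 8L)
  fwd_base(NULL, model, ad_node(NULL, x), training)$v
}

fwd_head <- function(tape, model, feat) {
  op_softmax_ch(tape, op_conv1(tape, feat, model$head$w, model$head$b))
}

#' Segmentation head
#'
#' 1x1x1 convolution to class logits followed by a voxelwise softmax.
#'
#' @param model The model owning the head weights.
#' @param features Fused feature array from [base_forward()].
#' @return Array `(n_classes, D, H, W)` of per-voxel class probabilities.
#' @export
segment_head <- function(model, features) {
  fwd_head(NULL, model, ad_node(NULL, features))$v
}

#' Single-path forward pass to class probabilities
#'
#' @inheritParams base_forward
#' @return Array `(n_classes, D, H, W)`; probabilities sum to 1 per voxel.
#' @export
model_forward <- function(model, x, training = FALSE) {
  check_divisible(dim(x)[-1], 8L)
  fwd_head(NULL, model, fwd_base(NULL, model, ad_node(NULL, x), training))$v
}

#' Instantiate the two-path decision-level fusion network
#'
#' Two independent base models (no weight sharing) extract 224-channel
#' feature maps from the FLAIR and T1-weighted inputs; the maps concatenate
#' to 448 channels and a single 1x1x1 convolution + softmax classifies.
#'
#' @param cfg A [model_config()] (shared by both paths).
#' @param seed Optional seed for weight initialisation.
#' @return An object of class `two_path_model`.
#' @export
new_two_path_model <- function(cfg = model_config(), seed = NULL) {
  build <- function() {
    m <- list(cfg = cfg,
              path_flair = new_base_model(cfg),
              path_t1 = new_base_model(cfg),
              fusion_head = new_conv1_params(2L * cfg$fused_channels,
                                             cfg$n_classes))
    class(m) <- "two_path_model"
    m
  }
  if (!is.null(seed)) withr::with_seed(seed, build()) else build()
}

fwd_two_path <- function(tape, model, xf, xt, training = FALSE) {
  ff <- fwd_base(tape, model$path_flair, xf, training)
  ft <- fwd_base(tape, model$path_t1, xt, training)
  fused <- op_concat_ch(tape, list(ff, ft))
  op_softmax_ch(tape, op_conv1(tape, fused, model$fusion_head$w,
                               model$fusion_head$b))
}

#' Two-path forward pass to class probabilities
#'
#' @param model A [new_two_path_model()].
#' @param flair_patch,t1_patch Spatially congruent `(2, D, H, W)` arrays.
#' @param training Use batch statistics in BN layers.
#' @return Array `(n_classes, D, H, W)` of per-voxel probabilities.
#' @export
two_path_forward <- function(model, flair_patch, t1_patch, training = FALSE) {
  if (!identical(dim(flair_patch), dim(t1_patch))) {
    stop("FLAIR and T1 patches must have identical shapes")
  }
  check_divisible(dim(flair_patch)[-1], 8L)
  fwd_two_path(NULL, model, ad_node(NULL, flair_patch),
               ad_node(NULL, t1_patch), training)$v
}

# Dispatch: forward producing the probability node for training/inference.
fwd_model <- function(tape, model, inputs, training = FALSE) {
  if (inherits(model, "two_path_model")) {
    fwd_two_path(tape, model, ad_node(tape, inputs[[1]]),
                 ad_node(tape, inputs[[2]]), training)
  } else {
    fwd_head(tape, model, fwd_base(tape, model, ad_node(tape, inputs[[1]]),
                                   training))
  }
}

# ---- checkpoints ------------------------------------------------------------

#' Save model weights (and optionally optimizer state) to a checkpoint
#'
#' The configuration is embedded so [load_checkpoint()] can rebuild the
#' model without further information. Saving a freshly loaded checkpoint is
#' a fixed point.
#'
#' @param model A base or two-path model.
#' @param path Output file.
#' @param optimizer Optional Adam state (from training) to embed for
#'   resuming.
#' @export
save_checkpoint <- function(model, path, optimizer = NULL) {
  params <- collect_params(model)
  bns <- collect_bn(model)
  ck <- list(
    type = class(model)[1],
    cfg = model$cfg,
    values = lapply(params, function(p) p$v),
    adam = lapply(params, function(p) list(m = p$m, u = p$u)),
    bn = lapply(bns, function(b) list(running_mean = b$running_mean,
                                      running_var = b$running_var)),
    opt_t = if (!is.null(optimizer)) optimizer$t else NULL
  )
  saveRDS(ck, path)
  invisible(path)
}

#' Load a model from a checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return The reconstructed model; if optimizer state was saved, it is
#'   attached as attribute `"adam_t"`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- if (ck$type == "two_path_model") {
    new_two_path_model(ck$cfg, seed = 0L)
  } else {
    new_base_model(ck$cfg, seed = 0L)
  }
  params <- collect_params(model)
  stopifnot(identical(names(params), names(ck$values)))
  for (nm in names(params)) {
    params[[nm]]$v <- ck$values[[nm]]
    params[[nm]]$m <- ck$adam[[nm]]$m
    params[[nm]]$u <- ck$adam[[nm]]$u
    params[[nm]]$g <- params[[nm]]$v * 0
  }
  bns <- collect_bn(model)
  for (nm in names(bns)) {
    bns[[nm]]$running_mean <- ck$bn[[nm]]$running_mean
    bns[[nm]]$running_var <- ck$bn[[nm]]$running_var
  }
  if (!is.null(ck$opt_t)) attr(model, "adam_t") <- ck$opt_t
  model
}
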