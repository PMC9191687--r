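# Minimal reverse-mode tape used by the volumetric network.
#
# A "node" is an environment holding the forward value ($v), the accumulated
# upstream gradient ($g) and a backward closure ($bw) that pushes gradients
# into parent nodes / parameter stores. Ops record nodes on a tape in creation
# order; ad_backward() replays the tape in reverse. With tape = NULL the same
# ops run in pure inference mode (no closures, no caches).
#
# Parameters are persistent environments (ad_param) holding value, gradient
# and Adam state; op backward closures accumulate straight into them.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$k <- 0L
  t
}

ad_node <- function(tape, value, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$bw <- bw
  if (!is.null(tape)) {
    if (tape$k == length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$k <- tape$k + 1L
    tape$nodes[[tape$k]] <- nd
  }
  nd
}

ad_accum <- function(nd, g) {
  nd$g <- if (is.null(nd$g)) g else nd$g + g
  invisible(NULL)
}

#' @noRd
ad_backward <- function(tape, root, seed_grad = 1) {
  root$g <- seed_grad
  for (i in rev(seq_len(tape$k))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd$g)
    nd$bw <- NULL # release closures/caches as we go
  }
  invisible(NULL)
}

# Persistent parameter store: value, gradient accumulator, Adam moments.
ad_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$v <- value
  p$g <- value * 0 # same shape (and dim attributes) as the value
  p$m <- NULL
  p$u <- NULL
  class(p) <- "ad_param"
  p
}

ad_zero_grad <- function(params) {
  for (p in params) p$g[] <- 0
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- elementwise / structural ops -------------------------------------------

op_add <- function(tape, a, b) {
  out <- ad_node(tape, a$v + b$v)
  if (!is.null(tape)) out$bw <- function(g) { ad_accum(a, g); ad_accum(b, g) }
  out
}

op_relu <- function(tape, a) {
  keep <- a$v > 0
  out <- ad_node(tape, a$v * keep)
  if (!is.null(tape)) out$bw <- function(g) ad_accum(a, g * keep)
  out
}

op_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$v))
  out <- ad_node(tape, s)
  if (!is.null(tape)) out$bw <- function(g) ad_accum(a, g * s * (1 - s))
  out
}

# y = omega * x with omega a scalar learnable parameter (Eq.-style residual
# weight of the spatial attention).
op_wscale <- function(tape, a, omega) {
  out <- ad_node(tape, omega$v * a$v)
  if (!is.null(tape)) {
    av <- a$v
    out$bw <- function(g) {
      omega$g <- omega$g + sum(g * av)
      ad_accum(a, omega$v * g)
    }
  }
  out
}

op_reshape <- function(tape, a, dims) {
  v <- a$v
  olddim <- dim(v) %||% length(v)
  dim(v) <- dims
  out <- ad_node(tape, v)
  if (!is.null(tape)) out$bw <- function(g) { dim(g) <- olddim; ad_accum(a, g) }
  out
}

# Concatenate (C_i, D, H, W) feature maps along the channel axis.
op_concat_ch <- function(tape, nodes) {
  chs <- vapply(nodes, function(n) dim(n$v)[1], integer(1))
  sp <- dim(nodes[[1]]$v)[-1]
  tot <- sum(chs)
  v <- array(0, dim = c(tot, sp))
  vm <- matrix(v, nrow = tot)
  at <- 0L
  for (i in seq_along(nodes)) {
    vm[(at + 1):(at + chs[i]), ] <- matrix(nodes[[i]]$v, nrow = chs[i])
    at <- at + chs[i]
  }
  out <- ad_node(tape, array(vm, dim = c(tot, sp)))
  if (!is.null(tape)) {
    out$bw <- function(g) {
      gm <- matrix(g, nrow = tot)
      at <- 0L
      for (i in seq_along(nodes)) {
        gi <- gm[(at + 1):(at + chs[i]), , drop = FALSE]
        ad_accum(nodes[[i]], array(gi, dim = c(chs[i], sp)))
        at <- at + chs[i]
      }
    }
  }
  out
}

# ---- convolutions -----------------------------------------------------------

# 3D convolution, weight stored as a (C_out) x (C_in * k^3) matrix whose
# column index is c_in + C_in * kernel_offset (matching .im2col3 rows).
op_conv3 <- function(tape, a, w, b, stride = 1L, pad = 1L, kernel = 3L) {
  dm <- dim(a$v)
  C <- dm[1]; D <- dm[2]; H <- dm[3]; W <- dm[4]
  cols <- .im2col3(as.numeric(a$v), C, D, H, W, kernel, kernel, kernel, stride, pad)
  y <- w$v %*% cols
  y <- y + b$v # b recycles down columns (per-output-channel bias)
  Do <- (D + 2 * pad - kernel) %/% stride + 1
  Ho <- (H + 2 * pad - kernel) %/% stride + 1
  Wo <- (W + 2 * pad - kernel) %/% stride + 1
  out <- ad_node(tape, array(y, dim = c(nrow(w$v), Do, Ho, Wo)))
  if (!is.null(tape)) {
    out$bw <- function(g) {
      gm <- matrix(g, nrow = nrow(w$v))
      w$g <- w$g + tcrossprod(gm, cols)
      b$g <- b$g + rowSums(gm)
      dx <- .col2im3(crossprod(w$v, gm), C, D, H, W, kernel, kernel, kernel, stride, pad)
      ad_accum(a, array(dx, dim = dm))
    }
  }
  out
}

# 1x1x1 convolution: a channel-mixing matrix multiply.
op_conv1 <- function(tape, a, w, b) {
  dm <- dim(a$v)
  xm <- matrix(a$v, nrow = dm[1])
  y <- w$v %*% xm + b$v
  out <- ad_node(tape, array(y, dim = c(nrow(w$v), dm[-1])))
  if (!is.null(tape)) {
    out$bw <- function(g) {
      gm <- matrix(g, nrow = nrow(w$v))
      w$g <- w$g + tcrossprod(gm, xm)
      b$g <- b$g + rowSums(gm)
      ad_accum(a, array(crossprod(w$v, gm), dim = dm))
    }
  }
  out
}

# Transposed convolution, kernel 2 stride 2 (non-overlapping upsampling).
# Weight is a (C_out * 8) x (C_in) matrix, row index c_out + C_out * k with
# k = kx + 2*(ky + 2*kz); the 8 kernel offsets scatter to disjoint outputs,
# so forward is a GEMM followed by an index permutation.
op_deconv2 <- function(tape, a, w, b, c_out) {
  dm <- dim(a$v)
  C <- dm[1]; D <- dm[2]; H <- dm[3]; W <- dm[4]
  xm <- matrix(a$v, nrow = C)
  y8 <- w$v %*% xm # (c_out*8) x (D*H*W)
  y <- array(y8, dim = c(c_out, 2, 2, 2, D, H, W))
  y <- aperm(y, c(1, 2, 5, 3, 6, 4, 7))
  dim(y) <- c(c_out, 2 * D, 2 * H, 2 * W)
  y <- y + b$v
  out <- ad_node(tape, y)
  if (!is.null(tape)) {
    out$bw <- function(g) {
      b$g <- b$g + rowSums(matrix(g, nrow = c_out))
      dim(g) <- c(c_out, 2, D, 2, H, 2, W)
      g8 <- aperm(g, c(1, 2, 4, 6, 3, 5, 7))
      g8 <- matrix(g8, nrow = c_out * 8)
      w$g <- w$g + tcrossprod(g8, xm)
      ad_accum(a, array(crossprod(w$v, g8), dim = dm))
    }
  }
  out
}

# ---- batch normalisation ----------------------------------------------------

# Per-channel batch norm over the spatial grid of one patch. bn is an
# environment with gamma/beta parameters and running moments for inference.
op_bn <- function(tape, a, bn, training = FALSE) {
  dm <- dim(a$v)
  C <- dm[1]
  xm <- matrix(a$v, nrow = C)
  n <- ncol(xm)
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    va <- rowMeans(xc * xc)
    bn$running_mean <- (1 - bn$momentum) * bn$running_mean + bn$momentum * mu
    bn$running_var <- (1 - bn$momentum) * bn$running_var +
      bn$momentum * va * n / max(n - 1, 1)
  } else {
    mu <- bn$running_mean
    xc <- xm - mu
    va <- bn$running_var
  }
  invstd <- 1 / sqrt(va + bn$eps)
  xhat <- xc * invstd
  y <- xhat * bn$gamma$v + bn$beta$v
  out <- ad_node(tape, array(y, dim = dm))
  if (!is.null(tape)) {
    out$bw <- function(g) {
      gm <- matrix(g, nrow = C)
      bn$gamma$g <- bn$gamma$g + rowSums(gm * xhat)
      bn$beta$g <- bn$beta$g + rowSums(gm)
      if (training) {
        s1 <- rowSums(gm)
        s2 <- rowSums(gm * xhat)
        dx <- (bn$gamma$v * invstd) * (gm - s1 / n - xhat * s2 / n)
      } else {
        dx <- (bn$gamma$v * invstd) * gm
      }
      ad_accum(a, array(dx, dim = dm))
    }
  }
  out
}

new_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  bn <- new.env(parent = emptyenv())
  bn$gamma <- ad_param(rep(1, channels))
  bn$beta <- ad_param(rep(0, channels))
  bn$running_mean <- rep(0, channels)
  bn$running_var <- rep(1, channels)
  bn$momentum <- momentum
  bn$eps <- eps
  bn
}

# ---- pooling / upsampling ---------------------------------------------------

# Average-pool a (C, D, H, W) map by integer factor f along each spatial axis
# (dims must be divisible by f; the network only pools power-of-two grids).
op_avgpool <- function(tape, a, f) {
  if (f == 1) return(a)
  dm <- dim(a$v)
  C <- dm[1]; Db <- dm[2] %/% f; Hb <- dm[3] %/% f; Wb <- dm[4] %/% f
  v <- a$v
  dim(v) <- c(C, f, Db, f, Hb, f, Wb)
  v <- aperm(v, c(1, 3, 5, 7, 2, 4, 6))
  dim(v) <- c(C * Db * Hb * Wb, f^3)
  pooled <- array(rowMeans(v), dim = c(C, Db, Hb, Wb))
  out <- ad_node(tape, pooled)
  if (!is.null(tape)) {
    out$bw <- function(g) {
      gg <- g[, rep(seq_len(Db), each = f), rep(seq_len(Hb), each = f),
              rep(seq_len(Wb), each = f), drop = FALSE] / f^3
      ad_accum(a, gg)
    }
  }
  out
}

# Nearest-neighbour upsample by integer factor f along each spatial axis.
op_upnearest <- function(tape, a, f) {
  if (f == 1) return(a)
  dm <- dim(a$v)
  C <- dm[1]; Db <- dm[2]; Hb <- dm[3]; Wb <- dm[4]
  up <- a$v[, rep(seq_len(Db), each = f), rep(seq_len(Hb), each = f),
            rep(seq_len(Wb), each = f), drop = FALSE]
  out <- ad_node(tape, up)
  if (!is.null(tape)) {
    out$bw <- function(g) {
      dim(g) <- c(C, f, Db, f, Hb, f, Wb)
      g <- aperm(g, c(1, 3, 5, 7, 2, 4, 6))
      dim(g) <- c(C * Db * Hb * Wb, f^3)
      ad_accum(a, array(rowSums(g), dim = dm))
    }
  }
  out
}

# ---- vector heads (channel attention) ---------------------------------------

# Global average pool: (C, D, H, W) -> length-C vector.
op_gap <- function(tape, a) {
  dm <- dim(a$v)
  C <- dm[1]
  n <- prod(dm[-1])
  out <- ad_node(tape, rowMeans(matrix(a$v, nrow = C)))
  if (!is.null(tape)) {
    out$bw <- function(g) {
      ad_accum(a, array(rep(g / n, n), dim = dm))
    }
  }
  out
}

op_fc <- function(tape, a, w, b) {
  out <- ad_node(tape, as.numeric(w$v %*% a$v + b$v))
  if (!is.null(tape)) {
    av <- a$v
    out$bw <- function(g) {
      w$g <- w$g + g %o% av
      b$g <- b$g + g
      ad_accum(a, as.numeric(crossprod(w$v, g)))
    }
  }
  out
}

# Scale channel c of x by s[c] (the channel-attention gating).
op_scale_ch <- function(tape, a, s) {
  dm <- dim(a$v)
  C <- dm[1]
  out <- ad_node(tape, a$v * s$v) # s recycles along the channel (first) axis
  if (!is.null(tape)) {
    av <- a$v
    out$bw <- function(g) {
      ad_accum(s, rowSums(matrix(g * av, nrow = C)))
      ad_accum(a, g * s$v)
    }
  }
  out
}

# ---- matrix ops (spatial attention) -----------------------------------------

op_matmul <- function(tape, a, b) {
  out <- ad_node(tape, a$v %*% b$v)
  if (!is.null(tape)) {
    out$bw <- function(g) {
      ad_accum(a, tcrossprod(g, b$v))
      ad_accum(b, crossprod(a$v, g))
    }
  }
  out
}

# y = A %*% t(B)
op_matmul_nt <- function(tape, a, b) {
  out <- ad_node(tape, tcrossprod(a$v, b$v))
  if (!is.null(tape)) {
    out$bw <- function(g) {
      ad_accum(a, g %*% b$v)
      ad_accum(b, crossprod(g, a$v))
    }
  }
  out
}

op_transpose <- function(tape, a) {
  out <- ad_node(tape, t(a$v))
  if (!is.null(tape)) out$bw <- function(g) ad_accum(a, t(g))
  out
}

# Row-wise softmax of a matrix; every row of the result sums to 1.
op_rowsoftmax <- function(tape, a) {
  x <- a$v
  x <- x - apply(x, 1, max)
  e <- exp(x)
  p <- e / rowSums(e)
  out <- ad_node(tape, p)
  if (!is.null(tape)) {
    out$bw <- function(g) {
      ad_accum(a, p * (g - rowSums(g * p)))
    }
  }
  out
}

# Voxelwise softmax over the channel (first) axis of a (C, D, H, W) map.
op_softmax_ch <- function(tape, a) {
  dm <- dim(a$v)
  C <- dm[1]
  xm <- matrix(a$v, nrow = C)
  mx <- xm[1, ]
  if (C > 1) for (c in 2:C) mx <- pmax(mx, xm[c, ])
  e <- exp(sweep(xm, 2, mx))
  p <- sweep(e, 2, colSums(e), "/")
  out <- ad_node(tape, array(p, dim = dm))
  if (!is.null(tape)) {
    out$bw <- function(g) {
      gm <- matrix(g, nrow = C)
      dot <- colSums(gm * p)
      ad_accum(a, array(p * sweep(gm, 2, dot), dim = dm))
    }
  }
  out
}

# ---- loss node --------------------------------------------------------------

# Focal Tversky loss on a (n_classes, ...) probability node against a one-hot
# ground truth array of the same shape. Closed-form gradient (see losses.R
# for the reference forward implementation used in tests).
op_focal_tversky <- function(tape, a, g_onehot, params) {
  p <- a$v
  C <- dim(p)[1]
  pm <- matrix(p, nrow = C)
  gm <- matrix(g_onehot, nrow = C)
  eps <- params$epsilon
  loss <- 0
  dL <- matrix(0, nrow = C, ncol = ncol(pm))
  for (c in seq_len(C)) {
    pc <- pm[c, ]; gc <- gm[c, ]
    P <- sum(pc * gc)
    FN <- sum((1 - pc) * gc)
    FP <- sum(pc * (1 - gc))
    Q <- P + params$alpha * FN + params$beta * FP
    TI <- (P + eps) / (Q + eps)
    loss <- loss + (1 - TI)^params$gamma
    if (!is.null(tape)) {
      # dTI/dp_ic = (g_ic*(Q+eps) - (P+eps)*(g_ic - alpha*g_ic + beta*(1-g_ic))) / (Q+eps)^2
      dQ <- gc - params$alpha * gc + params$beta * (1 - gc)
      dTI <- (gc * (Q + eps) - (P + eps) * dQ) / (Q + eps)^2
      dL[c, ] <- -params$gamma * (1 - TI)^(params$gamma - 1) * dTI
    }
  }
  out <- ad_node(tape, loss)
  if (!is.null(tape)) {
    out$bw <- function(g) ad_accum(a, array(g * dL, dim = dim(p)))
  }
  out
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function() {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st
}

adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (p in params) {
    if (is.null(p$m)) {
      p$m <- p$g * 0
      p$u <- p$g * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * p$g
    p$u <- beta2 * p$u + (1 - beta2) * p$g^2
    p$v <- p$v - lr * (p$m / bc1) / (sqrt(p$u / bc2) + eps)
  }
  invisible(NULL)
}
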