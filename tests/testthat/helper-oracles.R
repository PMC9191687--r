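# Independent oracles used across the suite. These deliberately avoid the
# package's own fast paths: components by pure-R flood fill, histogram
# equalization by direct CDF lookup, gradients by central differences.

# Pure-R flood fill labelling under a given neighbourhood offset set.
flood_fill_label <- function(mask, offsets) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nxt <- 0L
  idx_ok <- function(v) all(v >= 1L) && all(v <= dm)
  for (s in which(mask != 0)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- list(arrayInd(s, dm)[1, ])
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (o in offsets) {
        u <- v + o
        if (!idx_ok(u)) next
        if (mask[u[1], u[2], u[3]] != 0 && lab[u[1], u[2], u[3]] == 0L) {
          lab[u[1], u[2], u[3]] <- nxt
          queue[[length(queue) + 1L]] <- u
        }
      }
    }
  }
  attr(lab, "n_components") <- nxt
  lab
}

offsets_18 <- local({
  out <- list()
  for (dd in -1:1) for (dh in -1:1) for (dw in -1:1) {
    nz <- sum(c(dd, dh, dw) != 0)
    if (nz == 1 || nz == 2) out[[length(out) + 1L]] <- c(dd, dh, dw)
  }
  out
})

offsets_26 <- local({
  out <- list()
  for (dd in -1:1) for (dh in -1:1) for (dw in -1:1) {
    if (any(c(dd, dh, dw) != 0)) out[[length(out) + 1L]] <- c(dd, dh, dw)
  }
  out
})

# Lesion-wise rates by brute-force pairwise overlap of labelled components.
oracle_lesion_rates <- function(pred, gt) {
  lg <- flood_fill_label(gt, offsets_18)
  lp <- flood_fill_label(pred, offsets_18)
  ng <- attr(lg, "n_components")
  np <- attr(lp, "n_components")
  hit_gt <- if (ng > 0) {
    sum(vapply(seq_len(ng), function(i) any(pred[lg == i] != 0), logical(1)))
  } else 0L
  fp_pred <- if (np > 0) {
    sum(vapply(seq_len(np), function(i) all(gt[lp == i] == 0), logical(1)))
  } else 0L
  list(
    ltpr = if (ng == 0) 1 else hit_gt / ng,
    lfpr = if (np == 0) 0 else fp_pred / np,
    n_gt = ng, n_pred = np
  )
}

# Plain (global) histogram equalization by direct CDF lookup.
oracle_hist_eq <- function(x, bins = 256L) {
  b <- pmin(floor(x * bins), bins - 1L)
  h <- tabulate(b + 1L, nbins = bins)
  cdf <- cumsum(h) / sum(h)
  cdf[b + 1L]
}

# Central-difference gradient of f() w.r.t. a sample of entries of an
# ad_param store; returns max relative error against the analytic gradient.
grad_check <- function(param, forward_loss, analytic, n = 6L, eps = 1e-6) {
  idx <- sample(length(param$v), min(n, length(param$v)))
  worst <- 0
  for (i in idx) {
    v0 <- param$v[i]
    param$v[i] <- v0 + eps
    lp <- forward_loss()
    param$v[i] <- v0 - eps
    lm <- forward_loss()
    param$v[i] <- v0
    fd <- (lp - lm) / (2 * eps)
    # the floor absorbs finite-difference noise when a gradient is exactly
    # cancelled (e.g. a bias followed by batch-norm mean subtraction)
    denom <- max(1e-2, abs(fd) + abs(analytic[i]))
    worst <- max(worst, abs(fd - analytic[i]) / denom)
  }
  worst
}

# Small deterministic phantom reused by several files.
test_phantom <- function(shape = 32L, n_lesions = 2L, seed = 42L) {
  make_phantom(phantom_spec(shape = rep(shape, 3), n_lesions = n_lesions,
                            lesion_radius_range = c(3, 5), seed = seed))
}

random_mask <- function(dm = c(20L, 20L, 20L), p = 0.06) {
  array(as.integer(stats::runif(prod(dm)) < p), dm)
}
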