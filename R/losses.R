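#' Tversky / Focal Tversky loss parameters
#'
#' `alpha` weights false negatives and `beta` false positives in the Tversky
#' index; with `alpha > beta` (default 0.7 / 0.3) the loss favours recall,
#' which is what a heavily imbalanced lesion/background problem needs.
#' `gamma` (default 4/3) is the focal exponent emphasising hard, small
#' regions; `epsilon` smooths the ratio so perfect/empty cases stay finite.
#'
#' @param alpha False-negative weight in `[0, 1]`.
#' @param beta False-positive weight in `[0, 1]`.
#' @param gamma Focal exponent (> 0).
#' @param epsilon Smoothing constant (> 0).
#' @return An object of class `loss_params`.
#' @export
loss_params <- function(alpha = 0.7, beta = 0.3, gamma = 4 / 3,
                        epsilon = 1e-5) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]")
  if (beta < 0 || beta > 1) stop("`beta` must be in [0, 1]")
  if (gamma <= 0) stop("`gamma` must be > 0")
  if (epsilon <= 0) stop("`epsilon` must be > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, epsilon = epsilon),
            class = "loss_params")
}

check_soft_pred <- function(p, g) {
  if (!identical(dim(p), dim(g))) {
    stop("prediction and ground truth shapes differ")
  }
  invisible(NULL)
}

#' Tversky index for one class
#'
#' `TI_c = (sum p_ic g_ic + eps) / (sum p_ic g_ic + alpha * sum (1-p_ic) g_ic
#' + beta * sum p_ic (1-g_ic) + eps)` — an asymmetric overlap between the
#' soft prediction and one-hot ground truth, weighting false negatives by
#' `alpha` and false positives by `beta`.
#'
#' @param p Array `(n_classes, ...)` of per-voxel class probabilities.
#' @param g One-hot ground truth array of the same shape.
#' @param class Class index (1-based into the first dimension).
#' @param params A [loss_params()].
#' @return Scalar in `[0, 1]`.
#' @export
tversky_index <- function(p, g, class = 2L, params = loss_params()) {
  check_soft_pred(p, g)
  pm <- matrix(p, nrow = dim(p)[1])
  gm <- matrix(g, nrow = dim(g)[1])
  pc <- pm[class, ]
  gc <- gm[class, ]
  P <- sum(pc * gc)
  FN <- sum((1 - pc) * gc)
  FP <- sum(pc * (1 - gc))
  (P + params$epsilon) /
    (P + params$alpha * FN + params$beta * FP + params$epsilon)
}

#' Focal Tversky loss
#'
#' `FTL = sum_c (1 - TI_c)^gamma`, summed over all classes (background and
#' lesion by default; set `classes` to restrict).
#'
#' @inheritParams tversky_index
#' @param classes Integer vector of class indices to sum over (default: all).
#' @return Scalar loss `>= 0`.
#' @export
focal_tversky_loss <- function(p, g, params = loss_params(),
                               classes = seq_len(dim(p)[1])) {
  if (params$gamma <= 0) stop("`gamma` must be > 0")
  check_soft_pred(p, g)
  sum(vapply(classes,
             function(c) (1 - tversky_index(p, g, c, params))^params$gamma,
             numeric(1)))
}

#' Tversky loss
#'
#' The focal Tversky loss with `gamma = 1`: `sum_c (1 - TI_c)`.
#'
#' @inheritParams focal_tversky_loss
#' @return Scalar loss.
#' @export
tversky_loss <- function(p, g, params = loss_params(),
                         classes = seq_len(dim(p)[1])) {
  params$gamma <- 1
  focal_tversky_loss(p, g, params, classes)
}

# One-hot encode a binary 3D label into (2, D, H, W): class 1 = background,
# class 2 = lesion.
one_hot <- function(label) {
  dm <- dim(label)
  g <- array(0, dim = c(2, dm))
  g[1, , , ] <- 1 - label
  g[2, , , ] <- label
  g
}
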