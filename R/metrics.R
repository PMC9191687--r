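#' 18-connected components of a binary mask
#'
#' Labels the connected components of a 3D binary mask under 18-connectivity
#' (face and edge neighbours connect; pure corner contacts do not), the
#' adjacency used for lesion-wise evaluation.
#'
#' @param mask A [lesion_mask()] or binary 3D array.
#' @return Integer 3D array of component labels (background 0), with
#'   attribute `"n_components"`.
#' @export
connected_components_18 <- function(mask) {
  mask <- as_lesion_mask(mask)
  dm <- dim(mask$data)
  lab <- .cc18_label(as.integer(mask$data), dm[1], dm[2], dm[3])
  n <- attr(lab, "n_components")
  lab <- array(lab, dim = dm)
  attr(lab, "n_components") <- n
  lab
}

check_pair <- function(pred, gt) {
  pred <- as_lesion_mask(pred)
  gt <- as_lesion_mask(gt)
  if (!identical(dim(pred$data), dim(gt$data))) {
    stop("prediction and ground-truth masks have different shapes")
  }
  list(pred = pred, gt = gt)
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |A intersect R| / (|A| + |R|)`; defined as 1 when both masks are
#' empty.
#'
#' @param pred Predicted binary mask.
#' @param gt Ground-truth binary mask.
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(pred, gt) {
  m <- check_pair(pred, gt)
  a <- sum(m$gt$data)
  r <- sum(m$pred$data)
  if (a + r == 0) return(1)
  2 * sum(m$pred$data * m$gt$data) / (a + r)
}

#' Lesion-wise true positive rate
#'
#' Fraction of ground-truth lesions (18-connected components) overlapped by
#' the prediction in at least one voxel. Defined as 1 when the ground truth
#' has no lesions.
#'
#' @inheritParams dsc
#' @return Scalar in `[0, 1]`.
#' @export
ltpr <- function(pred, gt) {
  m <- check_pair(pred, gt)
  lab <- connected_components_18(m$gt)
  n <- attr(lab, "n_components")
  if (n == 0) return(1)
  hit <- unique(lab[m$pred$data != 0 & lab != 0])
  length(hit) / n
}

#' Lesion-wise false positive rate
#'
#' Fraction of predicted lesions (18-connected components) with zero overlap
#' with the ground truth. Defined as 0 when the prediction has no lesions.
#'
#' @inheritParams dsc
#' @return Scalar in `[0, 1]`.
#' @export
lfpr <- function(pred, gt) {
  m <- check_pair(pred, gt)
  lab <- connected_components_18(m$pred)
  n <- attr(lab, "n_components")
  if (n == 0) return(0)
  hit <- unique(lab[m$gt$data != 0 & lab != 0])
  (n - length(hit)) / n
}

#' Absolute volume difference
#'
#' `AVD = | |R| - |A| | / |A|`, the absolute predicted-vs-true volume
#' discrepancy normalised by the ground-truth volume.
#'
#' @inheritParams dsc
#' @return Scalar `>= 0`.
#' @export
avd <- function(pred, gt) {
  m <- check_pair(pred, gt)
  a <- sum(m$gt$data)
  if (a == 0) stop("AVD is undefined for an empty ground-truth mask")
  abs(sum(m$pred$data) - a) / a
}

#' Full metrics report for one prediction / ground-truth pair
#'
#' @inheritParams dsc
#' @return A `metrics_report`: a one-row [tibble::tibble()] with columns
#'   `dsc`, `ltpr`, `lfpr`, `avd`, `n_components_pred`, `n_components_gt`,
#'   plus an attribute `"per_component_overlaps"` (tibble of ground-truth
#'   component id, size, and overlapping voxel count).
#' @export
evaluate_pair <- function(pred, gt) {
  m <- check_pair(pred, gt)
  lab_gt <- connected_components_18(m$gt)
  lab_pred <- connected_components_18(m$pred)
  n_gt <- attr(lab_gt, "n_components")
  n_pred <- attr(lab_pred, "n_components")
  overlaps <- if (n_gt > 0) {
    tibble::tibble(
      component = seq_len(n_gt),
      size = as.integer(tabulate(lab_gt[lab_gt != 0], nbins = n_gt)),
      overlap = as.integer(tabulate(lab_gt[lab_gt != 0 & m$pred$data != 0],
                                    nbins = n_gt))
    )
  } else {
    tibble::tibble(component = integer(0), size = integer(0),
                   overlap = integer(0))
  }
  rep <- tibble::tibble(
    dsc = dsc(m$pred, m$gt),
    ltpr = ltpr(m$pred, m$gt),
    lfpr = lfpr(m$pred, m$gt),
    avd = if (sum(m$gt$data) > 0) avd(m$pred, m$gt) else NA_real_,
    n_components_pred = n_pred,
    n_components_gt = n_gt
  )
  attr(rep, "per_component_overlaps") <- overlaps
  class(rep) <- c("metrics_report", class(rep))
  rep
}

#' Evaluate one prediction against two raters
#'
#' Computes the metrics report against each rater's ground truth and the
#' across-rater mean, mirroring evaluation on a dataset where every scan has
#' two manual delineations.
#'
#' @param pred Predicted binary mask.
#' @param gt1,gt2 The two rater masks.
#' @return A tibble with rows `rater1`, `rater2` and `mean`.
#' @export
evaluate_two_raters <- function(pred, gt1, gt2) {
  r1 <- evaluate_pair(pred, gt1)
  r2 <- evaluate_pair(pred, gt2)
  out <- rbind(as.data.frame(r1), as.data.frame(r2))
  means <- colMeans(out)
  out <- rbind(out, means)
  tibble::as_tibble(cbind(rater = c("rater1", "rater2", "mean"), out))
}

#' Write a metrics report to CSV
#'
#' @param report A `metrics_report` or the tibble from
#'   [evaluate_two_raters()].
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Read a metrics report back from CSV
#'
#' @param path CSV path written by [write_metrics_csv()].
#' @return A tibble.
#' @export
read_metrics_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
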