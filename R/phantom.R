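#' Phantom specification
#'
#' Parameters of the synthetic skull-stripped brain phantom: an ellipsoidal
#' brain support with a smooth tissue-intensity field, a configurable number
#' of bright superellipsoid lesions (FLAIR-hyperintense, mildly
#' T1-hypointense), additive Gaussian noise, and two rater masks derived
#' from the true lesion mask by independently flipping boundary voxels.
#'
#' @param shape Volume extent in voxels (default 96^3; 32^3 is convenient
#'   for unit-scale work).
#' @param n_lesions Number of lesions (>= 0).
#' @param lesion_radius_range Min/max lesion semi-axis in voxels.
#' @param lesion_intensity_offset Added FLAIR intensity inside lesions, in
#'   the arbitrary units of the tissue field (tissue mean 100, sd 10).
#' @param background_smoothness Gaussian smoothing sd (voxels) of the tissue
#'   field.
#' @param noise_sigma Additive Gaussian noise sd.
#' @param rater_disagreement Probability that a lesion-boundary voxel flips
#'   between raters, in `[0, 0.5]`.
#' @param seed Optional seed; phantoms are bit-identical given a seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L), n_lesions = 4L,
                         lesion_radius_range = c(3, 6),
                         lesion_intensity_offset = 40,
                         background_smoothness = 6, noise_sigma = 5,
                         rater_disagreement = 0.1, seed = NULL) {
  if (length(shape) == 1L) shape <- rep(shape, 3)
  shape <- as.integer(shape)
  if (any(shape < 8L)) stop("`shape` must be at least 8 voxels per axis")
  if (n_lesions < 0) stop("`n_lesions` must be >= 0")
  if (lesion_radius_range[1] < 1 ||
      2 * lesion_radius_range[2] >= min(shape)) {
    stop("lesion radii must be >= 1 voxel and fit inside the volume")
  }
  if (rater_disagreement < 0 || rater_disagreement > 0.5) {
    stop("`rater_disagreement` must be in [0, 0.5]")
  }
  structure(list(shape = shape, n_lesions = as.integer(n_lesions),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 lesion_intensity_offset = lesion_intensity_offset,
                 background_smoothness = background_smoothness,
                 noise_sigma = noise_sigma,
                 rater_disagreement = rater_disagreement, seed = seed),
            class = "phantom_spec")
}

# FFT-based circular Gaussian smoothing of a 3D field.
gaussian_smooth3 <- function(x, sigma) {
  dm <- dim(x)
  g1 <- function(n) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-d^2 / (2 * sigma^2))
    k / sum(k)
  }
  K <- outer(outer(g1(dm[1]), g1(dm[2])), g1(dm[3]))
  dim(K) <- dm
  Re(stats::fft(stats::fft(x) * stats::fft(K), inverse = TRUE)) / prod(dm)
}

# Binary 6-neighbour dilation by `r` voxel shells.
dilate6 <- function(mask, r = 1L) {
  out <- mask
  for (i in seq_len(r)) {
    acc <- out
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      acc <- acc | (shift3(out * 1, d) > 0)
    }
    out <- acc
  }
  out
}

#' Generate a synthetic brain phantom
#'
#' @param spec A [phantom_spec()].
#' @return A list with `flair` and `t1` ([raw_volume()]s sharing the brain
#'   mask), `rater1`, `rater2` and `truth` ([lesion_mask()]s). `truth`
#'   carries a `"lesions"` attribute tabulating each lesion's centre,
#'   semi-axes, superellipsoid exponent, analytic volume and voxel count.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  build <- function() {
    dm <- spec$shape
    ax <- lapply(1:3, function(a) (seq_len(dm[a]) - (dm[a] + 1) / 2))
    semi <- 0.45 * dm
    ell <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, "+"),
                 (ax[[3]] / semi[3])^2, "+")
    support <- ell <= 1

    field <- gaussian_smooth3(array(stats::rnorm(prod(dm)), dm),
                              spec$background_smoothness)
    field <- (field - mean(field)) / stats::sd(as.vector(field))
    tissue <- array(0, dm)
    tissue[support] <- 100 + 10 * field[support]

    truth <- array(0L, dm)
    occupied <- array(FALSE, dm) # lesions + 2-voxel separation shell
    rr <- spec$lesion_radius_range
    lesion_info <- list()
    if (spec$n_lesions > 0) {
      for (i in seq_len(spec$n_lesions)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          a <- stats::runif(3, rr[1], rr[2])
          p <- stats::runif(1, 1.6, 2.8) # superellipsoid exponent
          marg <- ceiling(max(a)) + 2L
          ctr <- vapply(1:3, function(k) {
            sample(seq(marg + 1L, dm[k] - marg), 1L)
          }, numeric(1))
          # lesion must sit inside the support with margin
          if (!support[ctr[1], ctr[2], ctr[3]]) next
          if (sum(((ctr - (dm + 1) / 2) / (0.9 * semi))^2) > 1) next
          bb <- lapply(1:3, function(k) {
            seq(max(1, ctr[k] - marg), min(dm[k], ctr[k] + marg))
          })
          d1 <- (abs(bb[[1]] - ctr[1]) / a[1])^p
          d2 <- (abs(bb[[2]] - ctr[2]) / a[2])^p
          d3 <- (abs(bb[[3]] - ctr[3]) / a[3])^p
          blob <- outer(outer(d1, d2, "+"), d3, "+") <= 1
          if (any(occupied[bb[[1]], bb[[2]], bb[[3]]] & blob)) next
          les <- array(FALSE, dm)
          les[bb[[1]], bb[[2]], bb[[3]]] <- blob
          les <- les & support
          if (sum(les) < 2) next
          truth[les] <- 1L
          occupied <- occupied | dilate6(les, 2L)
          # analytic superellipsoid volume: 8abc * Gamma(1+1/p)^3 / Gamma(1+3/p)
          lesion_info[[length(lesion_info) + 1L]] <- c(
            ctr, a, p,
            vol_analytic = 8 * prod(a) * gamma(1 + 1 / p)^3 / gamma(1 + 3 / p),
            vol_voxels = sum(les)
          )
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place lesion ", i,
               " without overlap after 200 attempts; reduce n_lesions or radii")
        }
      }
    }

    noise1 <- array(stats::rnorm(prod(dm), 0, spec$noise_sigma), dm)
    noise2 <- array(stats::rnorm(prod(dm), 0, spec$noise_sigma), dm)
    flair <- tissue + spec$lesion_intensity_offset * truth + noise1
    t1 <- tissue - 0.5 * spec$lesion_intensity_offset * truth + noise2
    flair[!support] <- 0
    t1[!support] <- 0

    flip_boundary <- function(truth) {
      inner <- truth == 1L & (dilate6(truth == 0L, 1L) & TRUE)
      outer_shell <- truth == 0L & dilate6(truth == 1L, 1L) & support
      boundary <- which(inner | outer_shell)
      if (length(boundary) == 0 || spec$rater_disagreement == 0) return(truth)
      flip <- boundary[stats::runif(length(boundary)) < spec$rater_disagreement]
      r <- truth
      r[flip] <- 1L - r[flip]
      r
    }
    rater1 <- flip_boundary(truth)
    rater2 <- flip_boundary(truth)

    bm <- array(as.integer(support), dm)
    lesions <- if (length(lesion_info)) {
      li <- do.call(rbind, lesion_info)
      colnames(li) <- c("d", "h", "w", "a1", "a2", "a3", "exponent",
                        "vol_analytic", "vol_voxels")
      tibble::as_tibble(li)
    } else {
      NULL
    }
    truth_mask <- lesion_mask(truth)
    attr(truth_mask, "lesions") <- lesions
    list(
      flair = raw_volume(flair, brain_mask = bm),
      t1 = raw_volume(t1, brain_mask = bm),
      rater1 = lesion_mask(rater1),
      rater2 = lesion_mask(rater2),
      truth = truth_mask
    )
  }
  if (!is.null(spec$seed)) withr::with_seed(spec$seed, build()) else build()
}

#' Hand-checkable mask fixtures for the lesion-wise metrics
#'
#' Small constructed prediction/ground-truth pairs whose metric values are
#' known by construction: an identical pair, a disjoint pair, a
#' 4-lesion ground truth with 3 detected plus 2 spurious predictions
#' (LTPR 0.75, LFPR 0.4), a face-touching voxel pair (one 18-connected
#' component) and a corner-touching pair (two components), and a volume
#' fixture with |gt| = 100, |pred| = 80, overlap 60 (DSC 2/3, AVD 0.2).
#'
#' @return Named list of fixtures; each has `pred`, `gt` and an `expected`
#'   list of metric values.
#' @export
make_worked_masks <- function() {
  z <- function() array(0L, c(20L, 20L, 20L))
  fx <- list()

  a <- z(); a[3:5, 3:5, 3:5] <- 1L
  fx$identical <- list(pred = lesion_mask(a), gt = lesion_mask(a),
                       expected = list(dsc = 1, ltpr = 1, lfpr = 0, avd = 0))

  b <- z(); b[10:12, 10:12, 10:12] <- 1L
  fx$disjoint <- list(pred = lesion_mask(b), gt = lesion_mask(a),
                      expected = list(dsc = 0, ltpr = 0, lfpr = 1))

  # ground truth: 4 separated 2^3 lesions; prediction overlaps 3 of them and
  # adds 2 spurious components (5 predicted in total)
  gt <- z()
  centers <- list(c(3, 3, 3), c(10, 3, 3), c(3, 10, 3), c(3, 3, 10))
  for (ct in centers) gt[ct[1] + 0:1, ct[2] + 0:1, ct[3] + 0:1] <- 1L
  pred <- z()
  for (ct in centers[1:3]) pred[ct[1] + 0:1, ct[2] + 0:1, ct[3] + 0:1] <- 1L
  pred[16:17, 16:17, 16:17] <- 1L
  pred[16:17, 3:4, 16:17] <- 1L
  fx$three_of_four_plus2 <- list(
    pred = lesion_mask(pred), gt = lesion_mask(gt),
    expected = list(ltpr = 0.75, lfpr = 0.4, n_pred = 5, n_gt = 4)
  )

  ft <- z(); ft[5, 5, 5] <- 1L; ft[6, 5, 5] <- 1L
  fx$face_touch <- list(pred = lesion_mask(ft), gt = lesion_mask(ft),
                        expected = list(n_components = 1))

  ct <- z(); ct[5, 5, 5] <- 1L; ct[6, 6, 6] <- 1L
  fx$corner_touch <- list(pred = lesion_mask(ct), gt = lesion_mask(ct),
                          expected = list(n_components = 2))

  gt2 <- z(); gt2[seq_len(100)] <- 1L # first 100 voxels (column-major)
  pr2 <- z(); pr2[seq_len(60)] <- 1L; pr2[101:120] <- 1L
  fx$volume_60_80_100 <- list(
    pred = lesion_mask(pr2), gt = lesion_mask(gt2),
    expected = list(dsc = 2 * 60 / 180, avd = 0.2)
  )

  fx
}
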