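#' Preprocessing configuration
#'
#' Parameters of the contrast-enhancement / edge-extraction stage that turns
#' a raw modality volume into the network's 2-channel representation.
#'
#' @param clahe_clip_limit Normalised CLAHE clip limit (> 0). Intensities are
#'   rescaled to `[0, 1]` first so the limit is unit-free; 0.01 bounds each
#'   histogram bin at 1% of the tile's voxel count.
#' @param clahe_tile_grid Number of CLAHE tiles per in-slice axis (>= 1);
#'   with a single tile the whole slice gets one clipped equalization map
#'   (no interpolation).
#' @param laplacian_mode `"full3d"` (6-neighbour stencil) or `"slice2d"`
#'   (per-axial-slice 4-neighbour stencil).
#' @param normalize_region Region over which z-normalisation statistics are
#'   taken: `"nonzero"` (default; skull-stripped background is zero),
#'   `"brain"` (requires a brain mask) or `"all"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(clahe_clip_limit = 0.01, clahe_tile_grid = 8L,
                              laplacian_mode = c("full3d", "slice2d"),
                              normalize_region = c("nonzero", "brain", "all")) {
  if (!is.numeric(clahe_clip_limit) || clahe_clip_limit <= 0) {
    stop("`clahe_clip_limit` must be > 0")
  }
  if (clahe_tile_grid < 1) stop("`clahe_tile_grid` must be >= 1")
  laplacian_mode <- match.arg(laplacian_mode)
  normalize_region <- match.arg(normalize_region)
  structure(list(clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 laplacian_mode = laplacian_mode,
                 normalize_region = normalize_region),
            class = "preprocess_config")
}

check_finite <- function(x, what = "volume") {
  nbad <- sum(!is.finite(x))
  if (nbad > 0) {
    stop(what, " contains ", nbad, " non-finite voxel(s)")
  }
  invisible(NULL)
}

#' Contrast-Limited Adaptive Histogram Equalization
#'
#' Rescales the volume to `[0, 1]` and equalises each axial slice with CLAHE
#' (a `tile_grid` x `tile_grid` tiling per slice, histogram clipped at the
#' configured limit). A constant volume has no contrast to equalise and is
#' returned unchanged. When a brain mask is attached, voxels outside it are
#' reset to zero afterwards so the skull-stripped background stays background.
#'
#' @param vol A [raw_volume()].
#' @param cfg A [preprocess_config()].
#' @return A [raw_volume()] with intensities in `[0, 1]`.
#' @export
apply_clahe <- function(vol, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "raw_volume"))
  check_finite(vol$data)
  rng <- range(vol$data)
  if (rng[1] == rng[2]) {
    return(vol) # degenerate: no contrast
  }
  x <- (vol$data - rng[1]) / (rng[2] - rng[1])
  bins <- 256L
  limit <- cfg$clahe_clip_limit * bins
  out <- x
  nz <- dim(x)[3]
  for (k in seq_len(nz)) {
    sl <- x[, , k]
    if (max(sl) > min(sl)) {
      out[, , k] <- if (cfg$clahe_tile_grid >= 2L) {
        EBImage::clahe(sl, nx = cfg$clahe_tile_grid, ny = cfg$clahe_tile_grid,
                       bins = bins, limit = limit)
      } else {
        clipped_hist_eq(sl, bins, cfg$clahe_clip_limit)
      }
    }
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (!is.null(vol$brain_mask)) out[vol$brain_mask == 0] <- 0
  raw_volume(out, spacing = vol$spacing, affine = vol$affine,
             brain_mask = vol$brain_mask)
}

# Single-tile CLAHE: contrast-limited equalization of the whole slice.
# Histogram counts are clipped at clip_limit * n and the excess redistributed
# uniformly before the CDF mapping (the one-tile case of the tiled method;
# monotone by construction).
clipped_hist_eq <- function(sl, bins, clip_limit) {
  b <- pmin(floor(sl * bins), bins - 1L)
  h <- tabulate(b + 1L, nbins = bins)
  n <- length(sl)
  clip <- max(1, clip_limit * n)
  excess <- sum(pmax(h - clip, 0))
  h <- pmin(h, clip) + excess / bins
  cdf <- cumsum(h) / sum(h)
  matrix(cdf[b + 1L], nrow = nrow(sl))
}

# Shift array by integer offset d (length 3) with edge replication: the
# vacated boundary takes the nearest in-volume value (Neumann condition), so
# the Laplacian of a constant volume is zero everywhere including the border.
shift3_clamp <- function(x, d) {
  dm <- dim(x)
  idx <- lapply(1:3, function(a) pmin(pmax(seq_len(dm[a]) - d[a], 1L), dm[a]))
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

shift3 <- function(x, d) {
  # shift array by integer offset d (length 3), zero-filling
  dm <- dim(x)
  out <- array(0, dm)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (d[a] >= 0) {
      src[[a]] <- seq_len(dm[a] - d[a])
      dst[[a]] <- src[[a]] + d[a]
    } else {
      src[[a]] <- seq_len(dm[a] + d[a]) - d[a]
      dst[[a]] <- seq_len(dm[a] + d[a])
    }
    if (dm[a] <= abs(d[a])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Laplacian edge map
#'
#' Discrete Laplacian response of the volume: in `"full3d"` mode the 3D
#' 6-neighbour stencil (centre weight -6), in `"slice2d"` mode the 2D
#' 4-neighbour stencil applied to each axial slice (centre weight -4).
#' Boundaries use edge replication, so a constant volume maps to an exactly
#' zero edge map everywhere.
#'
#' @inheritParams apply_clahe
#' @return A [raw_volume()] holding the edge response.
#' @export
laplacian_edges <- function(vol, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "raw_volume"))
  check_finite(vol$data)
  x <- vol$data
  offs <- switch(cfg$laplacian_mode,
    full3d = list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1)),
    slice2d = list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)),
    stop("unknown laplacian_mode: ", cfg$laplacian_mode)
  )
  out <- -length(offs) * x
  for (d in offs) out <- out + shift3_clamp(x, d)
  raw_volume(out, spacing = vol$spacing, affine = vol$affine,
             brain_mask = vol$brain_mask)
}

norm_region_idx <- function(vol, cfg) {
  switch(cfg$normalize_region,
    nonzero = vol$data != 0,
    brain = {
      if (is.null(vol$brain_mask)) {
        stop("normalize_region = \"brain\" requires a brain mask")
      }
      vol$brain_mask != 0
    },
    all = array(TRUE, dim(vol$data))
  )
}

#' Z-score normalisation
#'
#' Standardises voxels of the configured region to zero mean and unit
#' (population) variance; voxels outside the region are set to 0.
#'
#' @inheritParams apply_clahe
#' @return A [raw_volume()].
#' @export
zscore_normalize <- function(vol, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "raw_volume"))
  region <- norm_region_idx(vol, cfg)
  v <- vol$data[region]
  if (length(v) < 2) stop("normalisation region has fewer than 2 voxels")
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv == 0) stop("normalisation region has zero variance")
  out <- array(0, dim(vol$data))
  out[region] <- (v - mu) / sdv
  raw_volume(out, spacing = vol$spacing, affine = vol$affine,
             brain_mask = vol$brain_mask)
}

#' Build the 2-channel network input
#'
#' Channel 1 is the z-normalised CLAHE-enhanced intensity; channel 2 the
#' Laplacian edge map of the enhanced image. Spatial shape is preserved.
#'
#' @inheritParams apply_clahe
#' @return A [volume4d()].
#' @export
build_volume4d <- function(vol, cfg = preprocess_config()) {
  enh <- apply_clahe(vol, cfg)
  ch0 <- zscore_normalize(enh, cfg)
  ch1 <- laplacian_edges(enh, cfg)
  dm <- dim(vol$data)
  ch <- array(0, dim = c(2, dm))
  ch[1, , , ] <- ch0$data
  ch[2, , , ] <- ch1$data
  volume4d(ch, affine = vol$affine)
}
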