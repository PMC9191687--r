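#' Patch sampling specification
#'
#' @param size Integer length-3 patch extent in voxels (default `c(80,80,80)`,
#'   the size used for both training patches and inference tiles).
#' @param lesion_fraction Fraction of sampled training patches centred on a
#'   lesion voxel, in `[0, 1]` (default 0.6).
#' @param seed Optional integer seed making center sampling reproducible.
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(size = c(80L, 80L, 80L), lesion_fraction = 0.6,
                       seed = NULL) {
  if (length(size) == 1L) size <- rep(size, 3)
  size <- as.integer(size)
  if (length(size) != 3L || any(size < 1L)) stop("`size` must be 3 integers >= 1")
  if (lesion_fraction < 0 || lesion_fraction > 1) {
    stop("`lesion_fraction` must be in [0, 1]")
  }
  structure(list(size = size, lesion_fraction = lesion_fraction, seed = seed),
            class = "patch_spec")
}

#' Sample lesion-biased patch centers
#'
#' Draws exactly `round(n * lesion_fraction)` centers uniformly (with
#' replacement) from lesion voxels and the remainder uniformly from
#' non-lesion voxels.
#'
#' @param mask A [lesion_mask()] (or binary 3D array).
#' @param n Number of centers (>= 0).
#' @param spec A [patch_spec()].
#' @return An `n` x 3 integer matrix of 1-based voxel coordinates, with a
#'   logical attribute `"on_lesion"` flagging the lesion-centred rows.
#' @export
sample_centers <- function(mask, n, spec = patch_spec()) {
  mask <- as_lesion_mask(mask)
  n <- as.integer(n)
  if (n < 0) stop("`n` must be >= 0")
  dm <- dim(mask$data)
  if (n == 0L) {
    out <- matrix(integer(0), 0, 3)
    attr(out, "on_lesion") <- logical(0)
    return(out)
  }
  n_les <- as.integer(round(n * spec$lesion_fraction))
  n_bg <- n - n_les
  les_idx <- which(mask$data != 0)
  bg_idx <- which(mask$data == 0)
  if (n_les > 0 && length(les_idx) == 0) {
    stop("lesion_fraction > 0 but the mask has no lesion voxels")
  }
  if (n_bg > 0 && length(bg_idx) == 0) {
    stop("mask has no non-lesion voxels to sample from")
  }
  draw <- function() {
    picks <- c(
      if (n_les > 0) les_idx[sample.int(length(les_idx), n_les, replace = TRUE)],
      if (n_bg > 0) bg_idx[sample.int(length(bg_idx), n_bg, replace = TRUE)]
    )
    picks
  }
  picks <- if (!is.null(spec$seed)) withr::with_seed(spec$seed, draw()) else draw()
  out <- arrayInd(picks, dm)
  attr(out, "on_lesion") <- c(rep(TRUE, n_les), rep(FALSE, n_bg))
  out
}

#' Extract one 4D patch
#'
#' The patch window is centred on `center` and clamped so it lies fully
#' inside the volume (no padding); coordinates are 1-based with closed
#' windows `[origin, origin + size - 1]`.
#'
#' @param vol A [volume4d()].
#' @param center Integer length-3 voxel coordinate inside the volume.
#' @param spec A [patch_spec()].
#' @param label_mask Optional [lesion_mask()] to crop congruently.
#' @return A list of class `patch` with elements `data` (`(2, d, h, w)`),
#'   `origin` and optionally `label`.
#' @export
extract_patch <- function(vol, center, spec = patch_spec(), label_mask = NULL) {
  stopifnot(inherits(vol, "volume4d"))
  dm <- dim(vol$channels)[-1]
  size <- spec$size
  if (any(dm < size)) {
    stop("volume (", paste(dm, collapse = "x"), ") is smaller than the patch ",
         "size (", paste(size, collapse = "x"), "); use a smaller patch size")
  }
  center <- as.integer(center)
  if (any(center < 1L) || any(center > dm)) stop("`center` is outside the volume")
  origin <- pmin(pmax(center - size %/% 2L, 1L), dm - size + 1L)
  i1 <- origin[1]:(origin[1] + size[1] - 1L)
  i2 <- origin[2]:(origin[2] + size[2] - 1L)
  i3 <- origin[3]:(origin[3] + size[3] - 1L)
  p <- list(data = vol$channels[, i1, i2, i3, drop = FALSE], origin = origin)
  if (!is.null(label_mask)) {
    label_mask <- as_lesion_mask(label_mask)
    p$label <- label_mask$data[i1, i2, i3, drop = FALSE]
  }
  structure(p, class = "patch")
}

#' Tile a volume for inference
#'
#' Lays non-overlapping tiles on a grid from origin `(1,1,1)`, zero-padding
#' the volume up to the next multiple of the tile size so the tiles cover it
#' exactly; tile origins are recorded for stitching.
#'
#' @param vol A [volume4d()].
#' @param spec A [patch_spec()] giving the tile size.
#' @return A list of `patch` objects; attributes `"orig_dim"` and
#'   `"padded_dim"` describe the stitching geometry.
#' @export
tile_volume <- function(vol, spec = patch_spec()) {
  stopifnot(inherits(vol, "volume4d"))
  dm <- dim(vol$channels)[-1]
  size <- spec$size
  pdm <- as.integer(ceiling(dm / size) * size)
  ch <- vol$channels
  if (any(pdm > dm)) {
    padded <- array(0, dim = c(2, pdm))
    padded[, seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- ch
    ch <- padded
  }
  origins <- expand.grid(
    d = seq(1L, pdm[1], by = size[1]),
    h = seq(1L, pdm[2], by = size[2]),
    w = seq(1L, pdm[3], by = size[3])
  )
  tiles <- lapply(seq_len(nrow(origins)), function(i) {
    o <- as.integer(origins[i, ])
    structure(list(
      data = ch[, o[1]:(o[1] + size[1] - 1L), o[2]:(o[2] + size[2] - 1L),
                o[3]:(o[3] + size[3] - 1L), drop = FALSE],
      origin = o
    ), class = "patch")
  })
  attr(tiles, "orig_dim") <- dm
  attr(tiles, "padded_dim") <- pdm
  attr(tiles, "tile_size") <- size
  tiles
}

#' Stitch tiled arrays back into a volume
#'
#' Inverse of [tile_volume()] for per-tile outputs: places each tile's array
#' at its recorded origin and strips the padding. Works for label tiles
#' (3D arrays) and probability tiles (`(C, d, h, w)` arrays).
#'
#' @param tiles List of arrays, one per tile, in [tile_volume()] order.
#' @param origins List/matrix of tile origins (or the `patch` list itself).
#' @param orig_dim,padded_dim,tile_size Geometry as recorded by
#'   [tile_volume()].
#' @return A stitched array of shape `orig_dim` (3D input) or
#'   `c(C, orig_dim)` (4D input).
#' @export
stitch_tiles <- function(tiles, origins, orig_dim, padded_dim, tile_size) {
  first <- tiles[[1]]
  has_ch <- length(dim(first)) == 4L
  C <- if (has_ch) dim(first)[1] else 1L
  out <- array(0, dim = c(C, padded_dim))
  for (i in seq_along(tiles)) {
    o <- as.integer(origins[[i]])
    a <- tiles[[i]]
    if (!has_ch) dim(a) <- c(1L, dim(a))
    out[, o[1]:(o[1] + tile_size[1] - 1L), o[2]:(o[2] + tile_size[2] - 1L),
        o[3]:(o[3] + tile_size[3] - 1L)] <- a
  }
  out <- out[, seq_len(orig_dim[1]), seq_len(orig_dim[2]), seq_len(orig_dim[3]),
             drop = FALSE]
  if (!has_ch) {
    dim(out) <- orig_dim
  }
  out
}
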