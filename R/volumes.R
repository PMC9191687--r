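#' Raw 3D volume
#'
#' Container for a single-modality 3D scalar image (e.g. a skull-stripped
#' FLAIR or T1-weighted volume) with voxel spacing, a voxel-to-world affine
#' and an optional brain mask.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Numeric length-3, per-axis voxel size in mm (all > 0).
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)` with
#'   a unit homogeneous row.
#' @param brain_mask Optional binary 3D array of the same shape (nonzero =
#'   brain).
#' @return An object of class `raw_volume`.
#' @export
raw_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                       brain_mask = NULL) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
  }
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive voxel sizes (mm)")
  }
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- matrix(as.numeric(affine), 4, 4)
  if (!is.null(brain_mask)) {
    if (!identical(dim(brain_mask), dim(data))) {
      stop("`brain_mask` shape must match `data`")
    }
    brain_mask <- array(as.integer(brain_mask != 0), dim = dim(data))
  }
  structure(
    list(data = data, spacing = spacing, affine = affine,
         brain_mask = brain_mask),
    class = "raw_volume"
  )
}

#' @export
print.raw_volume <- function(x, ...) {
  cat("<raw_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm", if (!is.null(x$brain_mask)) ", with brain mask", "\n", sep = "")
  invisible(x)
}

#' Two-channel 4D volume (enhanced intensity + edge map)
#'
#' The network input representation: channel 1 is the contrast-enhanced,
#' z-normalised intensity; channel 2 the Laplacian edge map. Stored
#' channel-first as a `(2, D, H, W)` array.
#'
#' @param channels 4D array with first dimension exactly 2.
#' @param affine 4x4 affine inherited from the source volume.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(channels, affine = diag(4)) {
  if (length(dim(channels)) != 4L || dim(channels)[1] != 2L) {
    stop("`channels` must be a (2, D, H, W) array")
  }
  structure(list(channels = channels, affine = matrix(as.numeric(affine), 4, 4)),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  cat("<volume4d> 2 channels, ", paste(dim(x$channels)[-1], collapse = " x "),
      " voxels\n", sep = "")
  invisible(x)
}

#' Binary lesion mask
#'
#' @param data 3D array; values must be 0/1 (or logical).
#' @param affine Optional 4x4 affine.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1, TRUE, FALSE))) {
    stop("lesion mask must be binary (0/1); found other values")
  }
  structure(list(data = array(as.integer(data != 0), dim = dim(data)),
                 affine = matrix(as.numeric(affine), 4, 4)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("<lesion_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " positive\n", sep = "")
  invisible(x)
}

# Coerce masks given as plain arrays.
as_lesion_mask <- function(x) {
  if (inherits(x, "lesion_mask")) x else lesion_mask(x)
}

#' Read a 3D NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param brain_mask Optional `lesion_mask`-like binary array to attach.
#' @return A [raw_volume()].
#' @export
read_nifti <- function(path, brain_mask = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI header in ", path,
                                           ": ", conditionMessage(e)))
  arr <- as.array(img)
  arr <- array(as.double(arr), dim = dim(arr)) # plain numeric array
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim = dim(arr)[1:3])
  }
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D image, got ", length(dim(arr)), "D: ", path)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  affine <- unclass(RNifti::xform(img))
  raw_volume(arr, spacing = spacing, affine = affine, brain_mask = brain_mask)
}

#' Write a volume or mask to NIfTI
#'
#' Integer-valued data are written as int32 and floats as float64, so that a
#' write/read round trip preserves voxel values (exactly for integers, to
#' better than 1e-6 otherwise) and the affine.
#'
#' @param vol A [raw_volume()], [lesion_mask()], or 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_nifti <- function(vol, path) {
  if (inherits(vol, "raw_volume")) {
    arr <- vol$data; affine <- vol$affine; spacing <- vol$spacing
  } else if (inherits(vol, "lesion_mask")) {
    arr <- vol$data; affine <- vol$affine; spacing <- c(1, 1, 1)
  } else {
    arr <- vol; affine <- diag(4); spacing <- c(1, 1, 1)
  }
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  is_int <- is.integer(arr) ||
    (is.numeric(arr) && all(is.finite(arr)) && all(arr == round(arr)) &&
       max(abs(arr)) < .Machine$integer.max)
  dt <- if (is_int) "int32" else "double"
  img <- RNifti::asNifti(array(as.numeric(arr), dim = dim(arr)))
  RNifti::pixdim(img) <- spacing
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
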