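#' DWI dataset container
#'
#' Bundles a 4-D signal grid with its voxel-to-world affine, gradient table
#' and a brain mask. The 4th dimension indexes acquired volumes and must
#' match the gradient table length.
#'
#' @param signal 4-D numeric array (x, y, z, volume) of nonnegative values.
#' @param affine 4x4 voxel-to-world (mm) matrix, 0-based voxel centers.
#' @param gradients a [gradient_table()].
#' @param brain_mask 3-D logical array matching the spatial grid; if `NULL`,
#'   voxels whose mean b = 0 signal is positive.
#' @return A `dwi_dataset` object.
#' @export
dwi_dataset <- function(signal, affine, gradients, brain_mask = NULL) {
  stopifnot(length(dim(signal)) == 4, inherits(gradients, "gradient_table"))
  if (dim(signal)[4] != length(gradients$bvals)) {
    stop(sprintf(
      "format error: signal has %d volumes but gradient table has %d rows",
      dim(signal)[4], length(gradients$bvals)), call. = FALSE)
  }
  solve_affine(affine)  # errors early on singular affines
  if (any(signal < 0)) stop("validation error: negative signal", call. = FALSE)
  if (is.null(brain_mask)) {
    b0 <- which(gradients$bvals == 0)
    mb0 <- apply(signal[, , , b0, drop = FALSE], 1:3, mean)
    brain_mask <- mb0 > 0
  }
  if (!all(dim(brain_mask) == dim(signal)[1:3])) {
    stop("format error: brain mask shape does not match signal grid",
         call. = FALSE)
  }
  structure(list(signal = signal, affine = affine,
                 gradients = gradients, brain_mask = array(as.logical(brain_mask), dim(signal)[1:3])),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_dataset> %d x %d x %d grid, %d volumes, %d brain voxels\n",
              d[1], d[2], d[3], d[4], sum(x$brain_mask)))
  invisible(x)
}

#' Read a DWI dataset from NIfTI + bvals/bvecs
#'
#' @param image_path path to a 4-D NIfTI volume.
#' @param bval_path,bvec_path FSL-style gradient text files.
#' @param mask_path optional NIfTI brain mask; derived from the mean b = 0
#'   signal when absent.
#' @return A [dwi_dataset()].
#' @export
read_dwi_dataset <- function(image_path, bval_path, bvec_path,
                             mask_path = NULL) {
  img <- RNifti::readNifti(image_path)
  if (length(dim(img)) != 4) {
    stop(sprintf("format error: expected a 4-D image, got %d dimensions",
                 length(dim(img))), call. = FALSE)
  }
  gtab <- read_bvals_bvecs(bval_path, bvec_path)
  if (dim(img)[4] != length(gtab$bvals)) {
    stop(sprintf(
      "format error: image has %d volumes but gradient files have %d entries",
      dim(img)[4], length(gtab$bvals)), call. = FALSE)
  }
  affine <- unclass(RNifti::xform(img))
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    mask <- array(as.logical(m > 0), dim(m)[1:3])
  }
  dwi_dataset(array(as.numeric(img), dim(img)), affine, gtab, mask)
}

#' Write a DWI dataset (or any grid) to NIfTI
#'
#' @param x a [dwi_dataset()], [scalar_map()], or plain array plus `affine`.
#' @param path output `.nii`/`.nii.gz` path.
#' @param affine used when `x` is a bare array.
#' @return Invisibly, `path`.
#' @export
write_nifti_volume <- function(x, path, affine = NULL) {
  if (inherits(x, "dwi_dataset")) {
    arr <- x$signal; affine <- x$affine
  } else if (inherits(x, "scalar_map")) {
    arr <- x$values; affine <- x$affine
  } else {
    arr <- x
    if (is.null(affine)) stop("affine required for bare arrays", call. = FALSE)
  }
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Scalar map (FA, MD, ...) on a voxel grid
#'
#' @param values 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param label metric name, e.g. `"FA"` or `"MD"`.
#' @return A `scalar_map` object.
#' @export
scalar_map <- function(values, affine, label = "scalar") {
  stopifnot(length(dim(values)) == 3)
  solve_affine(affine)
  structure(list(values = values, affine = affine, label = label),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<scalar_map:%s> %s grid, range [%.4g, %.4g]\n", x$label,
              paste(dim(x$values), collapse = " x "), rng[1], rng[2]))
  invisible(x)
}

#' Read a scalar NIfTI map
#'
#' @param path NIfTI path.
#' @param label metric name.
#' @return A [scalar_map()].
#' @export
read_scalar_map <- function(path, label = "scalar") {
  img <- RNifti::readNifti(path)
  scalar_map(array(as.numeric(img), dim(img)[1:3]),
             unclass(RNifti::xform(img)), label)
}
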