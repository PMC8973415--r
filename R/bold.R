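#' BOLD volume series
#'
#' A light container for a preprocessed 4D BOLD image: a numeric array with
#' dimensions (x, y, z, t), a 4x4 voxel-to-world affine (mm, RAS+), and the
#' repetition time in seconds.
#'
#' @param data 4D numeric array (x, y, z, t), t >= 2.
#' @param affine 4x4 voxel-to-world matrix (maps 0-based voxel indices to mm).
#' @param tr Repetition time in seconds.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, affine = diag(4), tr = 2) {
  stopifnot(is.array(data), length(dim(data)) == 4L, dim(data)[4] >= 2L,
            is.matrix(affine), all(dim(affine) == c(4L, 4L)),
            abs(det(affine)) > 0, tr > 0)
  structure(list(data = data, affine = affine, tr = tr),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d voxels, %d time points, TR = %gs\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

#' Read a 4D BOLD NIfTI image
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param tr Repetition time override in seconds; if `NULL`, taken from the
#'   header's time pixdim.
#' @return A [bold_series()].
#' @export
read_bold <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  stopifnot(length(dim(img)) == 4L)
  if (is.null(tr)) {
    pd <- RNifti::pixdim(img)
    tr <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else 2
  }
  bold_series(unclass(img)[, , , , drop = FALSE],
              affine = unname(RNifti::xform(img)), tr = tr)
}

#' Read a 3D mask NIfTI image
#'
#' Nonzero voxels are in-mask.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A list with `mask` (3D logical array) and `affine`.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  stopifnot(length(dim(img)) == 3L)
  list(mask = array(unclass(img) != 0, dim(img)),
       affine = unname(RNifti::xform(img)))
}

#' Write a 3D/4D array as NIfTI
#'
#' Undefined voxels (`NA`) are written as NaN. The affine is stored as both
#' qform and sform.
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param tr Time step for the 4th dimension, seconds (4D only).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, affine, path, tr = NULL) {
  nd <- length(dim(data))
  data[is.na(data)] <- NaN   # undefined voxels are stored as plain NaN
  voxdim <- sqrt(colSums(affine[1:3, 1:3]^2))
  nim <- oro.nifti::nifti(data, datatype = 64L, bitpix = 64L)
  nim@pixdim <- c(-1, voxdim, if (is.null(tr)) 1 else tr, 0, 0, 0)[1:8]
  nim@srow_x <- affine[1, ]
  nim@srow_y <- affine[2, ]
  nim@srow_z <- affine[3, ]
  nim@sform_code <- 2L
  nim@qform_code <- 0L
  nim@xyzt_units <- 10L   # mm + seconds
  gz <- grepl("\\.gz$", path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  oro.nifti::writeNIfTI(nim, stem, gzipped = gz)
  invisible(path)
}
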