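#' Voxel-wise dynamic entropy map
#'
#' Slides a window along the time axis and computes the sample entropy of
#' every in-mask voxel's windowed series, giving a 4D (x, y, z, window) map
#' of transient signal complexity — the brain-entropy (BEN) map sequence.
#' Out-of-mask voxels are `NA` throughout; in-mask windows whose entropy is
#' undefined (constant signal or no template matches) are `NA` and propagate
#' through [summarize_entropy()].
#'
#' The computation is pure per voxel and per window, so the result is
#' deterministic and independent of iteration order.
#'
#' @param bold A [bold_series()].
#' @param mask 3D logical array on the same grid.
#' @param params A [sampen_params()].
#' @param scheme A [window_scheme()].
#' @return An object of class `dynamic_entropy_map`: list with `data`
#'   (4D array, x-y-z-window), `scheme`, `mask`, `affine`, `tr`.
#' @export
dynamic_entropy_map <- function(bold, mask,
                                params = sampen_params(),
                                scheme = window_scheme(70)) {
  stopifnot(inherits(bold, "bold_series"), is.array(mask),
            length(dim(mask)) == 3L)
  d <- dim(bold$data)
  if (!all(dim(mask) == d[1:3])) {
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match BOLD grid ", paste(d[1:3], collapse = "x"),
         call. = FALSE)
  }
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("mask is empty (all FALSE)", call. = FALSE)

  win <- window_indices(d[4], scheme)
  vox <- which(mask)
  # voxels x time, then transpose to time x voxels for contiguous columns
  series <- matrix(bold$data[rep(vox, d[4]) +
                               rep((seq_len(d[4]) - 1L) * prod(d[1:3]),
                                   each = length(vox))],
                   nrow = length(vox))
  ent <- sampen_map_cpp(t(series), win$start - 1L, scheme$length,
                        params$m, params$r_factor)  # M x V
  out <- array(NA_real_, c(d[1:3], nrow(win)))
  nvox3 <- prod(d[1:3])
  for (w in seq_len(nrow(win))) {
    out[vox + (w - 1L) * nvox3] <- ent[w, ]
  }
  structure(list(data = out, scheme = scheme, mask = mask,
                 affine = bold$affine, tr = bold$tr,
                 params = params),
            class = "dynamic_entropy_map")
}

#' @export
print.dynamic_entropy_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dynamic_entropy_map> %d x %d x %d voxels, %d windows (Len = %d, step = %d)\n",
    d[1], d[2], d[3], d[4], x$scheme$length, x$scheme$step))
  cat(sprintf("  in-mask voxels: %d; m = %d, r = %g * SD\n",
              sum(x$mask), x$params$m, x$params$r_factor))
  invisible(x)
}

#' Mean-BEN and Std-BEN summary maps
#'
#' Collapses the window axis of a dynamic entropy map to its per-voxel mean
#' (Mean-BEN) and sample standard deviation (Std-BEN, divisor M-1). A voxel
#' with any undefined window value is undefined (`NA`) in both summaries.
#'
#' @param dmap A [dynamic_entropy_map()].
#' @return An object of class `summary_entropy_maps`: list with `mean_ben`,
#'   `std_ben` (3D arrays), `affine`, `mask`.
#' @export
summarize_entropy <- function(dmap) {
  stopifnot(inherits(dmap, "dynamic_entropy_map"))
  d <- dim(dmap$data)
  M <- d[4]
  if (M < 2L) {
    warning("single-window map: Std-BEN is undefined", call. = FALSE)
  }
  flat <- matrix(dmap$data, ncol = M)     # voxel x window
  mean_ben <- rowMeans(flat)              # NA propagates
  std_ben <- if (M >= 2L) {
    sqrt(rowSums((flat - mean_ben)^2) / (M - 1))
  } else {
    rep(NA_real_, nrow(flat))
  }
  std_ben[is.na(mean_ben)] <- NA_real_
  structure(list(mean_ben = array(mean_ben, d[1:3]),
                 std_ben = array(std_ben, d[1:3]),
                 affine = dmap$affine, mask = dmap$mask),
            class = "summary_entropy_maps")
}

#' @export
print.summary_entropy_maps <- function(x, ...) {
  ok <- !is.na(x$mean_ben)
  cat(sprintf("<summary_entropy_maps> %s grid, %d defined voxels\n",
              paste(dim(x$mean_ben), collapse = " x "), sum(ok)))
  if (any(ok)) {
    cat(sprintf("  Mean-BEN range: [%.3f, %.3f]; Std-BEN range: [%.3f, %.3f]\n",
                min(x$mean_ben[ok]), max(x$mean_ben[ok]),
                min(x$std_ben[ok]), max(x$std_ben[ok])))
  }
  invisible(x)
}

#' Write a dynamic entropy map or its summaries to NIfTI
#'
#' @param x A `dynamic_entropy_map` or `summary_entropy_maps` object.
#' @param path Output path for a 4D map; for summaries, a path prefix which
#'   gets `_mean_ben.nii.gz` / `_std_ben.nii.gz` appended.
#' @return The path(s) written, invisibly.
#' @export
write_entropy_map <- function(x, path) {
  if (inherits(x, "dynamic_entropy_map")) {
    return(write_nifti(x$data, x$affine, path, tr = x$tr))
  }
  if (inherits(x, "summary_entropy_maps")) {
    p1 <- paste0(path, "_mean_ben.nii.gz")
    p2 <- paste0(path, "_std_ben.nii.gz")
    write_nifti(x$mean_ben, x$affine, p1)
    write_nifti(x$std_ben, x$affine, p2)
    return(invisible(c(p1, p2)))
  }
  stop("x must be a dynamic_entropy_map or summary_entropy_maps object",
       call. = FALSE)
}
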