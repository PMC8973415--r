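#' Integer-labelled parcellation atlas
#'
#' Wraps a 3D integer label image (0 = background) with an ordered region-id
#' list and optional region names, as used by AAL-style templates.
#'
#' @param labels 3D integer array; 0 is background.
#' @param region_ids Ordered vector of positive region ids; defaults to the
#'   sorted nonzero labels present.
#' @param region_names Optional character vector, one name per id.
#' @param affine 4x4 voxel-to-world matrix.
#' @return An object of class `parcellation_atlas`.
#' @export
parcellation_atlas <- function(labels, region_ids = NULL,
                               region_names = NULL, affine = diag(4)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  labels <- array(as.integer(labels), dim(labels))
  present <- sort(unique(labels[labels > 0L]))
  if (is.null(region_ids)) region_ids <- present
  region_ids <- as.integer(region_ids)
  stopifnot(!anyDuplicated(region_ids), all(region_ids > 0L))
  if (!all(region_ids %in% present)) {
    stop("region ids absent from the label image: ",
         paste(setdiff(region_ids, present), collapse = ", "), call. = FALSE)
  }
  if (!is.null(region_names)) stopifnot(length(region_names) == length(region_ids))
  structure(list(labels = labels, region_ids = region_ids,
                 region_names = region_names, affine = affine),
            class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat(sprintf("<parcellation_atlas> %s grid, %d regions\n",
              paste(dim(x$labels), collapse = " x "), length(x$region_ids)))
  invisible(x)
}

#' Read a parcellation atlas from NIfTI (+ optional name table)
#'
#' @param path Label image (`.nii` / `.nii.gz`).
#' @param names_tsv Optional TSV with columns `id` and `name`.
#' @return A [parcellation_atlas()].
#' @export
read_atlas <- function(path, names_tsv = NULL) {
  img <- RNifti::readNifti(path)
  stopifnot(length(dim(img)) == 3L)
  nm <- NULL; ids <- NULL
  if (!is.null(names_tsv)) {
    tab <- utils::read.delim(names_tsv, header = TRUE)
    ids <- as.integer(tab$id); nm <- as.character(tab$name)
  }
  parcellation_atlas(round(unclass(img)), region_ids = ids,
                     region_names = nm, affine = unname(RNifti::xform(img)))
}

#' Region-mean entropy sequences
#'
#' Reduces a voxel-wise dynamic entropy map to one entropy time series per
#' atlas region: for each window, the mean over the region's defined in-mask
#' voxels. A voxel is used for a region only if its entropy is defined in
#' every window, so rows contain no missing values. Regions with no such
#' voxel are dropped with a warning.
#'
#' @param dmap A [dynamic_entropy_map()].
#' @param atlas A [parcellation_atlas()] on the same grid.
#' @return An object of class `region_entropy_matrix`: list with `values`
#'   (regions x windows), `region_ids`, `scheme`.
#' @export
extract_region_series <- function(dmap, atlas) {
  stopifnot(inherits(dmap, "dynamic_entropy_map"),
            inherits(atlas, "parcellation_atlas"))
  d <- dim(dmap$data)
  if (!all(dim(atlas$labels) == d[1:3])) {
    stop("atlas grid ", paste(dim(atlas$labels), collapse = "x"),
         " does not match entropy-map grid ",
         paste(d[1:3], collapse = "x"), call. = FALSE)
  }
  M <- d[4]
  flat <- matrix(dmap$data, ncol = M)           # voxel x window
  usable <- dmap$mask & array(rowSums(is.na(flat)) == 0L, d[1:3])
  lab <- as.integer(atlas$labels)

  rows <- lapply(atlas$region_ids, function(id) {
    sel <- which(lab == id & usable)
    if (length(sel) == 0L) return(NULL)
    colMeans(flat[sel, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no atlas region has defined entropy voxels", call. = FALSE)
  if (!all(keep)) {
    warning("dropping region(s) with no defined voxels: ",
            paste(atlas$region_ids[!keep], collapse = ", "), call. = FALSE)
  }
  structure(list(values = do.call(rbind, rows[keep]),
                 region_ids = atlas$region_ids[keep],
                 scheme = dmap$scheme),
            class = "region_entropy_matrix")
}

#' @export
print.region_entropy_matrix <- function(x, ...) {
  cat(sprintf("<region_entropy_matrix> %d regions x %d windows\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
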