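#' Pearson connectivity of regional entropy sequences
#'
#' Correlates every pair of region entropy time series, giving the
#' entropy-sequence connectivity matrix of one subject. Regions whose
#' sequence has zero variance cannot be correlated and are dropped with a
#' warning.
#'
#' @param rem A [extract_region_series()] result.
#' @return An object of class `connectivity_matrix`: list with `values`
#'   (symmetric R x R correlation matrix, unit diagonal) and `region_ids`.
#' @export
pearson_connectivity <- function(rem) {
  stopifnot(inherits(rem, "region_entropy_matrix"))
  if (ncol(rem$values) < 3L) {
    stop("need at least 3 windows to correlate (have ",
         ncol(rem$values), ")", call. = FALSE)
  }
  v <- apply(rem$values, 1L, stats::var)
  keep <- v > 0
  if (!all(keep)) {
    warning("dropping zero-variance region(s): ",
            paste(rem$region_ids[!keep], collapse = ", "), call. = FALSE)
  }
  if (sum(keep) < 2L) stop("fewer than 2 regions with variance", call. = FALSE)
  vals <- stats::cor(t(rem$values[keep, , drop = FALSE]))
  dimnames(vals) <- NULL
  structure(list(values = vals, region_ids = rem$region_ids[keep]),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<connectivity_matrix> %d regions; off-diagonal r in [%.3f, %.3f]\n",
              nrow(x$values), min(off), max(off)))
  invisible(x)
}

#' Proportional-threshold binarisation
#'
#' Keeps the `round(k * R*(R-1)/2)` strongest edges of a connectivity matrix
#' and binarises. By default edges are ranked by signed correlation (largest
#' positive first); set `rank = "absolute"` to rank by magnitude. Ties are
#' broken deterministically by lexicographic (row, column) order of the
#' upper triangle.
#'
#' @param conn A [pearson_connectivity()] result.
#' @param k Proportional threshold in (0, 1]: fraction of possible edges kept.
#' @param rank `"signed"` (default) or `"absolute"`.
#' @return An object of class `binary_graph`: list with `adjacency`
#'   (logical R x R, zero diagonal), `threshold`, `region_ids`.
#' @export
proportional_threshold <- function(conn, k, rank = c("signed", "absolute")) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  rank <- match.arg(rank)
  if (!(is.numeric(k) && length(k) == 1L && k > 0 && k <= 1)) {
    stop("k must be a single value in (0, 1], got ", k, call. = FALSE)
  }
  R <- nrow(conn$values)
  ut <- which(upper.tri(conn$values), arr.ind = TRUE)
  w <- conn$values[ut]
  if (rank == "absolute") w <- abs(w)
  n_keep <- round(k * R * (R - 1) / 2)
  ord <- order(-w, ut[, 1L], ut[, 2L])
  sel <- ord[seq_len(n_keep)]
  adj <- matrix(FALSE, R, R)
  adj[ut[sel, , drop = FALSE]] <- TRUE
  adj <- adj | t(adj)
  structure(list(adjacency = adj, threshold = k, region_ids = conn$region_ids),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (K = %g)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$threshold))
  invisible(x)
}
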