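#' Sample-entropy parameters
#'
#' Bundles the embedding dimension `m` and the similarity-criterion factor
#' `r_factor`. The tolerance used for template matching is
#' `r = r_factor * SD(series)` (sample SD, divisor n-1), recomputed for each
#' windowed series, so SampEn is invariant to shifting and positive rescaling
#' of the signal.
#'
#' @param m Embedding dimension (integer >= 1). Default 2.
#' @param r_factor Tolerance as a multiple of the series SD (> 0). Default 0.3.
#' @return An object of class `sampen_params`.
#' @examples
#' sampen_params()
#' @export
sampen_params <- function(m = 2L, r_factor = 0.3) {
  m <- as.integer(m)
  stopifnot(length(m) == 1L, m >= 1L,
            length(r_factor) == 1L, is.finite(r_factor), r_factor > 0)
  structure(list(m = m, r_factor = r_factor), class = "sampen_params")
}

#' Sliding-window scheme
#'
#' Describes the sliding window applied along the time axis: `length` time
#' points per window (in TRs) and a stride of `step` TRs. With `step = 1`,
#' a series of `N` points yields `N - length + 1` windows.
#'
#' @param length Window length in time points (TRs).
#' @param step Stride in time points. Default 1.
#' @return An object of class `window_scheme`.
#' @examples
#' window_scheme(70)
#' @export
window_scheme <- function(length, step = 1L) {
  length <- as.integer(length); step <- as.integer(step)
  stopifnot(length >= 1L, step >= 1L)
  structure(list(length = length, step = step), class = "window_scheme")
}

#' Sliding-window start/end indices
#'
#' Returns the half-open `[start, end)` index pairs (1-based starts, `end`
#' exclusive) of every window that fits in a series of `n_timepoints` points.
#' The number of windows is `floor((n - length)/step) + 1`; for `step = 1`
#' this is `n - length + 1` (e.g. 160 time points with windows of 70, 80 and
#' 90 TRs give 81, 71 and 61 windows).
#'
#' @param n_timepoints Series length.
#' @param scheme A [window_scheme()].
#' @return A tibble with columns `window`, `start`, `end` (end exclusive).
#' @examples
#' nrow(window_indices(160, window_scheme(70))) # 81
#' @export
window_indices <- function(n_timepoints, scheme) {
  stopifnot(inherits(scheme, "window_scheme"))
  n <- as.integer(n_timepoints)
  if (scheme$length > n) {
    stop("window length (", scheme$length,
         ") exceeds series length (", n, ")", call. = FALSE)
  }
  starts <- seq.int(1L, n - scheme$length + 1L, by = scheme$step)
  tibble::tibble(window = seq_along(starts),
                 start = starts,
                 end = starts + scheme$length)
}

#' Sample entropy of a univariate series
#'
#' SampEn(m, r) = -ln(A/B), where B counts pairs of distinct length-`m`
#' templates whose Chebyshev distance is strictly below `r`, and A counts the
#' same pairs extended to length `m + 1`. Self-matches are excluded, and only
#' templates whose (m+1)-point extension exists are enumerated, so A and B
#' range over the same pair set. `r` is `r_factor` times the sample SD of
#' `series`. Lower values indicate a more regular (predictable) signal.
#'
#' Degenerate inputs return `NA_real_` rather than an error or infinity:
#' a constant series (SD = 0, tolerance undefined), or zero match counts
#' (A = 0 or B = 0).
#'
#' @param series Numeric vector, length >= m + 2.
#' @param params A [sampen_params()].
#' @return Entropy in nats (single numeric), or `NA_real_` if undefined.
#' @examples
#' sample_entropy(rep(c(1, 2), 10))  # periodic -> 0
#' sample_entropy(rep(5, 20))        # constant -> NA
#' @export
sample_entropy <- function(series, params = sampen_params()) {
  stopifnot(inherits(params, "sampen_params"), is.numeric(series))
  series <- as.numeric(series)
  if (length(series) < params$m + 2L) {
    stop("series length (", length(series), ") must be at least m + 2 = ",
         params$m + 2L, call. = FALSE)
  }
  if (anyNA(series) || !all(is.finite(series))) {
    stop("series contains non-finite values", call. = FALSE)
  }
  sampen_cpp(series, params$m, params$r_factor)
}
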