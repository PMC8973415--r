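#' Voxel-wise two-sample t-test
#'
#' Independent two-sample t statistic with pooled variance at every voxel,
#' plus the two-tailed p-value. Voxels undefined (`NA`) in any subject of
#' either group are undefined in both outputs. Swapping the groups negates
#' the t-map exactly.
#'
#' @param group_a,group_b Lists of 3D numeric arrays (one map per subject)
#'   on a common grid; at least 2 subjects per group.
#' @return A list with `t` (3D array), `p` (3D array), `df`.
#' @export
voxelwise_two_sample_t <- function(group_a, group_b) {
  check_group <- function(g, nm) {
    if (!is.list(g) || length(g) < 2L) {
      stop(nm, " needs at least 2 subject maps", call. = FALSE)
    }
    d <- dim(g[[1]])
    stopifnot(length(d) == 3L)
    for (m in g) if (!all(dim(m) == d)) stop("maps differ in grid", call. = FALSE)
    d
  }
  d <- check_group(group_a, "group_a")
  stopifnot(all(check_group(group_b, "group_b") == d))
  na <- length(group_a); nb <- length(group_b)
  A <- matrix(vapply(group_a, as.numeric, numeric(prod(d))), prod(d), na)
  B <- matrix(vapply(group_b, as.numeric, numeric(prod(d))), prod(d), nb)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2L
  p <- 2 * stats::pt(-abs(tstat), df)
  list(t = array(tstat, d), p = array(p, d), df = df)
}

#' AlphaSim configuration
#'
#' Parameters of the Monte-Carlo cluster-extent correction: cluster-forming
#' voxel threshold (two-tailed p), assumed spatial smoothness (Gaussian
#' FWHM in mm), number of noise simulations, target family-wise alpha, and
#' the cluster-connectivity rule.
#'
#' @param voxel_p Two-tailed cluster-forming p (default 0.01).
#' @param fwhm_mm Gaussian smoothing FWHM in mm (default 8; 0 disables
#'   smoothing).
#' @param n_iterations Monte-Carlo iterations (default 1000).
#' @param alpha Target family-wise error rate (default 0.05).
#' @param connectivity Neighbourhood rule: 6, 18 or 26 (default 26).
#' @param seed Integer seed.
#' @return An object of class `alphasim_config`.
#' @export
alphasim_config <- function(voxel_p = 0.01, fwhm_mm = 8, n_iterations = 1000L,
                            alpha = 0.05, connectivity = 26L, seed = 1L) {
  stopifnot(voxel_p > 0, voxel_p < 1, fwhm_mm >= 0, alpha > 0, alpha < 1,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(voxel_p = voxel_p, fwhm_mm = fwhm_mm,
                 n_iterations = as.integer(n_iterations), alpha = alpha,
                 connectivity = as.integer(connectivity),
                 seed = as.integer(seed)),
            class = "alphasim_config")
}

# separable 3D Gaussian smoothing, zero-padded boundaries
smooth_gaussian_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    radius <- max(1L, ceiling(4 * s))
    k <- exp(-0.5 * ((-radius):radius / s)^2)
    k <- k / sum(k)
    # bring axis `ax` first, convolve columns via band matrix product
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), nrow = d[ax])
    n <- d[ax]
    K <- matrix(0, n, n)
    for (off in (-radius):radius) {
      idx <- which(seq_len(n) + off >= 1 & seq_len(n) + off <= n)
      K[cbind(idx, idx + off)] <- k[off + radius + 1L]
    }
    m <- K %*% m
    arr <- aperm(array(m, d[perm]), order(perm))
  }
  arr
}

#' Connected components of a 3D logical array
#'
#' @param fg 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(fg, connectivity = 26L) {
  stopifnot(is.array(fg), length(dim(fg)) == 3L)
  label_components_cpp(as.logical(fg), as.integer(dim(fg)),
                       as.integer(connectivity))
}

# one null max-cluster-size draw shared by threshold estimation and FWE checks
alphasim_max_cluster <- function(mask, sigma_vox, z_crit, connectivity) {
  d <- dim(mask)
  noise <- array(stats::rnorm(prod(d)), d)
  if (any(sigma_vox > 0)) noise <- smooth_gaussian_3d(noise, sigma_vox)
  inm <- noise[mask]
  z <- (noise - mean(inm)) / stats::sd(inm)
  supra <- abs(z) > z_crit & mask
  if (!any(supra)) return(0L)
  lab <- label_components(supra, connectivity)
  max(tabulate(lab[lab > 0L]))
}

#' Monte-Carlo cluster-extent threshold (AlphaSim-style)
#'
#' Estimates the minimum cluster size (in voxels) that controls the
#' family-wise error at `cfg$alpha` for a map thresholded voxel-wise at
#' `cfg$voxel_p` (two-tailed). Each iteration fills the mask's grid with
#' i.i.d. Gaussian noise, smooths it to `cfg$fwhm_mm`, re-standardises
#' within the mask, thresholds at `|z| > z_crit`, and records the largest
#' suprathreshold cluster under `cfg$connectivity`. The returned extent is
#' the smallest k with `P(max cluster >= k) <= alpha` over the iterations.
#'
#' @param mask 3D logical array.
#' @param cfg An [alphasim_config()].
#' @param voxel_mm Voxel edge lengths in mm (length 3), used to convert the
#'   FWHM to voxels. Default `c(3, 3, 3)`.
#' @return Integer minimum cluster extent, with attribute `max_sizes`
#'   (the simulated max-cluster-size distribution).
#' @export
alphasim_cluster_threshold <- function(mask, cfg = alphasim_config(),
                                       voxel_mm = c(3, 3, 3)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (cfg$n_iterations < 100L) {
    warning("fewer than 100 iterations: extent estimate is unstable",
            call. = FALSE)
  }
  sigma_vox <- cfg$fwhm_mm / (voxel_mm * sqrt(8 * log(2)))
  z_crit <- stats::qnorm(1 - cfg$voxel_p / 2)
  max_sizes <- withr::with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_iterations), function(i) {
      alphasim_max_cluster(mask, sigma_vox, z_crit, cfg$connectivity)
    }, integer(1))
  })
  # smallest k with fraction(max >= k) <= alpha
  k <- 1L
  n <- length(max_sizes)
  while (sum(max_sizes >= k) / n > cfg$alpha) k <- k + 1L
  structure(k, max_sizes = max_sizes)
}

#' Suprathreshold clusters of a statistic map
#'
#' Finds connected components of voxels with `p < voxel_p`, split by the
#' sign of the statistic, discards components smaller than `min_extent`, and
#' reports each surviving cluster's peak (voxel of maximal |statistic|),
#' its world coordinate via the affine, and the atlas label at the peak.
#'
#' @param stat_map,p_map 3D arrays on a common grid.
#' @param voxel_p Voxel-wise forming threshold on `p_map`.
#' @param min_extent Minimum cluster size in voxels.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param atlas Optional [parcellation_atlas()] for peak labels.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A tibble of class `dbca_clusters` with columns `direction`,
#'   `size`, `peak_stat`, `peak_x`, `peak_y`, `peak_z` (mm), `peak_i`,
#'   `peak_j`, `peak_k` (1-based voxel), `label`. Attribute
#'   `n_subthreshold_voxels` counts suprathreshold voxels in discarded
#'   components.
#' @export
extract_clusters <- function(stat_map, p_map, voxel_p, min_extent, affine,
                             atlas = NULL, connectivity = 26L) {
  d <- dim(stat_map)
  stopifnot(length(d) == 3L, all(dim(p_map) == d), min_extent >= 1)
  rows <- list()
  discarded <- 0L
  for (dir in c("positive", "negative")) {
    sgn <- if (dir == "positive") 1 else -1
    supra <- !is.na(p_map) & p_map < voxel_p & sgn * stat_map > 0
    if (!any(supra)) next
    lab <- label_components(supra, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    for (cl in which(sizes >= min_extent)) {
      idx <- which(lab == cl)
      peak <- idx[which.max(abs(stat_map[idx]))]
      ijk <- arrayInd(peak, d)
      world <- affine %*% c(ijk - 1L, 1)
      lbl <- "unlabeled"
      if (!is.null(atlas)) {
        id <- atlas$labels[peak]
        if (id > 0L) {
          lbl <- if (!is.null(atlas$region_names)) {
            atlas$region_names[match(id, atlas$region_ids)]
          } else {
            paste0("region_", id)
          }
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        direction = dir, size = sizes[cl],
        peak_stat = stat_map[peak],
        peak_x = world[1], peak_y = world[2], peak_z = world[3],
        peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
        label = lbl)
    }
    discarded <- discarded + sum(sizes[sizes < min_extent])
  }
  out <- if (length(rows)) {
    dplyr::arrange(dplyr::bind_rows(rows), .data$direction, -.data$size)
  } else {
    tibble::tibble(direction = character(), size = integer(),
                   peak_stat = numeric(), peak_x = numeric(),
                   peak_y = numeric(), peak_z = numeric(),
                   peak_i = integer(), peak_j = integer(),
                   peak_k = integer(), label = character())
  }
  attr(out, "n_subthreshold_voxels") <- discarded
  class(out) <- c("dbca_clusters", class(out))
  out
}
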