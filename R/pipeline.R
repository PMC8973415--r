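compute_group_summaries <- function(cohort, params, scheme, map = "mean",
                                    cache = NULL) {
  lapply(cohort$groups, function(subjects) {
    lapply(seq_along(subjects), function(i) {
      dm <- dynamic_entropy_map(subjects[[i]], cohort$mask, params, scheme)
      sm <- summarize_entropy(dm)
      if (map == "mean") sm$mean_ben else sm$std_ben
    })
  })
}

#' Entropy-mapping arm: cohort to corrected group contrast
#'
#' Runs the voxel-wise complexity pipeline end to end for each configured
#' window length: per-subject dynamic entropy maps, Mean-BEN (or Std-BEN)
#' summaries, a voxel-wise two-sample t-test between the groups, a
#' Monte-Carlo cluster-extent threshold, and the corrected cluster table
#' with peaks located in the cohort atlas.
#'
#' @param cohort A [generate_cohort()] result (or an equivalent list with
#'   `groups`, `mask`, `atlas`).
#' @param window_lengths Window lengths in TRs (default `c(70, 80, 90)`).
#' @param params A [sampen_params()].
#' @param map `"mean"` (Mean-BEN, default) or `"std"` (Std-BEN).
#' @param alphasim An [alphasim_config()]. For unsmoothed synthetic data use
#'   `fwhm_mm = 0` so the null model matches the data's smoothness.
#' @param voxel_mm Voxel size in mm for the FWHM conversion.
#' @param extent Optional precomputed cluster-extent threshold (voxels);
#'   skips the Monte-Carlo simulation, e.g. when the same mask is analysed
#'   repeatedly.
#' @return A list of class `dbca_entropy_arm`, one element per window
#'   length: `window_length`, `ttest`, `extent`, `clusters`.
#' @export
run_entropy_arm <- function(cohort, window_lengths = c(70, 80, 90),
                            params = sampen_params(), map = c("mean", "std"),
                            alphasim = alphasim_config(),
                            voxel_mm = c(3, 3, 3), extent = NULL) {
  map <- match.arg(map)
  if (is.null(extent)) {
    extent <- alphasim_cluster_threshold(cohort$mask, alphasim, voxel_mm)
  }
  res <- lapply(window_lengths, function(len) {
    scheme <- window_scheme(len)
    maps <- compute_group_summaries(cohort, params, scheme, map)
    tt <- voxelwise_two_sample_t(maps[[1]], maps[[2]])
    cl <- extract_clusters(tt$t, tt$p, alphasim$voxel_p, as.integer(extent),
                           cohort$atlas$affine, atlas = cohort$atlas,
                           connectivity = alphasim$connectivity)
    list(window_length = len, ttest = tt, extent = as.integer(extent),
         clusters = cl)
  })
  names(res) <- paste0("len", window_lengths)
  structure(res, class = "dbca_entropy_arm")
}

#' @export
print.dbca_entropy_arm <- function(x, ...) {
  cat("<dbca_entropy_arm>\n")
  for (r in x) {
    cat(sprintf("  Len = %d: extent threshold %d voxels, %d cluster(s)\n",
                r$window_length, r$extent, nrow(r$clusters)))
  }
  invisible(x)
}

#' Network arm: cohort to group-by-threshold ANOVA
#'
#' Per subject: dynamic entropy map, region entropy sequences, Pearson
#' connectivity, and graph metrics across proportional thresholds; region
#' sets are intersected across subjects so every network shares one node
#' set. The per-subject metric tables are then compared by the two-way
#' group-by-threshold ANOVA.
#'
#' @param cohort A [generate_cohort()] result.
#' @param window_length Window length in TRs (default 70).
#' @param params A [sampen_params()].
#' @param thresholds Proportional thresholds (default 0.05..0.30 step 0.05).
#' @param null_cfg A [null_model_config()].
#' @param quiet Passed to [anova_group_threshold()].
#' @return A list of class `dbca_network_arm`: `metrics` (tibble with
#'   subject, group, and one row per threshold), `anova` (a `dbca_anova`),
#'   `window_length`, `region_ids`.
#' @export
run_network_arm <- function(cohort, window_length = 70,
                            params = sampen_params(),
                            thresholds = seq(0.05, 0.30, by = 0.05),
                            null_cfg = null_model_config(),
                            quiet = TRUE) {
  scheme <- window_scheme(window_length)
  subj <- cohort$subject_seeds
  rems <- vector("list", nrow(subj))
  idx <- 0L
  for (g in names(cohort$groups)) {
    for (i in seq_along(cohort$groups[[g]])) {
      idx <- idx + 1L
      dm <- dynamic_entropy_map(cohort$groups[[g]][[i]], cohort$mask,
                                params, scheme)
      rems[[idx]] <- extract_region_series(dm, cohort$atlas)
    }
  }
  common <- Reduce(intersect, lapply(rems, function(r) r$region_ids))
  if (length(common) < 3L) stop("fewer than 3 regions shared across subjects",
                                call. = FALSE)
  metrics <- purrr::map_dfr(seq_len(nrow(subj)), function(i) {
    r <- rems[[i]]
    keep <- match(common, r$region_ids)
    r$values <- r$values[keep, , drop = FALSE]
    r$region_ids <- common
    m <- metrics_over_thresholds(
      pearson_connectivity(r), thresholds,
      null_model_config(null_cfg$n_random, null_cfg$n_swaps_per_edge,
                        seed = null_cfg$seed + i * 1000L))
    dplyr::bind_cols(tibble::tibble(subject = subj$subject[i],
                                    group = subj$group[i]), m)
  })
  class(metrics) <- c("dbca_metrics", class(metrics))
  an <- anova_group_threshold(metrics, quiet = quiet)
  structure(list(metrics = metrics, anova = an,
                 window_length = window_length, region_ids = common),
            class = "dbca_network_arm")
}

#' @export
print.dbca_network_arm <- function(x, ...) {
  cat(sprintf("<dbca_network_arm> Len = %d, %d nodes, %d subjects\n",
              x$window_length, length(x$region_ids),
              length(unique(x$metrics$subject))))
  print(x$anova$tests)
  invisible(x)
}

#' Write pipeline outputs and a reproducibility manifest
#'
#' Writes t/p maps as NIfTI, cluster and metric/ANOVA tables as TSV, and a
#' JSON manifest (package version, configuration echo) sufficient to re-run
#' the analysis bit for bit.
#'
#' @param result A `dbca_entropy_arm` or `dbca_network_arm` object.
#' @param dir Output directory.
#' @param affine Affine for NIfTI outputs (entropy arm).
#' @param config_echo List of configuration values to record.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, affine = diag(c(3, 3, 3, 1)),
                          config_echo = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "dbca",
                   version = as.character(utils::packageVersion("dbca")),
                   config = config_echo)
  if (inherits(result, "dbca_entropy_arm")) {
    for (r in result) {
      pre <- file.path(dir, sprintf("len%d", r$window_length))
      write_nifti(r$ttest$t, affine, paste0(pre, "_tmap.nii.gz"))
      write_nifti(r$ttest$p, affine, paste0(pre, "_pmap.nii.gz"))
      utils::write.table(r$clusters, paste0(pre, "_clusters.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      manifest[[sprintf("extent_len%d", r$window_length)]] <- r$extent
    }
  } else if (inherits(result, "dbca_network_arm")) {
    long <- tidyr::pivot_longer(
      result$metrics,
      dplyr::all_of(c("cp", "lp", "gamma", "lambda", "s", "e_glob", "e_loc")),
      names_to = "metric", values_to = "value")
    utils::write.table(
      long[, c("subject", "group", "k", "metric", "value")],
      file.path(dir, sprintf("len%d_metrics.tsv", result$window_length)),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      result$anova$tests,
      file.path(dir, sprintf("len%d_anova.tsv", result$window_length)),
      sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$window_length <- result$window_length
    manifest$region_ids <- result$region_ids
  } else {
    stop("unsupported result type", call. = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
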