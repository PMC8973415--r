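#' Synthetic-cohort specification
#'
#' Describes a fully seeded two-group fMRI cohort with regionally controlled
#' signal regularity, mirroring a 20 + 20 subject resting-state design with
#' 160 time points at TR = 2 s. Each voxel's series mixes a deterministic
#' low-frequency component (two sinusoids with region-specific phases) with
#' white Gaussian noise; the mix weight `w` of the stochastic part controls
#' regularity, and higher `w` yields higher expected sample entropy.
#'
#' Planted effects: regions listed in `effect_regions` use `effect_mix`
#' instead of `base_mix` in group A, so the two groups differ in complexity
#' exactly there. `coupling` mixes a per-subject global noise series into
#' every voxel's stochastic part (fraction of noise variance shared across
#' regions); giving the groups different coupling plants a global
#' connectivity-topology difference while leaving single-region complexity
#' contrasts alone.
#'
#' @param grid_shape 3D grid dimensions (default `c(12, 12, 12)`).
#' @param n_regions Number of rectangular atlas regions (default 27).
#' @param n_timepoints Time points per subject (default 160).
#' @param tr Repetition time, seconds (default 2).
#' @param n_per_group Subjects per group (default 20).
#' @param effect_regions Region ids with a planted group difference.
#' @param base_mix Baseline stochastic mix weight `w` in \[0, 1\]
#'   (default 0.4).
#' @param effect_mix Mix weight in effect regions for group A, recycled over
#'   `effect_regions` (default 0.9).
#' @param noise_sd SD of additional i.i.d. voxel noise (default 0.1).
#' @param coupling Named length-2 vector in \[0, 1\]: strength of the slow
#'   noise-amplitude envelope shared across regions per group (default
#'   `c(A = 0, B = 0)`, i.e. no shared complexity dynamics). The stochastic
#'   part of each voxel is scaled by `exp(0.8 * coupling * s(t))` where
#'   `s(t)` is a standardized sum of very-low-frequency sinusoids drawn per
#'   subject; windows where the envelope is high are high-entropy for every
#'   voxel sharing it, so entropy sequences co-fluctuate.
#' @param coupling_scope Named length-2 character vector, `"global"` (one
#'   envelope for the whole brain) or `"modular"` (an independent envelope
#'   per module of contiguous regions) per group. A modular group develops
#'   clustered, segregated entropy-sequence networks (higher Cp and Lp,
#'   lower global efficiency at fixed edge count) relative to a globally
#'   coupled one.
#' @param n_modules Number of region modules used by modular coupling
#'   (default: 4, capped at `n_regions`).
#' @param seed Master seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid_shape = c(12L, 12L, 12L), n_regions = 27L,
                           n_timepoints = 160L, tr = 2,
                           n_per_group = 20L,
                           effect_regions = integer(0),
                           base_mix = 0.4, effect_mix = 0.9,
                           noise_sd = 0.1,
                           coupling = c(A = 0, B = 0),
                           coupling_scope = c(A = "global", B = "global"),
                           n_modules = NULL,
                           seed = 1L) {
  if (is.null(n_modules)) n_modules <- min(4L, n_regions)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            n_regions >= 1L, n_regions <= prod(grid_shape),
            n_timepoints >= 2L, tr > 0, n_per_group >= 2L,
            base_mix >= 0, base_mix <= 1,
            all(effect_mix >= 0), all(effect_mix <= 1),
            noise_sd >= 0,
            length(coupling) == 2L, all(coupling >= 0), all(coupling <= 1),
            length(coupling_scope) == 2L,
            all(coupling_scope %in% c("global", "modular")),
            n_modules >= 1L, n_modules <= n_regions)
  effect_regions <- as.integer(effect_regions)
  if (length(effect_regions)) {
    stopifnot(all(effect_regions >= 1L), all(effect_regions <= n_regions))
    effect_mix <- rep_len(effect_mix, length(effect_regions))
  }
  if (is.null(names(coupling))) names(coupling) <- c("A", "B")
  if (is.null(names(coupling_scope))) names(coupling_scope) <- c("A", "B")
  structure(list(grid_shape = as.integer(grid_shape),
                 n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints), tr = tr,
                 n_per_group = as.integer(n_per_group),
                 effect_regions = effect_regions,
                 base_mix = base_mix, effect_mix = effect_mix,
                 noise_sd = noise_sd, coupling = coupling,
                 coupling_scope = coupling_scope,
                 n_modules = as.integer(n_modules),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# near-equal integer partition of `n` into `parts` slab widths
split_slabs <- function(n, parts) {
  base <- n %/% parts
  widths <- rep(base, parts)
  extra <- n - base * parts
  if (extra > 0) widths[seq_len(extra)] <- widths[seq_len(extra)] + 1L
  widths
}

# factor n into 3 integers (each <= the matching grid dim), as cubic as possible
factor3 <- function(n, dims) {
  best <- NULL
  for (a in 1:n) {
    if (n %% a) next
    for (b in 1:(n %/% a)) {
      rem <- n %/% a
      if (rem %% b) next
      cands <- c(a, b, rem %/% b)
      if (any(cands > dims)) next
      score <- max(cands) - min(cands)
      if (is.null(best) || score < best$score) best <- list(f = cands, score = score)
    }
  }
  if (is.null(best)) {
    stop("cannot partition a ", paste(dims, collapse = "x"),
         " grid into ", n, " rectangular regions", call. = FALSE)
  }
  best$f
}

#' Toy rectangular-block parcellation
#'
#' Partitions the grid into `n_regions` contiguous rectangular blocks with
#' ids 1..n_regions (e.g. a 6x6x6 grid with 8 regions gives 8 octants of 27
#' voxels). Deterministic for a given spec; the blocks tile the grid exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return A [parcellation_atlas()] with a 3 mm isotropic affine.
#' @export
generate_atlas_grid <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- spec$grid_shape
  f <- factor3(spec$n_regions, d)
  bx <- rep(seq_len(f[1]), times = split_slabs(d[1], f[1]))
  by <- rep(seq_len(f[2]), times = split_slabs(d[2], f[2]))
  bz <- rep(seq_len(f[3]), times = split_slabs(d[3], f[3]))
  labels <- array(0L, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) {
    labels[, y, z] <- bx + f[1] * (by[y] - 1L) + f[1] * f[2] * (bz[z] - 1L)
  }
  parcellation_atlas(labels, region_ids = seq_len(spec$n_regions),
                     affine = diag(c(3, 3, 3, 1)))
}

# region-wise stochastic mix weights for one group
region_mix <- function(spec, group) {
  w <- rep(spec$base_mix, spec$n_regions)
  if (group == "A" && length(spec$effect_regions)) {
    w[spec$effect_regions] <- spec$effect_mix
  }
  w
}

#' Generate one subject's 4D BOLD image
#'
#' Per voxel in region g: `(1 - w_g) * det_g(t) + w_g * e(t) + noise_sd * z(t)`
#' where `det_g` is a unit-SD sum of two low-frequency sinusoids (0.02 and
#' 0.05 Hz) with region-specific phases fixed by the master seed, `e` is
#' white Gaussian voxel noise optionally amplitude-modulated by the group's
#' shared slow envelope (see [synthetic_spec()]), and `z` is extra i.i.d.
#' voxel noise. Bit-reproducible from `(spec, group, subject_seed)`.
#'
#' @param spec A [synthetic_spec()].
#' @param group `"A"` or `"B"`.
#' @param subject_seed Integer seed for this subject's noise.
#' @return A [bold_series()].
#' @export
generate_subject_bold <- function(spec, group, subject_seed) {
  stopifnot(inherits(spec, "synthetic_spec"), group %in% c("A", "B"))
  d <- spec$grid_shape
  Tn <- spec$n_timepoints
  R <- spec$n_regions
  tsec <- (seq_len(Tn) - 1L) * spec$tr

  phases <- withr::with_seed(spec$seed, {
    list(p1 = stats::runif(R, 0, 2 * pi), p2 = stats::runif(R, 0, 2 * pi))
  })
  det <- vapply(seq_len(R), function(g) {
    s <- sin(2 * pi * 0.02 * tsec + phases$p1[g]) +
      0.5 * sin(2 * pi * 0.05 * tsec + phases$p2[g])
    s / stats::sd(s)
  }, numeric(Tn))                                   # T x R

  atlas <- generate_atlas_grid(spec)
  lab <- as.integer(atlas$labels)
  w <- region_mix(spec, group)
  cpl <- unname(spec$coupling[group])

  scope <- unname(spec$coupling_scope[group])
  # contiguous region-id chunks act as modules for modular coupling
  module_of <- rep(seq_len(spec$n_modules),
                   times = split_slabs(R, spec$n_modules))

  nvox <- prod(d)
  arr <- withr::with_seed(as.integer(subject_seed), {
    # slow envelopes: one per module (column); "global" uses column 1 only
    env_f <- c(0.004, 0.007, 0.011)
    env <- vapply(seq_len(spec$n_modules), function(mo) {
      s <- rowSums(vapply(env_f, function(f)
        sin(2 * pi * f * tsec + stats::runif(1, 0, 2 * pi)), numeric(Tn)))
      s <- s / stats::sd(s)
      exp(0.8 * cpl * s)
    }, numeric(Tn))
    own <- matrix(stats::rnorm(Tn * nvox), Tn, nvox)
    extra <- if (spec$noise_sd > 0) {
      matrix(stats::rnorm(Tn * nvox), Tn, nvox)
    } else NULL
    env_vox <- if (scope == "global") env[, 1L] else
      env[, module_of[lab], drop = FALSE]
    e <- if (cpl > 0) own * env_vox else own
    sig <- det[, lab, drop = FALSE] *
      rep(1 - w[lab], each = Tn) + e * rep(w[lab], each = Tn)
    if (!is.null(extra)) sig <- sig + spec$noise_sd * extra
    array(t(sig), c(nvox, Tn))  # voxel x time
  })
  bold_series(array(arr, c(d, Tn)), affine = diag(c(3, 3, 3, 1)),
              tr = spec$tr)
}

#' Generate a two-group synthetic cohort
#'
#' Draws distinct subject seeds from the master seed and generates
#' `n_per_group` subjects per group, together with the toy atlas, the
#' whole-grid mask, and a ground-truth record of the planted complexity
#' ordering per region.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `dbca_cohort`: `groups` (named list `A`/`B` of
#'   [bold_series()] lists), `atlas`, `mask`, `ground_truth` (tibble:
#'   region, w_A, w_B, expected ordering), `subject_seeds` (tibble), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_per_group
  seeds <- withr::with_seed(spec$seed,
                            sample.int(.Machine$integer.max - 1L, 2L * n))
  subjects <- tibble::tibble(
    subject = c(paste0("A", seq_len(n)), paste0("B", seq_len(n))),
    group = rep(c("A", "B"), each = n),
    seed = seeds)
  groups <- list(
    A = lapply(seq_len(n), function(i)
      generate_subject_bold(spec, "A", seeds[i])),
    B = lapply(seq_len(n), function(i)
      generate_subject_bold(spec, "B", seeds[n + i])))
  wA <- region_mix(spec, "A"); wB <- region_mix(spec, "B")
  gt <- tibble::tibble(
    region = seq_len(spec$n_regions), w_A = wA, w_B = wB,
    expected = dplyr::case_when(wA > wB ~ "A>B", wA < wB ~ "B>A",
                                TRUE ~ "equal"))
  structure(list(groups = groups, atlas = generate_atlas_grid(spec),
                 mask = array(TRUE, spec$grid_shape),
                 ground_truth = gt, subject_seeds = subjects, spec = spec),
            class = "dbca_cohort")
}

#' @export
print.dbca_cohort <- function(x, ...) {
  cat(sprintf(
    "<dbca_cohort> %d + %d subjects, %s grid, %d regions, %d time points\n",
    length(x$groups$A), length(x$groups$B),
    paste(x$spec$grid_shape, collapse = " x "),
    x$spec$n_regions, x$spec$n_timepoints))
  eff <- x$ground_truth[x$ground_truth$expected != "equal", ]
  if (nrow(eff)) {
    cat("  planted effects in region(s):",
        paste(eff$region, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a cohort to disk as NIfTI + JSON
#'
#' One 4D NIfTI per subject, the atlas and mask as 3D NIfTI, and the spec,
#' seeds and ground truth as JSON.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dbca_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(cohort$groups)) {
    for (i in seq_along(cohort$groups[[g]])) {
      b <- cohort$groups[[g]][[i]]
      write_nifti(b$data, b$affine,
                  file.path(dir, sprintf("sub-%s%02d_bold.nii.gz", g, i)),
                  tr = b$tr)
    }
  }
  write_nifti(cohort$atlas$labels, cohort$atlas$affine,
              file.path(dir, "atlas.nii.gz"))
  write_nifti(cohort$mask * 1, cohort$atlas$affine,
              file.path(dir, "mask.nii.gz"))
  meta <- list(spec = unclass(cohort$spec),
               subject_seeds = cohort$subject_seeds,
               ground_truth = cohort$ground_truth)
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
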