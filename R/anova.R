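#' Two-way group-by-threshold ANOVA on network metrics
#'
#' For each graph metric, fits an ordinary fixed-effects two-way ANOVA with
#' factors group and proportional threshold on the subject-by-threshold
#' table, and reports the main-effect p-values (the group main effect is the
#' primary comparison) plus the group-by-threshold cell means. With a single
#' threshold the design reduces to a one-way comparison and the group F
#' statistic equals the squared two-sample t statistic.
#'
#' Each subject contributes one observation per threshold; the ordinary
#' ANOVA treats these as independent, which ignores within-subject
#' correlation across thresholds and is therefore anti-conservative for the
#' group effect. A message flags this.
#'
#' @param metrics A tibble with columns `subject`, `group`, `k` and one
#'   column per metric (e.g. rows of [metrics_over_thresholds()] bound
#'   together with subject/group identifiers).
#' @param metric_cols Metric column names; defaults to the intersection of
#'   `c("cp","lp","gamma","lambda","s","e_glob","e_loc")` with `metrics`.
#' @param interaction Include the group:threshold interaction term
#'   (default TRUE; ignored when a factor has a single level).
#' @param quiet Suppress the anti-conservativeness message.
#' @return An object of class `dbca_anova`: list with `tests` (tibble:
#'   metric, p_group, p_threshold, p_interaction, f_group) and `cell_means`
#'   (tibble: metric, group, k, mean, n).
#' @export
anova_group_threshold <- function(metrics, metric_cols = NULL,
                                  interaction = TRUE, quiet = FALSE) {
  stopifnot(all(c("subject", "group", "k") %in% names(metrics)))
  if (is.null(metric_cols)) {
    metric_cols <- intersect(c("cp", "lp", "gamma", "lambda", "s",
                               "e_glob", "e_loc"), names(metrics))
    metric_cols <- metric_cols[vapply(metric_cols, function(mc)
      !all(is.na(metrics[[mc]])), logical(1))]
  }
  stopifnot(length(metric_cols) >= 1L)
  if (length(unique(metrics$group)) != 2L) {
    stop("exactly 2 groups are required", call. = FALSE)
  }
  # every subject must have a value at every threshold
  counts <- dplyr::count(metrics, .data$subject, .data$k)
  full <- tidyr::expand_grid(subject = unique(metrics$subject),
                             k = unique(metrics$k))
  missing <- dplyr::anti_join(full, counts, by = c("subject", "k"))
  if (nrow(missing) > 0L) {
    stop("missing cells, e.g. subject ", missing$subject[1],
         " at k = ", missing$k[1], call. = FALSE)
  }
  n_thr <- length(unique(metrics$k))
  if (!quiet) {
    message("note: thresholds are treated as independent observations; ",
            "the group test ignores within-subject correlation across K ",
            "and is anti-conservative")
  }
  long <- tidyr::pivot_longer(metrics, dplyr::all_of(metric_cols),
                              names_to = "metric", values_to = "value")
  tests <- purrr::map_dfr(metric_cols, function(mc) {
    dat <- dplyr::filter(long, .data$metric == mc)
    dat$group <- factor(dat$group)
    dat$threshold <- factor(dat$k)
    dat <- dat[!is.na(dat$value), , drop = FALSE]
    if (stats::var(dat$value) < 1e-14 * (1 + mean(dat$value)^2)) {
      warning("metric '", mc, "' is constant across subjects and thresholds; ",
              "ANOVA is degenerate", call. = FALSE)
      return(tibble::tibble(metric = mc, f_group = NA_real_,
                            p_group = NA_real_, p_threshold = NA_real_,
                            p_interaction = NA_real_))
    }
    form <- if (n_thr > 1L) {
      if (interaction) value ~ group * threshold else value ~ group + threshold
    } else {
      value ~ group
    }
    tab <- stats::anova(stats::aov(form, data = dat))
    grab <- function(term, col) {
      i <- match(term, trimws(rownames(tab)))
      if (is.na(i)) NA_real_ else tab[i, col]
    }
    tibble::tibble(metric = mc,
                   f_group = grab("group", "F value"),
                   p_group = grab("group", "Pr(>F)"),
                   p_threshold = grab("threshold", "Pr(>F)"),
                   p_interaction = grab("group:threshold", "Pr(>F)"))
  })
  cell_means <- long |>
    dplyr::group_by(.data$metric, .data$group, .data$k) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(),
                     .groups = "drop")
  structure(list(tests = tests, cell_means = cell_means,
                 n_thresholds = n_thr),
            class = "dbca_anova")
}

#' @export
print.dbca_anova <- function(x, ...) {
  cat("<dbca_anova> two-way group x threshold ANOVA,",
      x$n_thresholds, "threshold(s)\n")
  print(x$tests)
  invisible(x)
}

#' @rdname anova_group_threshold
#' @param x A `dbca_anova` object.
#' @param ... Unused.
#' @export
tidy.dbca_anova <- function(x, ...) x$tests

#' @rdname anova_group_threshold
#' @export
glance.dbca_anova <- function(x, ...) {
  tibble::tibble(n_metrics = nrow(x$tests),
                 n_thresholds = x$n_thresholds,
                 n_significant_group = sum(x$tests$p_group < 0.05,
                                           na.rm = TRUE))
}

#' Cell-mean table in wide (metric by threshold) layout
#'
#' One row per metric and group, one column per threshold — the layout used
#' to tabulate mean network parameters per group across K, with the group
#' main-effect p appended.
#'
#' @param x A `dbca_anova` object.
#' @return A tibble.
#' @export
cell_mean_table <- function(x) {
  stopifnot(inherits(x, "dbca_anova"))
  wide <- tidyr::pivot_wider(x$cell_means, id_cols = c("metric", "group"),
                             names_from = "k", values_from = "mean",
                             names_prefix = "K_")
  dplyr::left_join(wide, dplyr::select(x$tests, "metric", "p_group"),
                   by = "metric")
}
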