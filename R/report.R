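#' Summarize a cohort of preprocessed trials
#'
#' Assembles the headline per-cohort quantities from the other analysis
#' stages: the group-average spatial TPI curve, crossing-count means and
#' parity statistics, wall-proximity (MAD) summaries, and traversal times.
#' Upward traversal time is the elapsed time from the turning point to the
#' last sample with y <= 1; the cohort value is the median pooled over
#' trials (per-individual-first medians available via
#' `pooled_times = FALSE`).
#'
#' @param trials A normalized `ymaze_trials`.
#' @param yc Cul-de-sac boundary.
#' @param pooled_times Pool trials across individuals for the median
#'   traversal time (default), or take the median of per-individual
#'   medians.
#' @return A `cohort_summary` list; `$stats` is a one-row tibble of the
#'   scalar summaries, `$tpi` the group TPI curve, `$p_even` the
#'   per-individual parity table.
#' @export
summarize_cohort <- function(trials, yc = 0.34, pooled_times = TRUE) {
  stopifnot(inherits(trials, "ymaze_trials"))
  ct <- crossing_table(trials, yc = yc)
  pe <- p_even(trials, yc = yc, table = ct)
  pe_nz <- p_even(trials, yc = yc, exclude_zero = TRUE, table = ct)
  curves <- tpi_curves_by_id(trials)
  group_curve <- average_curves(curves)
  mad_up <- mad_score(trials, c(yc, 1))
  mad_dn <- mad_score(trials, c(-1, -yc))
  tt <- trials$trials
  pts <- trials$points
  key <- paste(pts$id, pts$trial, sep = "\r")
  tkey <- paste(tt$id, tt$trial, sep = "\r")
  t_by_trial <- split(pts$t[order(key, pts$k)], key[order(key, pts$k)])
  up_time <- vapply(seq_len(nrow(tt)), function(i) {
    tv <- t_by_trial[[tkey[i]]]
    tv[tt$k_p1m[i]] - tv[tt$k_min[i]]
  }, numeric(1))
  med_time <- if (pooled_times) {
    stats::median(up_time)
  } else {
    stats::median(tapply(up_time, tt$id, stats::median))
  }
  stats <- tibble::tibble(
    group = attr(trials, "group") %||% NA_character_,
    n_individuals = length(unique(tt$id)),
    n_trials = nrow(tt),
    mean_n_post = mean(ct$n_post),
    sd_n_post = stats::sd(ct$n_post),
    mean_n_culdesac = mean(ct$n_culdesac),
    sd_n_culdesac = stats::sd(ct$n_culdesac),
    pct_even = 100 * mean(ct$n_post %% 2 == 0),
    pct_zero_crossing = 100 * mean(ct$n_post == 0),
    sign_test_p = sample_sign_test(pe$p_even),
    pct_peven_above_half = 100 * mean(pe$p_even > 0.5, na.rm = TRUE),
    mad_up_median = stats::median(mad_up$mad, na.rm = TRUE),
    mad_down_median = stats::median(mad_dn$mad, na.rm = TRUE),
    median_up_time_s = med_time
  )
  structure(list(stats = stats, tpi = group_curve, p_even = pe,
                 p_even_excluding_zero = pe_nz, mad_up = mad_up,
                 mad_down = mad_dn, crossings = ct,
                 up_time = tibble::tibble(id = tt$id, trial = tt$trial,
                                          up_time = up_time)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    paste0("cohort `%s`: %d individuals, %d trials\n",
           "  crossings post cul-de-sac %.2f+-%.2f, within %.2f+-%.2f\n",
           "  %% even %.1f, %% zero-crossing %.1f, sign-test p %.3g\n",
           "  MAD up %.3f, median up-traversal %.2f s\n"),
    s$group, s$n_individuals, s$n_trials, s$mean_n_post, s$sd_n_post,
    s$mean_n_culdesac, s$sd_n_culdesac, s$pct_even, s$pct_zero_crossing,
    s$sign_test_p, s$mad_up_median, s$median_up_time_s))
  invisible(x)
}

#' Compare two cohorts
#'
#' One row per comparison, naming the test and the correction: rank-sum
#' tests on per-individual MAD scores, PEven values and per-trial upward
#' traversal times, plus the ratio of mean post-cul-de-sac crossing
#' counts. P-values are Bonferroni-corrected across the family by default.
#'
#' @param a,b `cohort_summary` objects from [summarize_cohort()].
#' @param correction A [stats::p.adjust()] method, default `"bonferroni"`;
#'   `"none"` disables correction.
#' @return A tibble `comparison`, `test`, `statistic`, `p`, `p_adj`,
#'   `correction`.
#' @export
compare_cohorts <- function(a, b, correction = "bonferroni") {
  stopifnot(inherits(a, "cohort_summary"), inherits(b, "cohort_summary"))
  rows <- list()
  add <- function(name, test, stat, p) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      comparison = name, test = test, statistic = stat, p = p)
  }
  w <- compare_groups(a$mad_up$mad, b$mad_up$mad)
  add("mad_up", "wilcoxon rank-sum, two-sided", w$statistic, w$p_value)
  w <- compare_groups(a$p_even$p_even, b$p_even$p_even)
  add("p_even", "wilcoxon rank-sum, two-sided", w$statistic, w$p_value)
  w <- compare_groups(a$up_time$up_time, b$up_time$up_time)
  add("up_time", "wilcoxon rank-sum, two-sided", w$statistic, w$p_value)
  ratio <- a$stats$mean_n_post / b$stats$mean_n_post
  add("mean_n_post_ratio", "ratio of means (a/b)", ratio, NA_real_)
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = correction)
  out$correction <- correction
  out
}
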