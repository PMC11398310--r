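#' Wall-proximity score: median absolute deviation from the midline
#'
#' For each individual, pools every sample whose signed y lies strictly
#' inside the window and takes the median of |x|, the absolute deviation
#' from the arm's horizontal midline x = 0 (not from the sample median:
#' the midline is the meaningful reference for wall proximity). The
#' default window, 0.34 < y < 1, covers the upward traversal from
#' cul-de-sac exit to the intersection; the mirrored window
#' (-1, -0.34) scores the downward traversal.
#'
#' @param trials A normalized `ymaze_trials`.
#' @param y_window Length-2 numeric window (open interval) on signed y.
#' @return A tibble `id`, `mad`, `n_samples`; individuals with no samples
#'   in the window get `NA`.
#' @export
mad_score <- function(trials, y_window = c(0.34, 1)) {
  stopifnot(length(y_window) == 2, y_window[1] < y_window[2])
  pts <- trials$points
  sel <- pts$y > y_window[1] & pts$y < y_window[2]
  ids <- unique(trials$trials$id)
  med <- tapply(abs(pts$x[sel]), pts$id[sel], stats::median)
  cnt <- tapply(pts$x[sel], pts$id[sel], length)
  tibble::tibble(id = ids,
                 mad = as.numeric(med[ids]),
                 n_samples = as.integer(cnt[ids]) %|NA|% 0L)
}

#' Split individuals into extreme low/high groups by a score
#'
#' @param scores A tibble with columns `id` and a score column (second
#'   column by default), e.g. from [mad_score()].
#' @param k Group size; alternatively `frac` gives a quantile fraction
#'   (e.g. 0.2 for quintile groups). Ties are broken by stable id order.
#' @param frac Optional fraction of individuals per group.
#' @return A list with `low` and `high` character id vectors, disjoint and
#'   of size `k` each.
#' @export
split_extreme_groups <- function(scores, k = NULL, frac = NULL) {
  score_col <- setdiff(names(scores), "id")[1]
  df <- scores[!is.na(scores[[score_col]]), , drop = FALSE]
  n <- nrow(df)
  if (is.null(k)) {
    if (is.null(frac)) stop("give either `k` or `frac`", call. = FALSE)
    k <- floor(n * frac)
  }
  if (2 * k > n) {
    stop(sprintf("cannot split %d individuals into two groups of %d", n, k),
         call. = FALSE)
  }
  ord <- order(df[[score_col]], df$id)
  list(low = df$id[ord[seq_len(k)]],
       high = df$id[ord[seq(n - k + 1L, n)]])
}

#' MAD conditioned on the post-cul-de-sac crossing count
#'
#' Stratifies trials by their number of post-cul-de-sac midline-crossings
#' and computes the window MAD within each stratum (pooled over the
#' stratum's samples), with a bootstrap-free SEM proxy from per-trial
#' medians. Empty strata are undefined, not zero.
#'
#' @inheritParams mad_score
#' @param yc Cul-de-sac boundary for the crossing count.
#' @param max_k Strata `0..max_k` are reported (counts above `max_k` are
#'   pooled into the last stratum).
#' @return A tibble `k`, `mad`, `sem`, `n_trials`.
#' @export
mad_given_crossings <- function(trials, y_window = c(0.34, 1), yc = 0.34,
                                max_k = 8L) {
  ct <- crossing_table(trials, yc = yc)
  kk <- pmin(ct$n_post, max_k)
  pts <- trials$points
  sel <- pts$y > y_window[1] & pts$y < y_window[2]
  pts <- pts[sel, , drop = FALSE]
  key <- paste(pts$id, pts$trial, sep = "\r")
  ckey <- paste(ct$id, ct$trial, sep = "\r")
  strat <- kk[match(key, ckey)]
  per_trial_med <- tapply(abs(pts$x), key, stats::median)
  trial_strat <- kk[match(names(per_trial_med), ckey)]
  dplyr::bind_rows(lapply(0:max_k, function(s) {
    xs <- abs(pts$x[strat == s & !is.na(strat)])
    med_tr <- per_trial_med[trial_strat == s & !is.na(trial_strat)]
    tibble::tibble(
      k = s,
      mad = if (length(xs)) stats::median(xs) else NA_real_,
      sem = if (length(med_tr) > 1) {
        stats::sd(med_tr) / sqrt(length(med_tr))
      } else {
        NA_real_
      },
      n_trials = length(med_tr)
    )
  }))
}

#' Rank-sum comparison of two samples
#'
#' Two-sided Wilcoxon rank-sum test for a difference in medians.
#'
#' @param values_a,values_b Numeric samples.
#' @return A list with `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_groups <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  w <- stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                          exact = FALSE, correct = TRUE)
  list(statistic = unname(w$statistic), p_value = w$p.value,
       n_a = length(values_a), n_b = length(values_b))
}

#' Pearson correlation between two per-individual scores
#'
#' @param values_a,values_b Numeric vectors of equal length (pairs with
#'   missing values are dropped).
#' @return A list with `r`, `p_value`, `n`.
#' @export
correlate <- function(values_a, values_b) {
  ok <- stats::complete.cases(values_a, values_b)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  ct <- stats::cor.test(values_a[ok], values_b[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
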