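#' Detect midline-crossings in a lateral position sequence
#'
#' A crossing occurs between consecutive samples whose x-positions have
#' opposite sign. Samples lying exactly on the midline (x = 0) are skipped:
#' a run of zeros between opposite signs counts as one crossing, between
#' equal signs as none. The crossing is attributed to the first (earlier)
#' non-zero sample of the sign-change pair, so no interpolation is needed
#' and results are reproducible bit-exactly.
#'
#' @param x Numeric vector of centred lateral positions.
#' @return Integer indices of the samples at which crossings occur; empty
#'   for sequences shorter than 2.
#' @export
detect_crossings <- function(x) {
  if (length(x) < 2) return(integer(0))
  nz <- which(x != 0 & !is.na(x))
  if (length(nz) < 2) return(integer(0))
  s <- sign(x[nz])
  ch <- which(s[-length(s)] * s[-1] == -1)
  nz[ch]
}

#' Per-trial midline-crossing records
#'
#' For every trial: all crossing locations, counts by maze region
#' (cul-de-sac `|y| <= yc`, post-cul-de-sac `y > yc` through the end of
#' the trial, down-arm `y < -yc`), the parity of the post-cul-de-sac
#' count, the y-location of the last crossing of the whole trial (LMC),
#' and the side of x at cul-de-sac exit (the first sample with `y > yc`).
#'
#' @param trials A normalized `ymaze_trials`.
#' @param yc Cul-de-sac boundary in normalized units.
#' @return A tibble with one row per trial: `id`, `trial`, `turn`,
#'   `n_total`, `n_culdesac`, `n_post`, `n_down`, `parity_post`
#'   (`"even"`/`"odd"`), `lmc_y` (`NA` when the trial never crosses),
#'   `exit_side` (`"left"`/`"right"`/`NA`). Crossing y-locations are
#'   attached as a list-column `cross_y`.
#' @export
crossing_table <- function(trials, yc = 0.34) {
  stopifnot(inherits(trials, "ymaze_trials"))
  pts <- trials$points
  by_trial <- split(pts[, c("k", "x", "y")],
                    paste(pts$id, pts$trial, sep = "\r"))
  tt <- trials$trials
  key <- paste(tt$id, tt$trial, sep = "\r")
  rows <- lapply(key, function(kk) {
    p <- by_trial[[kk]]
    p <- p[order(p$k), , drop = FALSE]
    idx <- detect_crossings(p$x)
    cy <- p$y[idx]
    n_post <- sum(cy > yc)
    up <- which(p$y > yc)
    exit_side <- NA_character_
    if (length(up)) {
      xs <- p$x[up]
      nz <- xs[xs != 0]
      if (length(nz)) exit_side <- if (nz[1] > 0) "right" else "left"
    }
    tibble::tibble(
      n_total = length(idx),
      n_culdesac = sum(abs(cy) <= yc),
      n_post = n_post,
      n_down = sum(cy < -yc),
      parity_post = if (n_post %% 2 == 0) "even" else "odd",
      lmc_y = if (length(cy)) cy[length(cy)] else NA_real_,
      exit_side = exit_side,
      cross_y = list(cy)
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_cols(tt[, c("id", "trial", "turn")], out)
}

#' Count crossings in a maze region
#'
#' @param trials A normalized `ymaze_trials` (or a precomputed
#'   [crossing_table()] passed via `table`).
#' @param region One of `"culdesac"`, `"post_culdesac"`, `"down_arm"`,
#'   `"whole"`. Regions are attributed by the y-location of the crossing;
#'   the three sub-regions partition the whole-trial count.
#' @param yc Cul-de-sac boundary.
#' @param table Optional precomputed crossing table.
#' @return Integer vector of per-trial counts, in crossing-table order.
#' @export
count_region <- function(trials, region = c("post_culdesac", "culdesac",
                                            "down_arm", "whole"),
                         yc = 0.34, table = NULL) {
  region <- match.arg(region)
  ct <- table %||% crossing_table(trials, yc = yc)
  switch(region,
         culdesac = ct$n_culdesac,
         post_culdesac = ct$n_post,
         down_arm = ct$n_down,
         whole = ct$n_total)
}

parity_summary_one <- function(counts) {
  n <- length(counts)
  if (!n) {
    return(list(p_even = NA_real_, n_trials = 0L, binom_p = NA_real_))
  }
  ev <- sum(counts %% 2 == 0)
  list(p_even = ev / n, n_trials = n,
       binom_p = stats::binom.test(ev, n, 0.5,
                                   alternative = "two.sided")$p.value)
}

#' Per-individual even-parity probability (PEven)
#'
#' PEven is the fraction of an individual's trials with an even number of
#' midline-crossings in the chosen region (post-cul-de-sac by default,
#' counting zero as even). Each individual also gets a two-sided exact
#' binomial test against 0.5. With `exclude_zero = TRUE` only trials with
#' at least one crossing in the region qualify, probing whether the parity
#' bias survives beyond pure wall-hugging (zero-crossing) trials.
#'
#' @inheritParams count_region
#' @param exclude_zero Restrict to trials with >= 1 crossing in the region.
#' @return A tibble with one row per individual: `id`, `n_trials`,
#'   `p_even`, `binom_p`. Individuals with no qualifying trials get `NA`.
#' @export
p_even <- function(trials, region = "post_culdesac", yc = 0.34,
                   exclude_zero = FALSE, table = NULL) {
  ct <- table %||% crossing_table(trials, yc = yc)
  counts <- count_region(NULL, region = region, yc = yc, table = ct)
  df <- tibble::tibble(id = ct$id, n = counts)
  if (exclude_zero) df <- df[df$n >= 1, , drop = FALSE]
  ids <- unique(ct$id)
  dplyr::bind_rows(lapply(ids, function(ind) {
    s <- parity_summary_one(df$n[df$id == ind])
    tibble::tibble(id = ind, n_trials = s$n_trials, p_even = s$p_even,
                   binom_p = s$binom_p)
  }))
}

#' Two-sided sign test of per-individual values against a null
#'
#' Standard sign test: values equal to the null are dropped, and the count
#' of values above it is referred to an exact Binomial(n, 1/2).
#'
#' @param values Numeric vector (e.g. per-individual PEven values).
#' @param null Null location, default 0.5.
#' @return Two-sided p-value, or `NA` if every value ties the null.
#' @export
sample_sign_test <- function(values, null = 0.5) {
  values <- values[!is.na(values)]
  values <- values[values != null]
  if (!length(values)) return(NA_real_)
  k <- sum(values > null)
  stats::binom.test(k, length(values), 0.5,
                    alternative = "two.sided")$p.value
}

#' Distribution of last midline-crossing locations
#'
#' Histogram of the y-location of each trial's final crossing, normalized
#' to unit mass over the trials that have at least one crossing; trials
#' without crossings are tallied separately.
#'
#' @inheritParams count_region
#' @param breaks Numeric vector of histogram bin edges over y.
#' @return A list with `hist` (tibble `lo`, `hi`, `n`, `mass`),
#'   `n_with_lmc`, and `n_no_lmc`.
#' @export
lmc_distribution <- function(trials, breaks = seq(-1.3, 1.3, by = 0.05),
                             yc = 0.34, table = NULL) {
  ct <- table %||% crossing_table(trials, yc = yc)
  lmc <- ct$lmc_y[!is.na(ct$lmc_y)]
  n_no <- sum(is.na(ct$lmc_y))
  h <- graphics::hist(lmc[lmc >= min(breaks) & lmc <= max(breaks)],
                      breaks = breaks, plot = FALSE)
  mass <- if (length(lmc)) h$counts / length(lmc) else h$counts * NA_real_
  list(hist = tibble::tibble(lo = breaks[-length(breaks)], hi = breaks[-1],
                             n = h$counts, mass = mass),
       n_with_lmc = length(lmc), n_no_lmc = n_no)
}

#' Parity fraction at continuously varying scoring positions
#'
#' For each threshold position `Y*` above the cul-de-sac boundary, counts
#' the crossings each trial makes with `yc < y <= Y*` and reports the
#' fraction of trials with an even count. A genuine parity tendency keeps
#' the fraction above 0.5 across thresholds, whereas a characteristic
#' crossing wavelength makes it oscillate with the threshold.
#'
#' @inheritParams count_region
#' @param thresholds Increasing positions, all strictly above `yc`.
#' @return A tibble `threshold`, `frac_even`, `n_trials`.
#' @export
crossing_scan <- function(trials, thresholds, yc = 0.34, table = NULL) {
  if (any(thresholds <= yc)) {
    stop("all scan thresholds must exceed the cul-de-sac boundary yc",
         call. = FALSE)
  }
  ct <- table %||% crossing_table(trials, yc = yc)
  post_y <- lapply(ct$cross_y, function(cy) sort(cy[cy > yc]))
  counts <- vapply(post_y, function(v) findInterval(thresholds, v),
                   numeric(length(thresholds)))
  counts <- matrix(counts, nrow = length(thresholds))
  tibble::tibble(
    threshold = thresholds,
    frac_even = rowMeans(counts %% 2 == 0),
    n_trials = ncol(counts)
  )
}

#' Interval-resampling null for crossing parity
#'
#' Destroys any dependence between consecutive midline-crossings while
#' preserving their spacing statistics: for each individual, the gaps
#' between successive post-cul-de-sac crossings (pooled over trials with
#' at least two of them) are resampled with replacement to rebuild
#' synthetic crossing sequences, starting at the cul-de-sac exit and
#' truncated at each trial's own maximal y. PEven recomputed on the
#' rebuilt sequences yields a null distribution against which the observed
#' PEven is located.
#'
#' @inheritParams count_region
#' @param n_resamples Number of resampled cohorts per individual.
#' @param seed Optional integer seed.
#' @return A list with `summary` (tibble: `id`, `observed`, `null_mean`,
#'   `q_upper` = fraction of null values >= observed, `q_lower`) and
#'   `null` (tibble of all resampled PEven values). Individuals whose
#'   interval pool is empty are skipped and listed in `skipped`.
#' @export
resample_interval_null <- function(trials, n_resamples = 1000, yc = 0.34,
                                   seed = NULL, table = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ct <- table %||% crossing_table(trials, yc = yc)
  pts <- trials$points
  ymax <- tapply(pts$y, paste(pts$id, pts$trial, sep = "\r"), max)
  key <- paste(ct$id, ct$trial, sep = "\r")
  spans <- pmax(as.numeric(ymax[key]) - yc, 0)
  summaries <- list()
  nulls <- list()
  skipped <- character()
  for (ind in unique(ct$id)) {
    sel <- ct$id == ind
    pool <- unlist(lapply(ct$cross_y[sel], function(cy) {
      v <- sort(cy[cy > yc])
      if (length(v) >= 2) diff(v) else numeric(0)
    }))
    pool <- pool[pool > 0]
    if (!length(pool)) {
      skipped <- c(skipped, ind)
      next
    }
    obs <- mean(ct$n_post[sel] %% 2 == 0)
    sp <- spans[sel]
    nt <- length(sp)
    max_span <- max(sp)
    k0 <- min(500L, max(16L, ceiling(max_span / min(pool)) + 2L))
    pe <- numeric(n_resamples)
    for (r in seq_len(n_resamples)) {
      draws <- matrix(sample(pool, k0 * nt, replace = TRUE), nrow = k0)
      cum <- apply(draws, 2, cumsum)
      counts <- colSums(cum <= rep(sp, each = k0))
      short <- which(cum[k0, ] <= sp) # pool exhausted before arm end
      for (j in short) {
        tot <- cum[k0, j]
        while (tot <= sp[j]) {
          d <- sample(pool, 1)
          tot <- tot + d
          if (tot <= sp[j]) counts[j] <- counts[j] + 1
        }
      }
      pe[r] <- mean(counts %% 2 == 0)
    }
    summaries[[length(summaries) + 1L]] <- tibble::tibble(
      id = ind, observed = obs, null_mean = mean(pe),
      q_upper = mean(pe >= obs), q_lower = mean(pe <= obs))
    nulls[[length(nulls) + 1L]] <- tibble::tibble(
      id = ind, resample = seq_len(n_resamples), p_even = pe)
  }
  list(summary = dplyr::bind_rows(summaries), null = dplyr::bind_rows(nulls),
       skipped = skipped)
}
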