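#' Binning schemes for TPI curves
#'
#' The spatial domain uses 26 equal y-bins of width 0.1 spanning
#' \[-1.3, 1.3\]; the temporal domain uses 17 equal relative-time bins of
#' width 0.075 for the downward phase (-1.275 to 0) and 17 for the upward
#' phase (0 to 1.275). Bin membership is inclusive at both edges.
#'
#' @param domain `"spatial"` or `"temporal"`.
#' @param edges Optional numeric vector of strictly increasing custom bin
#'   edges (overrides the default).
#' @return A tibble with columns `bin`, `lo`, `hi` and attribute `domain`.
#' @export
binning_scheme <- function(domain = c("spatial", "temporal"), edges = NULL) {
  domain <- match.arg(domain)
  if (is.null(edges)) {
    edges <- if (domain == "spatial") {
      seq(-1.3, 1.3, by = 0.1)
    } else {
      c(seq(-1.275, 0, by = 0.075), seq(0.075, 1.275, by = 0.075))
    }
  }
  if (any(diff(edges) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(bin = seq_len(length(edges) - 1L),
                        lo = edges[-length(edges)], hi = edges[-1])
  attr(out, "domain") <- domain
  out
}

#' Side of the trial-average lateral position within a range
#'
#' For each trial, averages the centred x-position over the samples whose
#' y (spatial domain) or relative time (temporal domain) falls inside
#' `[lo, hi]` (inclusive), and reports which side of the midline that
#' average lies on. Trials with no samples in the range are `"absent"`;
#' a mean of exactly zero is a `"tie"` (excluded from TPI conditionals).
#'
#' @param trials A normalized `ymaze_trials`.
#' @param lo,hi Range bounds; `lo < hi` required.
#' @param domain `"spatial"` or `"temporal"`.
#' @return A tibble with one row per trial: `id`, `trial`, `side`
#'   (`"left"`, `"right"`, `"absent"`, `"tie"`), `turn`.
#' @export
side_in_range <- function(trials, lo, hi, domain = c("spatial", "temporal")) {
  domain <- match.arg(domain)
  if (!(lo < hi)) stop("empty range: need lo < hi", call. = FALSE)
  pts <- trials$points
  v <- if (domain == "spatial") pts$y else pts$t_rel
  sel <- v >= lo & v <= hi
  key <- paste(pts$id, pts$trial, sep = "\r")
  mx <- tapply(pts$x[sel], key[sel], mean)
  tt <- trials$trials
  tkey <- paste(tt$id, tt$trial, sep = "\r")
  m <- mx[tkey]
  side <- ifelse(is.na(m), "absent",
                 ifelse(m > 0, "right", ifelse(m < 0, "left", "tie")))
  tibble::tibble(id = tt$id, trial = tt$trial, side = unname(side),
                 turn = tt$turn, mean_x = unname(as.numeric(m)))
}

#' TPI for one bin
#'
#' The Turn Predictiveness Index of a set of trials over a range is the
#' difference between two conditional probabilities: the probability of a
#' right turn given that the trial-average lateral position in the range
#' was right of the midline, minus the same probability given it was left
#' of the midline. Equivalently (counting form) it is
#' `n(right-side & right-turn)/n(right-side) - n(left-side & right-turn)/n(left-side)`.
#' Both forms are implemented; they agree on every input and the choice is
#' exposed for cross-checking. Ties and absent trials enter neither
#' conditional. If either side has no trials the TPI is undefined (`NA`),
#' never zero.
#'
#' @param sides Character vector of per-trial sides
#'   (`"left"`/`"right"`/`"absent"`/`"tie"`), e.g. from [side_in_range()].
#' @param turns Character vector of per-trial turn outcomes
#'   (`"left"`/`"right"`).
#' @param method `"conditional"` (probability difference) or `"counting"`.
#' @return A list with `tpi`, `n_pos`, `n_neg` (trial counts on the right
#'   and left side) and `se`, the standard error of a difference of two
#'   independent binomial proportions.
#' @export
tpi_bin <- function(sides, turns, method = c("conditional", "counting")) {
  method <- match.arg(method)
  stopifnot(length(sides) == length(turns))
  pos <- sides == "right"
  neg <- sides == "left"
  n_pos <- sum(pos)
  n_neg <- sum(neg)
  if (n_pos == 0 || n_neg == 0) {
    return(list(tpi = NA_real_, n_pos = n_pos, n_neg = n_neg, se = NA_real_))
  }
  if (method == "conditional") {
    p_r <- mean(turns[pos] == "right")
    p_l <- mean(turns[neg] == "right")
    tpi <- p_r - p_l
  } else {
    nR_pos <- sum(pos & turns == "right")
    nR_neg <- sum(neg & turns == "right")
    tpi <- nR_pos / n_pos - nR_neg / n_neg
    p_r <- nR_pos / n_pos
    p_l <- nR_neg / n_neg
  }
  se <- sqrt(p_r * (1 - p_r) / n_pos + p_l * (1 - p_l) / n_neg)
  list(tpi = tpi, n_pos = n_pos, n_neg = n_neg, se = se)
}

#' TPI tail values
#'
#' The negative-infinity tail evaluates the TPI at the first data point
#' considered in each trial, where the side indicator is fixed by the arm
#' the subject arrived from (+1 right arm, -1 left arm). It therefore
#' measures the tendency to repeat (+) or alternate (-) turn directions:
#' `P(right turn | previous turn right) - P(right turn | previous turn left)`.
#' The positive-infinity tail evaluates it at the last data point, where
#' the lateral position defines the turn outcome, so it equals 1 by
#' definition.
#'
#' @param trials A `ymaze_trials` with `prev_arm` and `turn` labels.
#' @return A list with `tail_minus` (`NA` when all trials share one
#'   previous arm) and `tail_plus` (always 1).
#' @export
tpi_tails <- function(trials) {
  tt <- trials$trials
  side <- ifelse(tt$prev_arm == "right", "right",
                 ifelse(tt$prev_arm == "left", "left", "absent"))
  b <- tpi_bin(side, tt$turn)
  list(tail_minus = b$tpi, tail_plus = 1)
}

#' TPI curve over a binning scheme
#'
#' Computes [tpi_bin()] over every bin of the scheme for one set of trials
#' (typically one individual); bins where one side is unpopulated are
#' carried as `NA`, not imputed. Tail values from [tpi_tails()] are
#' attached as attributes.
#'
#' @param trials A normalized `ymaze_trials`.
#' @param scheme A [binning_scheme()]; defaults to the domain's standard
#'   scheme.
#' @param domain `"spatial"` or `"temporal"`.
#' @param method Passed to [tpi_bin()].
#' @return A tibble with one row per bin (`bin`, `lo`, `hi`, `tpi`,
#'   `n_pos`, `n_neg`, `se`) and attributes `domain`, `tail_minus`,
#'   `tail_plus`.
#' @export
tpi_curve <- function(trials, scheme = NULL, domain = c("spatial", "temporal"),
                      method = c("conditional", "counting")) {
  domain <- match.arg(domain)
  method <- match.arg(method)
  if (is.null(scheme)) scheme <- binning_scheme(domain)
  if (n_trials(trials) < 1) stop("no trials", call. = FALSE)
  rows <- lapply(seq_len(nrow(scheme)), function(j) {
    s <- side_in_range(trials, scheme$lo[j], scheme$hi[j], domain)
    b <- tpi_bin(s$side, s$turn, method = method)
    tibble::tibble(bin = scheme$bin[j], lo = scheme$lo[j], hi = scheme$hi[j],
                   tpi = b$tpi, n_pos = b$n_pos, n_neg = b$n_neg, se = b$se)
  })
  out <- dplyr::bind_rows(rows)
  tails <- tpi_tails(trials)
  attr(out, "domain") <- domain
  attr(out, "tail_minus") <- tails$tail_minus
  attr(out, "tail_plus") <- tails$tail_plus
  out
}

#' Per-individual TPI curves
#'
#' @inheritParams tpi_curve
#' @return A tibble of stacked per-individual curves with an `id` column
#'   (tails included as columns `tail_minus`, `tail_plus`).
#' @export
tpi_curves_by_id <- function(trials, scheme = NULL,
                             domain = c("spatial", "temporal")) {
  domain <- match.arg(domain)
  if (is.null(scheme)) scheme <- binning_scheme(domain)
  ids <- unique(trials$trials$id)
  dplyr::bind_rows(lapply(ids, function(ind) {
    cur <- tpi_curve(filter_individuals(trials, ind), scheme, domain)
    cur$id <- ind
    cur$tail_minus <- attr(cur, "tail_minus")
    cur$tail_plus <- attr(cur, "tail_plus")
    cur
  }))
}

#' Average per-individual TPI curves into a group curve
#'
#' Per bin, the unweighted mean over the individuals with a defined value
#' there, with the standard error of that mean and the contributing count.
#' Bins defined for no individual stay undefined.
#'
#' @param curves Stacked per-individual curves from [tpi_curves_by_id()].
#' @return A tibble with `bin`, `lo`, `hi`, `tpi`, `sem`, `n_ids`, plus
#'   group-mean tails in attributes `tail_minus`, `tail_plus`.
#' @export
average_curves <- function(curves) {
  grp <- dplyr::group_by(curves, .data$bin, .data$lo, .data$hi)
  out <- dplyr::summarise(
    grp,
    n_ids = sum(!is.na(.data$tpi)),
    sem = ifelse(sum(!is.na(.data$tpi)) > 1,
                 stats::sd(.data$tpi, na.rm = TRUE) /
                   sqrt(sum(!is.na(.data$tpi))), NA_real_),
    tpi = ifelse(sum(!is.na(.data$tpi)) > 0,
                 mean(.data$tpi, na.rm = TRUE), NA_real_),
    .groups = "drop"
  )
  out <- out[, c("bin", "lo", "hi", "tpi", "sem", "n_ids")]
  per_id <- dplyr::distinct(curves, .data$id, .data$tail_minus,
                            .data$tail_plus)
  attr(out, "tail_minus") <- mean(per_id$tail_minus, na.rm = TRUE)
  attr(out, "tail_plus") <- mean(per_id$tail_plus, na.rm = TRUE)
  out
}

#' Mirror a trial set about the arm midline
#'
#' Negates every x-position; optionally also swaps the left/right turn and
#' previous-arm labels. Useful for symmetry checks: x-negation alone flips
#' the sign of every TPI bin, x-negation plus label swap leaves TPI
#' invariant.
#'
#' @param trials A `ymaze_trials`.
#' @param swap_labels Also swap `turn` and `prev_arm` labels?
#' @return The mirrored `ymaze_trials`.
#' @export
mirror_trials <- function(trials, swap_labels = FALSE) {
  out <- trials
  out$points$x <- -out$points$x
  if (swap_labels) {
    sw <- function(v) ifelse(v == "left", "right",
                             ifelse(v == "right", "left", v))
    out$trials$turn <- sw(out$trials$turn)
    out$trials$prev_arm <- sw(out$trials$prev_arm)
  }
  out
}
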