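new_trials <- function(trials, points, normalized, frame_rate, species, group) {
  structure(
    list(trials = tibble::as_tibble(trials),
         points = tibble::as_tibble(points)),
    normalized = normalized, frame_rate = frame_rate, species = species,
    group = group, class = "ymaze_trials"
  )
}

#' @export
print.ymaze_trials <- function(x, ...) {
  cat(sprintf(
    "ymaze_trials: %d trials from %d individual(s), %s coordinates (%s, %s)\n",
    nrow(x$trials), length(unique(x$trials$id)),
    if (isTRUE(attr(x, "normalized"))) "normalized" else "raw",
    attr(x, "species") %||% "?", attr(x, "group") %||% "?"))
  invisible(x)
}

#' Number of trials in a trials object
#' @param trials A `ymaze_trials` object.
#' @return Integer trial count.
#' @export
n_trials <- function(trials) nrow(trials$trials)

#' Segment raw tracks into bottom-arm trials
#'
#' A trial spans all the movement from the moment an individual enters the
#' bottom arm (its first bottom-arm sample after occupying the left or
#' right arm) until it exits into the left or right arm; intervening
#' intersection samples belong to the trial, the first sample inside the
#' destination arm does not. The arm occupied before entry gives
#' `prev_arm`; the destination arm gives `turn`. Every candidate traversal
#' is kept and flagged, so exclusion accounting stays explicit:
#' `reached_bottom` (the track got into the cul-de-sac region, deeper than
#' `reach_depth`), `has_gap` (missing samples inside the trial), `in_maze`
#' (no out-of-maze coordinates).
#'
#' @param tr A `ymaze_tracks` object.
#' @param geom A [maze_geometry()].
#' @param reach_depth Raw depth (arena units from the centre) a trial must
#'   reach to count as having visited the bottom of the arm; defaults to
#'   the start of the cul-de-sac cap, `geom$arm_length`.
#' @return A `ymaze_trials` object in raw coordinates.
#' @export
segment_trials <- function(tr, geom, reach_depth = NULL) {
  stopifnot(inherits(tr, "ymaze_tracks"), inherits(geom, "maze_geometry"))
  reach_depth <- reach_depth %||% geom$arm_length
  frame_rate <- attr(tr, "frame_rate")
  trials_out <- list()
  points_out <- list()
  trial_no <- 0L
  for (ind in unique(tr$id)) {
    d <- tr[tr$id == ind, , drop = FALSE]
    lab <- maze_arm(geom, d$x, d$y)
    armish <- which(lab %in% c("bottom", "left", "right"))
    if (!length(armish)) next
    r <- rle(lab[armish])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] != "bottom") next
      if (j == 1L || j == length(r$values)) next # unknown prev arm or no exit
      prev_arm <- r$values[j - 1L]
      turn <- r$values[j + 1L]
      i_start <- armish[starts[j]]
      i_exit <- armish[ends[j] + 1L] # first sample inside destination arm
      rows <- i_start:(i_exit - 1L)
      trial_no <- trial_no + 1L
      pts <- d[rows, c("t", "x", "y")]
      depth <- -pts$y
      trials_out[[trial_no]] <- tibble::tibble(
        id = ind, trial = trial_no, prev_arm = prev_arm, turn = turn,
        reached_bottom = max(depth) >= reach_depth,
        has_gap = any(d$gap_before[rows[-1]]),
        in_maze = !anyNA(lab[rows])
      )
      points_out[[trial_no]] <- tibble::tibble(
        id = ind, trial = trial_no, k = seq_along(rows),
        t = pts$t, x = pts$x, y = pts$y
      )
    }
  }
  if (!trial_no) {
    return(new_trials(
      tibble::tibble(id = character(), trial = integer(),
                     prev_arm = character(), turn = character(),
                     reached_bottom = logical(), has_gap = logical(),
                     in_maze = logical()),
      tibble::tibble(id = character(), trial = integer(), k = integer(),
                     t = numeric(), x = numeric(), y = numeric()),
      FALSE, frame_rate, attr(tr, "species"), attr(tr, "group")))
  }
  new_trials(dplyr::bind_rows(trials_out), dplyr::bind_rows(points_out),
             FALSE, frame_rate, attr(tr, "species"), attr(tr, "group"))
}

#' Apply the trial- and individual-level exclusion rules
#'
#' Drops trials that failed to reach the bottom of the arm, trials with
#' missing samples, and trials containing out-of-maze coordinates (the
#' individual is kept); then drops individuals with fewer than `min_trials`
#' valid trials. Every step is itemized in the report.
#'
#' @param trials A raw `ymaze_trials` from [segment_trials()].
#' @param min_trials Minimum valid trials per individual. Defaults by
#'   species: 80 for flies and agents, 28 for humans.
#' @return A list with `trials` (filtered) and `report` (an exclusion
#'   report list with non-increasing counts along the filter chain and the
#'   excluded ids with reasons).
#' @export
apply_exclusions <- function(trials, min_trials = NULL) {
  stopifnot(inherits(trials, "ymaze_trials"))
  species <- attr(trials, "species") %||% "fly"
  if (is.null(min_trials)) {
    min_trials <- c(fly = 80L, human = 28L, agent = 80L)[[species]]
  }
  tt <- trials$trials
  n_input <- nrow(tt)
  flag <- function(d, col, default) {
    if (col %in% names(d)) d[[col]] else rep(default, nrow(d))
  }
  tt1 <- tt[flag(tt, "reached_bottom", TRUE), , drop = FALSE]
  tt2 <- tt1[!flag(tt1, "has_gap", FALSE), , drop = FALSE]
  tt3 <- tt2[flag(tt2, "in_maze", TRUE), , drop = FALSE]
  counts <- table(tt3$id)
  keep_ids <- names(counts)[counts >= min_trials]
  excluded <- setdiff(unique(tt$id), keep_ids)
  tt4 <- tt3[tt3$id %in% keep_ids, , drop = FALSE]
  report <- list(
    n_input = n_input,
    n_after_reach_bottom = nrow(tt1),
    n_after_missing = nrow(tt2),
    n_after_in_maze = nrow(tt3),
    n_after_min_trials = nrow(tt4),
    min_trials = min_trials,
    excluded_ids = if (length(excluded)) {
      tibble::tibble(
        id = excluded,
        reason = sprintf("fewer than %d valid trials (%d)", min_trials,
                         as.integer(counts[excluded]) %|NA|% 0L)
      )
    } else {
      tibble::tibble(id = character(), reason = character())
    }
  )
  keep_key <- paste(tt4$id, tt4$trial)
  pts <- trials$points[paste(trials$points$id, trials$points$trial) %in%
                         keep_key, , drop = FALSE]
  out <- new_trials(tt4, pts, attr(trials, "normalized"),
                    attr(trials, "frame_rate"), species,
                    attr(trials, "group"))
  list(trials = out, report = report)
}

`%|NA|%` <- function(a, b) {
  a[is.na(a)] <- b
  a
}

#' Relative time within a trial
#'
#' Maps within-trial sample indices onto a dimensionless time axis anchored
#' at three landmarks: -1 where the trial first reaches signed y >= -1
#' (`k_m1p`), 0 at the turning point (`k_min`, the minimal-y sample), and
#' +1 where it last satisfies y <= 1 (`k_p1m`). Downward samples get
#' `-(k_min - k) / (k_min - k_m1p)`, upward samples
#' `(k - k_min) / (k_p1m - k_min)`; samples beyond the landmarks fall
#' outside \[-1, 1\].
#'
#' @param k Integer sample indices.
#' @param k_m1p,k_min,k_p1m Landmark indices.
#' @return Numeric relative times.
#' @export
relative_time <- function(k, k_m1p, k_min, k_p1m) {
  if (k_min == k_m1p || k_min == k_p1m) {
    stop("degenerate trial: zero-length downward or upward phase",
         call. = FALSE)
  }
  ifelse(k < k_min, -(k_min - k) / (k_min - k_m1p),
         ifelse(k > k_min, (k - k_min) / (k_p1m - k_min), 0))
}

#' Normalize segmented trials to signed arm coordinates
#'
#' Per individual, over all its valid trials, raw y is affinely mapped so
#' that 1 is the upper edge of the bottom arm (just below the intersection)
#' and 0 the minimal location reached during the experiment; x is scaled by
#' the same factor (aspect preserved). Within each trial the scaled
#' y' is signed by the turning point `k_min` (first sample attaining the
#' trial minimum): negative strictly before, positive after, so sign(y)
#' flips exactly once per trial. Finally x is centred by the midpoint of
#' the individual's x-range over -1 <= y <= 1, making x = 0 the arm's
#' horizontal midline, and relative time is attached.
#'
#' Trials flagged invalid by [segment_trials()], trials whose turning point
#' is the first or last sample, and trials with a zero-length downward or
#' upward phase are dropped.
#'
#' @param trials Raw `ymaze_trials` from [segment_trials()] (optionally
#'   filtered by [apply_exclusions()]).
#' @param geom The [maze_geometry()] used for segmentation.
#' @return A normalized `ymaze_trials`: points gain `t_rel` and replace
#'   `x`, `y` by centred/signed values; the trial table gains landmark
#'   indices `k_m1p`, `k_min`, `k_p1m`. A per-individual calibration table
#'   is attached as attribute `"calibration"`.
#' @export
normalize_trials <- function(trials, geom) {
  stopifnot(inherits(trials, "ymaze_trials"), inherits(geom, "maze_geometry"))
  if (isTRUE(attr(trials, "normalized"))) {
    stop("trials are already normalized", call. = FALSE)
  }
  tt <- trials$trials
  flag_cols <- c("reached_bottom", "has_gap", "in_maze")
  if (all(flag_cols %in% names(tt))) {
    tt <- tt[tt$reached_bottom & !tt$has_gap & tt$in_maze, , drop = FALSE]
  }
  y_top <- maze_norm_span(geom)$y_top
  trials_out <- list()
  points_out <- list()
  calib <- list()
  for (ind in unique(tt$id)) {
    ti <- tt[tt$id == ind, , drop = FALSE]
    pts <- trials$points[trials$points$id == ind &
                           trials$points$trial %in% ti$trial, , drop = FALSE]
    y_min <- min(pts$y)
    if (y_min >= y_top) next
    s <- 1 / (y_top - y_min)
    by_trial <- split(pts, pts$trial)[as.character(ti$trial)]
    keep <- list()
    for (tr_id in names(by_trial)) {
      p <- by_trial[[tr_id]]
      yp <- (p$y - y_min) * s
      k_min <- which.min(yp)[1]
      if (k_min == 1L || k_min == nrow(p)) next # no down or up phase
      ys <- ifelse(seq_len(nrow(p)) < k_min, -yp, yp)
      k_m1p <- which(ys >= -1)[1]
      k_p1m <- max(which(ys <= 1))
      if (k_min == k_m1p || k_min == k_p1m) next # zero-length phase
      p$y <- ys
      p$x <- p$x * s
      p$t_rel <- relative_time(p$k, k_m1p, k_min, k_p1m)
      keep[[tr_id]] <- list(points = p, k_m1p = k_m1p, k_min = k_min,
                            k_p1m = k_p1m)
    }
    if (!length(keep)) next
    allp <- dplyr::bind_rows(lapply(keep, `[[`, "points"))
    in_arm <- abs(allp$y) <= 1
    if (!any(in_arm)) next
    x_lo <- min(allp$x[in_arm])
    x_hi <- max(allp$x[in_arm])
    x_mid <- 0.5 * (x_lo + x_hi)
    for (tr_id in names(keep)) {
      k <- keep[[tr_id]]
      k$points$x <- k$points$x - x_mid
      points_out[[length(points_out) + 1L]] <- k$points
      row <- ti[ti$trial == as.integer(tr_id), , drop = FALSE]
      row$k_m1p <- k$k_m1p
      row$k_min <- k$k_min
      row$k_p1m <- k$k_p1m
      trials_out[[length(trials_out) + 1L]] <- row
    }
    calib[[length(calib) + 1L]] <- tibble::tibble(
      id = ind, y_min = y_min, y_top = y_top, scale = s,
      x_lo = x_lo, x_hi = x_hi, x_mid = x_mid)
  }
  if (!length(trials_out)) {
    stop("no valid trials survived normalization", call. = FALSE)
  }
  tt_out <- dplyr::bind_rows(trials_out)
  tt_out <- tt_out[, setdiff(names(tt_out), flag_cols), drop = FALSE]
  out <- new_trials(tt_out, dplyr::bind_rows(points_out), TRUE,
                    attr(trials, "frame_rate"), attr(trials, "species"),
                    attr(trials, "group"))
  attr(out, "calibration") <- dplyr::bind_rows(calib)
  out
}

rotate_xy <- function(x, y, deg) {
  th <- deg * pi / 180
  list(x = cos(th) * x - sin(th) * y, y = sin(th) * x + cos(th) * y)
}

#' Map traversals of any arm onto the bottom arm
#'
#' Exploits the maze's 3-fold rotational symmetry: the track is rotated by
#' 0, +120 and -120 degrees (mapping respectively the bottom, left and
#' right arm onto the bottom arm) and each rotated copy is segmented for
#' bottom-arm trials. Turn labels come out relative to the traversed arm.
#' Used for human data, where trials from all three arms are analyzed;
#' incomplete traversals are dropped by segmentation as usual.
#'
#' @param tr A `ymaze_tracks` object.
#' @param geom A [maze_geometry()] (3-fold symmetric by construction).
#' @inheritParams segment_trials
#' @return A raw `ymaze_trials` with trials from all arms expressed in
#'   bottom-arm coordinates.
#' @export
rotate_human_trials <- function(tr, geom, reach_depth = NULL) {
  stopifnot(inherits(tr, "ymaze_tracks"))
  pieces <- lapply(c(0, 120, -120), function(deg) {
    r <- rotate_xy(tr$x, tr$y, deg)
    tr2 <- tr
    tr2$x <- r$x
    tr2$y <- r$y
    segment_trials(tr2, geom, reach_depth = reach_depth)
  })
  offset <- 0L
  tt <- list()
  pp <- list()
  for (p in pieces) {
    if (!nrow(p$trials)) next
    t2 <- p$trials
    p2 <- p$points
    t2$trial <- t2$trial + offset
    p2$trial <- p2$trial + offset
    offset <- offset + max(p$trials$trial)
    tt[[length(tt) + 1L]] <- t2
    pp[[length(pp) + 1L]] <- p2
  }
  if (!length(tt)) {
    return(pieces[[1]])
  }
  new_trials(dplyr::bind_rows(tt), dplyr::bind_rows(pp), FALSE,
             attr(tr, "frame_rate"), attr(tr, "species"), attr(tr, "group"))
}

#' Keep only the listed individuals
#' @param trials A `ymaze_trials` object.
#' @param ids Character vector of individual ids to keep.
#' @return Filtered `ymaze_trials`.
#' @export
filter_individuals <- function(trials, ids) {
  out <- trials
  out$trials <- trials$trials[trials$trials$id %in% ids, , drop = FALSE]
  out$points <- trials$points[trials$points$id %in% ids, , drop = FALSE]
  out
}
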