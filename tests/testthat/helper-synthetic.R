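# Shared fixture builders: everything is generated in code at test time.

# Global coordinates of a point at `depth` along an arm axis with lateral
# offset `lat` (mirrors the package's arm-frame convention).
arm_xy <- function(arm, depth, lat) {
  s3 <- sqrt(3) / 2
  switch(arm,
         bottom = c(lat, -depth),
         left = c(-0.5 * lat - s3 * depth, -s3 * lat + 0.5 * depth),
         right = c(-0.5 * lat + s3 * depth, s3 * lat + 0.5 * depth),
         stop("unknown arm"))
}

# Linear interpolation through waypoints at a fixed spatial step, sampled
# at 30 Hz; returns a ymaze_tracks with a single individual.
build_track <- function(waypoints, step = 0.04, id = "f1", frame_rate = 30,
                        species = "fly") {
  pts <- list(waypoints[[1]])
  for (i in seq_along(waypoints)[-1]) {
    a <- waypoints[[i - 1]]
    b <- waypoints[[i]]
    len <- sqrt(sum((b - a)^2))
    n <- max(2L, ceiling(len / step))
    seg <- cbind(seq(a[1], b[1], length.out = n),
                 seq(a[2], b[2], length.out = n))
    pts[[length(pts) + 1L]] <- seg[-1, , drop = FALSE]
  }
  m <- do.call(rbind, lapply(pts, rbind))
  df <- tibble::tibble(id = id, t = seq_len(nrow(m)) / frame_rate,
                       x = m[, 1], y = m[, 2])
  tracks(df, frame_rate = frame_rate, species = species)
}

# Waypoints for a sequence of arm visits (each to the cul-de-sac cap and
# back to the centre), with a per-visit lateral offset.
visit_waypoints <- function(geom, arms, lat = 0.15, depth = NULL) {
  depth <- depth %||% (geom$arm_length + 0.3)
  lat <- rep_len(lat, length(arms))
  wp <- list(c(0, 0))
  for (i in seq_along(arms)) {
    wp[[length(wp) + 1L]] <- arm_xy(arms[i], depth, lat[i])
    wp[[length(wp) + 1L]] <- c(0, 0)
  }
  wp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built normalized trials from explicit per-trial x/y paths.
manual_trials <- function(xs, ys, turn, prev_arm = NULL, id = "m1") {
  stopifnot(length(xs) == length(ys), length(xs) == length(turn))
  prev_arm <- prev_arm %||% rep("left", length(xs))
  tt <- list()
  pp <- list()
  for (i in seq_along(xs)) {
    y <- ys[[i]]
    k_min <- which.min(abs(y))[1]
    tt[[i]] <- tibble::tibble(
      id = id, trial = i, prev_arm = prev_arm[i], turn = turn[i],
      k_m1p = which(y >= -1)[1], k_min = k_min, k_p1m = max(which(y <= 1)))
    pp[[i]] <- tibble::tibble(
      id = id, trial = i, k = seq_along(y), t = seq_along(y) / 30,
      x = xs[[i]], y = y,
      t_rel = ymaze::relative_time(seq_along(y), tt[[i]]$k_m1p, k_min,
                                   tt[[i]]$k_p1m))
  }
  ymaze:::new_trials(dplyr::bind_rows(tt), dplyr::bind_rows(pp), TRUE, 30,
                     "agent", "manual")
}

# Side/turn label vectors realizing given conditional right-turn counts.
sides_turns <- function(n_pos, k_pos_right, n_neg, k_neg_right) {
  list(
    sides = c(rep("right", n_pos), rep("left", n_neg)),
    turns = c(rep("right", k_pos_right), rep("left", n_pos - k_pos_right),
              rep("right", k_neg_right), rep("left", n_neg - k_neg_right))
  )
}
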