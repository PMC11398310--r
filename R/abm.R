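#' Agent locomotion parameters
#'
#' Three locomotor rule sets for point agents in the maze, integrated with
#' Euler steps and specular wall reflections:
#' * `brownian` — the heading is redrawn uniformly every step (no
#'   directional persistence, no wall interaction beyond collisions);
#' * `heading_rw` — the heading diffuses, `theta <- theta + sigma*sqrt(dt)*xi`;
#' * `wall_following` — heading diffusion plus a steering term that, within
#'   `wall_sensing_range` of a wall, rotates the heading toward the nearest
#'   wall tangent (blended slightly toward the wall, with the blend
#'   vanishing at contact) with gain `wall_attraction`.
#'
#' @param model One of `"brownian"`, `"heading_rw"`, `"wall_following"`.
#' @param speed Walking speed, arena units per second.
#' @param heading_noise Heading diffusion, rad per sqrt(second).
#' @param wall_attraction Dimensionless steering gain (>= 0); forced to 0
#'   for non-wall-following models.
#' @param wall_sensing_range Wall interaction range, arena units.
#' @param dt Integration step in seconds (default one camera frame, 1/30 s).
#' @return An `agent_params` list.
#' @export
agent_params <- function(model = c("wall_following", "heading_rw", "brownian"),
                         speed = 1.2, heading_noise = 2.0,
                         wall_attraction = 4, wall_sensing_range = 0.3,
                         dt = 1 / 30) {
  model <- match.arg(model)
  stopifnot(speed > 0, dt > 0, heading_noise >= 0, wall_attraction >= 0)
  if (model != "wall_following") wall_attraction <- 0
  structure(list(model = model, speed = speed, heading_noise = heading_noise,
                 wall_attraction = wall_attraction,
                 wall_sensing_range = wall_sensing_range, dt = dt),
            class = "agent_params")
}

#' Simulate one agent trajectory
#'
#' The agent starts mid-way down the bottom arm with a random heading.
#' Randomness comes from R's RNG stream, so wrapping the call in
#' `set.seed()` makes trajectories bit-identical across runs.
#'
#' @param params An [agent_params()].
#' @param duration Simulated time in seconds.
#' @param geom A [maze_geometry()].
#' @return A tibble with columns `t`, `x`, `y` sampled every `dt`.
#' @export
simulate_track <- function(params, duration, geom) {
  stopifnot(inherits(params, "agent_params"), inherits(geom, "maze_geometry"))
  n_steps <- as.integer(round(duration / params$dt))
  model_code <- match(params$model, c("brownian", "heading_rw",
                                      "wall_following")) - 1L
  y0 <- -(geom$y_intersect + geom$arm_length) / 2
  th0 <- stats::runif(1, -pi, pi)
  m <- abm_simulate_cpp(n_steps, 0, y0, th0, model_code, params$speed,
                        params$heading_noise, params$wall_attraction,
                        params$wall_sensing_range, params$dt,
                        geom$arm_length, geom$arm_width)
  tibble::tibble(t = seq_len(nrow(m)) / (1 / params$dt) - params$dt,
                 x = m[, 1], y = m[, 2])
}

#' Simulate a cohort of independent agents
#'
#' Each agent runs on its own RNG substream derived from the master seed,
#' so cohorts are reproducible and agents independent. The output is a
#' standard track table: simulated cohorts flow through segmentation,
#' normalization and every downstream analysis with no special-casing.
#'
#' @param params An [agent_params()] shared by the cohort.
#' @param n_agents Number of agents.
#' @param duration Simulated seconds per agent.
#' @param geom A [maze_geometry()].
#' @param seed Master seed (integer).
#' @param group Group tag stored on the track table.
#' @return A `ymaze_tracks` object (species `"agent"`).
#' @export
simulate_cohort <- function(params, n_agents, duration, geom, seed = 1,
                            group = "agents") {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_agents)
  out <- vector("list", n_agents)
  for (a in seq_len(n_agents)) {
    set.seed(sub_seeds[a])
    tr <- simulate_track(params, duration, geom)
    tr$id <- sprintf("agent%03d", a)
    out[[a]] <- tr
  }
  df <- dplyr::bind_rows(out)[, c("id", "t", "x", "y")]
  tracks(df, frame_rate = 1 / params$dt, species = "agent", group = group)
}

#' Parameters of the parametric parity-trial generator
#'
#' A fast sampler of ready-made normalized trials with controllable
#' midline-crossing structure, emulating the trial statistics of
#' wall-biased maze locomotion: with probability `p_zero` a trial hugs a
#' single wall all the way up (zero post-cul-de-sac crossings); otherwise
#' the number of post-cul-de-sac crossings is at least one and its parity
#' is even with probability `beta`. The expected overall even fraction is
#' therefore `p_zero + (1 - p_zero) * beta` in closed form. Defaults
#' emulate a wild-type-like short-maze cohort: 24% zero-crossing trials,
#' overall even fraction ~0.65, ~3.7 post-cul-de-sac and ~6 cul-de-sac
#' crossings per trial on average.
#'
#' @param p_zero Probability of a zero-crossing (wall-hugging) trial.
#' @param beta P(even count | at least one crossing).
#' @param lambda_post Poisson rate of the base crossing count (the count is
#'   `1 + Poisson(lambda_post)`, then nudged by one to match the drawn
#'   parity).
#' @param lambda_culdesac,lambda_down Poisson means of the cul-de-sac and
#'   down-arm crossing counts.
#' @param side_bias P(trial starts on the right wall).
#' @param wall_offset Mean |x| of the wall-hugging path, normalized units.
#' @param crossing_interval `"uniform"` (crossing positions are distinct
#'   uniform grid locations) or `"exponential"` (positions from cumulated
#'   exponential gaps, giving clustered short intervals).
#' @param step y-grid resolution of the synthetic path.
#' @return A `parity_params` list.
#' @export
parity_params <- function(p_zero = 0.24, beta = 0.54, lambda_post = 3.6,
                          lambda_culdesac = 6, lambda_down = 1,
                          side_bias = 0.5, wall_offset = 0.3,
                          crossing_interval = c("uniform", "exponential"),
                          step = 0.02) {
  crossing_interval <- match.arg(crossing_interval)
  stopifnot(p_zero >= 0, p_zero <= 1, beta >= 0, beta <= 1,
            side_bias >= 0, side_bias <= 1, wall_offset > 0, step > 0)
  structure(list(p_zero = p_zero, beta = beta, lambda_post = lambda_post,
                 lambda_culdesac = lambda_culdesac, lambda_down = lambda_down,
                 side_bias = side_bias, wall_offset = wall_offset,
                 crossing_interval = crossing_interval, step = step),
            class = "parity_params")
}

# Pick m distinct sample indices for crossings inside [lo, hi].
place_crossings <- function(m, lo, hi, mode) {
  avail <- lo:hi
  if (m > length(avail)) return(NULL) # infeasible
  if (mode == "uniform" || m <= 1) {
    sort(sample(avail, m))
  } else {
    gaps <- stats::rexp(m, rate = m / length(avail))
    pos <- lo + round(cumsum(gaps))
    pos <- pmin(pos, hi)
    pos <- unique(pos)
    while (length(pos) < m) {
      extra <- setdiff(avail, pos)
      if (!length(extra)) return(NULL)
      pos <- sort(c(pos, sample(extra, min(m - length(pos), length(extra)))))
    }
    sort(pos)
  }
}

#' Sample synthetic normalized trials with controlled crossing parity
#'
#' Trials are idealized bottom-arm traversals on a fixed y-grid: the path
#' descends from just above the arm top to the turning point, ascends back
#' out, and carries a lateral position that hugs one wall and flips sides
#' at the drawn crossing locations (plus sub-wall jitter that never changes
#' sign between crossings). The turn label is derived from the final side,
#' so the exit-side/parity/turn relation holds exactly by construction.
#' Ground-truth crossing counts per region are attached to the trial table.
#'
#' @param params A [parity_params()].
#' @param n_trials Total number of trials.
#' @param n_individuals Number of synthetic individuals the trials are
#'   split across (trial counts as equal as possible).
#' @param arm_end Normalized y of the arm top (1 for a short-maze-like
#'   arm; 2 emulates an arm twice as long on the same physical scale).
#' @param yc Cul-de-sac boundary used to place region-specific crossings.
#' @param seed Optional integer seed.
#' @param group Group tag.
#' @return A normalized `ymaze_trials` (species `"agent"`); the trial
#'   table carries ground truth columns `true_n_post`, `true_n_culdesac`,
#'   `true_n_down`.
#' @export
sample_parity_trials <- function(params = parity_params(), n_trials = 144,
                                 n_individuals = 1, arm_end = 1, yc = 0.34,
                                 seed = NULL, group = "parity") {
  stopifnot(inherits(params, "parity_params"))
  if (!is.null(seed)) set.seed(seed)
  step <- params$step
  entry <- arm_end + 0.08
  y_dn <- seq(-entry, -step, by = step)
  y_up <- seq(0, entry, by = step)
  y <- c(y_dn, y_up)
  n_samp <- length(y)
  k_min <- length(y_dn) + 1L
  idx_down <- which(y < -(yc + 2 * step))
  idx_cul <- which(abs(y) <= yc - 2 * step & seq_len(n_samp) != k_min)
  idx_post <- which(y > yc + 2 * step & y < arm_end - 2 * step)
  ids <- sprintf("synth%03d", seq_len(n_individuals))
  id_of_trial <- rep(ids, length.out = n_trials)
  xs <- vector("list", n_trials)
  meta <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    n_down <- stats::rpois(1, params$lambda_down)
    n_cul <- stats::rpois(1, params$lambda_culdesac)
    if (stats::runif(1) < params$p_zero) {
      n_post <- 0L
    } else {
      want_even <- stats::runif(1) < params$beta
      m <- 1L + stats::rpois(1, params$lambda_post)
      if ((m %% 2 == 0) != want_even) m <- m + 1L
      n_post <- m
    }
    c_down <- place_crossings(n_down, min(idx_down), max(idx_down),
                              params$crossing_interval)
    c_cul <- place_crossings(n_cul, min(idx_cul), max(idx_cul),
                             params$crossing_interval)
    c_post <- if (n_post > 0) {
      p <- place_crossings(n_post, min(idx_post), max(idx_post),
                           params$crossing_interval)
      if (is.null(p)) {
        warning("crossing positions infeasible for arm length; trial falls back to 0 crossings")
        n_post <- 0L
        integer(0)
      } else {
        p
      }
    } else {
      integer(0)
    }
    if (is.null(c_down)) { c_down <- integer(0); n_down <- 0L }
    if (is.null(c_cul)) { c_cul <- integer(0); n_cul <- 0L }
    cr <- sort(unique(c(c_down, c_cul, c_post)))
    s0 <- if (stats::runif(1) < params$side_bias) 1 else -1
    flip <- integer(n_samp)
    flip[cr + 1L] <- 1L
    s <- s0 * (-1)^cumsum(flip)
    amp <- params$wall_offset * (1 + stats::runif(n_samp, -0.45, 0.45))
    xs[[tr]] <- s * amp
    meta[[tr]] <- c(s_final = s[n_samp], n_post = n_post, n_cul = n_cul,
                    n_down = n_down)
  }
  mm <- do.call(rbind, meta)
  turn <- ifelse(mm[, "s_final"] > 0, "right", "left")
  prev_arm <- ifelse(stats::runif(n_trials) < 0.5, "left", "right")
  k_m1p <- which(y >= -1)[1]
  k_p1m <- max(which(y <= 1))
  t_rel <- relative_time(seq_len(n_samp), k_m1p, k_min, k_p1m)
  trials_tab <- tibble::tibble(
    id = id_of_trial, trial = seq_len(n_trials), prev_arm = prev_arm,
    turn = turn, k_m1p = k_m1p, k_min = k_min, k_p1m = k_p1m,
    true_n_post = as.integer(mm[, "n_post"]),
    true_n_culdesac = as.integer(mm[, "n_cul"]),
    true_n_down = as.integer(mm[, "n_down"])
  )
  points_tab <- tibble::tibble(
    id = rep(id_of_trial, each = n_samp),
    trial = rep(seq_len(n_trials), each = n_samp),
    k = rep(seq_len(n_samp), n_trials),
    t = rep(seq_len(n_samp) / 30, n_trials),
    x = unlist(xs, use.names = FALSE),
    y = rep(y, n_trials),
    t_rel = rep(t_rel, n_trials)
  )
  new_trials(trials_tab, points_tab, TRUE, 30, "agent", group)
}
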