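test_that("side_in_range matches a direct filter-and-average recomputation", {
  trials <- sample_parity_trials(n_trials = 100, seed = 15)
  rng <- c(0.35, 0.8)
  s <- side_in_range(trials, rng[1], rng[2])
  pts <- trials$points
  for (i in sample(nrow(s), 20)) {
    sel <- pts$trial == s$trial[i] & pts$y >= rng[1] & pts$y <= rng[2]
    m <- mean(pts$x[sel])
    want <- if (!any(sel)) "absent" else if (m > 0) "right" else
      if (m < 0) "left" else "tie"
    expect_identical(s$side[i], want)
  }
  # a range beyond the trials' reach is absent for every trial
  s2 <- side_in_range(trials, 5, 6)
  expect_true(all(s2$side == "absent"))
  expect_error(side_in_range(trials, 0.5, 0.5), "empty range")
})

test_that("tpi_bin handles perfect, absent and one-sided cases", {
  st <- sides_turns(10, 10, 10, 0) # perfect predictiveness
  expect_equal(tpi_bin(st$sides, st$turns)$tpi, 1)
  # one side empty: undefined, not zero
  b <- tpi_bin(rep("right", 5), rep("right", 5))
  expect_true(is.na(b$tpi))
  expect_equal(b$n_neg, 0)
  # ties and absents excluded from both conditionals
  st <- sides_turns(4, 4, 4, 0)
  b2 <- tpi_bin(c(st$sides, "tie", "absent"), c(st$turns, "right", "left"))
  expect_equal(b2$tpi, 1)
  expect_equal(b2$n_pos + b2$n_neg, 8)
  # SE is the two-proportion binomial form
  st <- sides_turns(100, 69, 100, 37)
  b3 <- tpi_bin(st$sides, st$turns)
  expect_equal(b3$se, sqrt(0.69 * 0.31 / 100 + 0.37 * 0.63 / 100),
               tolerance = 1e-12)
})

test_that("shuffled turn labels give zero TPI in expectation", {
  set.seed(8)
  sides <- sample(c("left", "right"), 200, replace = TRUE)
  vals <- replicate(2000, {
    turns <- sample(c("left", "right"), 200, replace = TRUE)
    tpi_bin(sides, turns)$tpi
  })
  expect_lt(abs(mean(vals)), 0.01)
})

test_that("tail values encode sequential effects and saturate at +1", {
  # perfectly alternating sequence: prev right -> turn left and vice versa
  n <- 40
  turn <- rep(c("left", "right"), n / 2)
  prev <- c("right", turn[-n]) # previous turn is the arrival arm
  trials <- manual_trials(
    xs = lapply(turn, function(tn) rep(if (tn == "right") 0.3 else -0.3, 11)),
    ys = rep(list(seq(-1, 1, length.out = 11)), n),
    turn = turn, prev_arm = prev)
  tl <- tpi_tails(trials)
  expect_equal(tl$tail_minus, -1)
  expect_equal(tl$tail_plus, 1)
  # turn independent of previous arm: tail ~ 0
  set.seed(2)
  turn2 <- sample(c("left", "right"), 400, TRUE)
  prev2 <- sample(c("left", "right"), 400, TRUE)
  trials2 <- manual_trials(
    xs = lapply(turn2, function(tn) rep(if (tn == "right") 0.3 else -0.3, 11)),
    ys = rep(list(seq(-1, 1, length.out = 11)), 400),
    turn = turn2, prev_arm = prev2)
  expect_lt(abs(tpi_tails(trials2)$tail_minus), 0.15)
  # all trials share one previous arm: undefined
  trials3 <- manual_trials(
    xs = list(rep(0.3, 11), rep(-0.3, 11)),
    ys = rep(list(seq(-1, 1, length.out = 11)), 2),
    turn = c("right", "left"), prev_arm = c("left", "left"))
  expect_true(is.na(tpi_tails(trials3)$tail_minus))
})

test_that("terminal saturation: the scoring bin has TPI exactly 1", {
  # the side of x in the last bin defines the turn by construction
  trials <- sample_parity_trials(n_trials = 200, seed = 5)
  cur <- tpi_curve(trials)
  last_def <- max(which(!is.na(cur$tpi)))
  expect_equal(cur$tpi[last_def], 1)
  expect_true(all(abs(cur$tpi) <= 1, na.rm = TRUE))
})

test_that("per-bin group averaging matches direct recomputation", {
  trials <- sample_parity_trials(n_trials = 300, n_individuals = 6, seed = 12)
  per <- tpi_curves_by_id(trials)
  grp <- average_curves(per)
  for (b in c(3, 14, 20)) {
    vals <- per$tpi[per$bin == b]
    expect_equal(grp$tpi[grp$bin == b], mean(vals, na.rm = TRUE))
    expect_equal(grp$n_ids[grp$bin == b], sum(!is.na(vals)))
  }
  # identical curves average to themselves with zero spread
  two <- dplyr::bind_rows(
    transform(per[per$id == per$id[1], ], id = "c1"),
    transform(per[per$id == per$id[1], ], id = "c2"))
  g2 <- average_curves(two)
  expect_equal(g2$tpi, per$tpi[per$id == per$id[1]])
  expect_true(all(g2$sem[!is.na(g2$sem)] == 0))
  # curves +c and -c average to zero
  flip <- per[per$id == per$id[1], ]
  two2 <- dplyr::bind_rows(transform(flip, id = "c1"),
                           transform(flip, id = "c2", tpi = -flip$tpi,
                                     tail_minus = -flip$tail_minus))
  g3 <- average_curves(two2)
  expect_true(all(abs(g3$tpi[!is.na(g3$tpi)]) < 1e-12))
})

test_that("a perfect wall-follower has TPI 1 in every occupied bin", {
  set.seed(3)
  n <- 60
  side <- sample(c(-1, 1), n, TRUE)
  trials <- manual_trials(
    xs = lapply(side, function(s) s * (0.3 + runif(41, 0, 0.1))),
    ys = rep(list(seq(-1.05, 1.05, length.out = 41)), n),
    turn = ifelse(side > 0, "right", "left"),
    prev_arm = sample(c("left", "right"), n, TRUE))
  cur <- tpi_curve(trials)
  expect_true(all(cur$tpi[!is.na(cur$tpi)] == 1))
})
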