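test_that("MAD from the midline matches closed forms and a sort oracle", {
  # constant offset c in the window -> MAD = |c|
  y <- seq(-1.05, 1.05, by = 0.05)
  one <- manual_trials(list(rep(-0.22, length(y))), list(y), "left")
  expect_equal(mad_score(one)$mad, 0.22)
  # alternating +-c -> c
  two <- manual_trials(list(rep(c(0.31, -0.31), length.out = length(y))),
                       list(y), "right")
  expect_equal(mad_score(two)$mad, 0.31)
  # random samples vs an independent sort-based median of |x|
  trials <- sample_parity_trials(n_trials = 80, seed = 66)
  got <- mad_score(trials, c(0.34, 1))$mad
  pts <- trials$points
  v <- sort(abs(pts$x[pts$y > 0.34 & pts$y < 1]))
  n <- length(v)
  want <- if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
  expect_equal(got, want)
  # empty window -> undefined
  expect_true(is.na(mad_score(trials, c(4, 5))$mad))
})

test_that("MAD is invariant to reflection and trial order", {
  trials <- sample_parity_trials(n_trials = 60, seed = 13)
  m1 <- mad_score(trials)$mad
  expect_equal(mad_score(mirror_trials(trials))$mad, m1)
  shuf <- trials
  set.seed(1)
  ord <- sample(nrow(shuf$points))
  shuf$points <- shuf$points[ord, ]
  expect_equal(mad_score(shuf)$mad, m1)
})

test_that("extreme-group splits take the k lowest and highest scorers", {
  sc <- tibble::tibble(id = letters[1:10], mad = 1:10)
  gr <- split_extreme_groups(sc, k = 2)
  expect_identical(gr$low, c("a", "b"))
  expect_identical(gr$high, c("i", "j"))
  # quintile split of 55 individuals gives 11 per group
  sc2 <- tibble::tibble(id = sprintf("f%02d", 1:55), mad = runif(55))
  gr2 <- split_extreme_groups(sc2, frac = 0.2)
  expect_equal(length(gr2$low), 11)
  expect_equal(length(gr2$high), 11)
  expect_length(intersect(gr2$low, gr2$high), 0)
  ord <- sc2$id[order(sc2$mad)]
  expect_setequal(gr2$low, ord[1:11])
  expect_setequal(gr2$high, ord[45:55])
  expect_error(split_extreme_groups(sc, k = 6), "cannot split")
})

test_that("conditional MAD stratifies by crossing count correctly", {
  # wall-huggers (0 crossings, |x| ~ 0.4) vs meanderers (3 crossings, |x| ~ 0.1)
  y <- seq(-1.02, 1.02, by = 0.02)
  up <- which(y > 0.4 & y < 0.96)
  mk_hug <- function() rep(0.4, length(y))
  mk_meander <- function() {
    cr <- sort(sample(up[5:(length(up) - 5)], 3))
    s <- (-1)^findInterval(seq_along(y), cr + 0.5)
    s * 0.1
  }
  set.seed(5)
  xs <- c(replicate(10, mk_hug(), simplify = FALSE),
          replicate(10, mk_meander(), simplify = FALSE))
  trials <- manual_trials(xs, rep(list(y), 20), rep(c("right", "left"), each = 10))
  mg <- mad_given_crossings(trials, max_k = 5)
  expect_equal(mg$mad[mg$k == 0], 0.4)
  expect_equal(mg$mad[mg$k == 3], 0.1)
  expect_gt(mg$mad[mg$k == 0], mg$mad[mg$k == 3])
  expect_true(is.na(mg$mad[mg$k == 5])) # empty stratum undefined, not 0
  expect_equal(mg$n_trials[mg$k == 0], 10)
})

test_that("group comparison statistics behave at their boundary cases", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  expect_equal(compare_groups(x, x)$p_value, 1)
  expect_equal(correlate(x, x)$r, 1)
  set.seed(2)
  a <- rnorm(200)
  b <- rnorm(200) + 1
  expect_lt(compare_groups(a, b)$p_value, 1e-10)
  expect_error(compare_groups(1, 2), "at least 2")
})

test_that("high-MAD cohorts have higher cul-de-sac TPI than low-MAD cohorts", {
  # mixed cohort: wall-huggers commit early (high MAD, predictive in the
  # cul-de-sac); meanderers decide late (low MAD, unpredictive early)
  set.seed(77)
  n_id <- 10
  mk_cohort <- function(hug) {
    sample_parity_trials(
      parity_params(p_zero = if (hug) 0.8 else 0.02,
                    beta = if (hug) 0.8 else 0.5,
                    lambda_post = if (hug) 1 else 5,
                    lambda_culdesac = if (hug) 0.5 else 6,
                    wall_offset = if (hug) 0.42 else 0.15),
      n_trials = 60, n_individuals = 1, seed = sample.int(1e6, 1),
      group = if (hug) "hug" else "meander")
  }
  parts <- list()
  for (i in 1:n_id) {
    tr <- mk_cohort(i <= n_id / 2)
    tr$trials$id <- sprintf("m%02d", i)
    tr$points$id <- sprintf("m%02d", i)
    parts[[i]] <- tr
  }
  cohort <- ymaze:::new_trials(dplyr::bind_rows(lapply(parts, `[[`, "trials")),
                               dplyr::bind_rows(lapply(parts, `[[`, "points")),
                               TRUE, 30, "agent", "mixed")
  sc <- mad_score(cohort)
  gr <- split_extreme_groups(sc, k = 3)
  cul_tpi <- function(ids) {
    cur <- average_curves(tpi_curves_by_id(filter_individuals(cohort, ids)))
    mean(cur$tpi[cur$lo >= -0.34 & cur$hi <= 0.34], na.rm = TRUE)
  }
  expect_gt(cul_tpi(gr$high), cul_tpi(gr$low))
})
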