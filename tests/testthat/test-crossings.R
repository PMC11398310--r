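test_that("crossing detection matches the sign-product definition", {
  expect_equal(detect_crossings(c(0.1, -0.2, 0.3)), c(1, 2))
  expect_equal(detect_crossings(c(1, 2, 0.5)), integer(0))
  expect_equal(detect_crossings(numeric(0)), integer(0))
  expect_equal(detect_crossings(0.3), integer(0))
  # zeros: a run of zeros between opposite signs is one crossing,
  # between equal signs none
  expect_equal(detect_crossings(c(0.2, 0, 0, -0.1)), 1)
  expect_equal(detect_crossings(c(0.2, 0, 0, 0.1)), integer(0))
  # brute-force oracle on random walks with occasional exact zeros
  set.seed(4)
  for (rep in 1:25) {
    x <- cumsum(rnorm(200))
    x[sample(200, 5)] <- 0
    got <- detect_crossings(x)
    last_sign <- 0
    want <- integer(0)
    last_idx <- 0L
    for (i in seq_along(x)) {
      s <- sign(x[i])
      if (s != 0) {
        if (last_sign != 0 && s * last_sign == -1) want <- c(want, last_idx)
        last_sign <- s
        last_idx <- i
      }
    }
    expect_identical(got, want)
  }
})

test_that("region counts partition the whole-trial count and match ground truth", {
  trials <- sample_parity_trials(n_trials = 400, seed = 6)
  ct <- crossing_table(trials)
  expect_equal(ct$n_culdesac + ct$n_post + ct$n_down, ct$n_total)
  # the generator's ground-truth labels agree with the pipeline recount
  expect_equal(ct$n_post, trials$trials$true_n_post)
  expect_equal(ct$n_culdesac, trials$trials$true_n_culdesac)
  expect_equal(ct$n_down, trials$trials$true_n_down)
  expect_identical(count_region(NULL, "post_culdesac", table = ct), ct$n_post)
  expect_identical(count_region(NULL, "whole", table = ct), ct$n_total)
})

fake_ct <- function(counts, id = "f1") {
  tibble::tibble(id = id, trial = seq_along(counts), turn = "right",
                 n_total = counts, n_culdesac = 0L, n_post = counts,
                 n_down = 0L,
                 parity_post = ifelse(counts %% 2 == 0, "even", "odd"),
                 lmc_y = NA_real_, exit_side = "right",
                 cross_y = lapply(counts, function(n) rep(0.5, n)))
}

test_that("PEven arithmetic and zero-exclusion behave as defined", {
  pe <- p_even(NULL, table = fake_ct(c(2, 0, 4, 1)))
  expect_equal(pe$p_even, 0.75)
  expect_equal(pe$n_trials, 4)
  pe2 <- p_even(NULL, table = fake_ct(c(1, 3, 5)))
  expect_equal(pe2$p_even, 0)
  pe2x <- p_even(NULL, table = fake_ct(c(1, 3, 5)), exclude_zero = TRUE)
  expect_equal(pe2x$p_even, 0) # no zero-count trials: unchanged
  pe3 <- p_even(NULL, table = fake_ct(c(0, 0, 2, 1)), exclude_zero = TRUE)
  expect_equal(pe3$p_even, 0.5)
  expect_equal(pe3$n_trials, 2)
  # exact binomial p-value against 0.5
  pe4 <- p_even(NULL, table = fake_ct(rep(c(2, 2, 2, 1), 5)))
  expect_equal(pe4$binom_p, binom.test(15, 20, 0.5)$p.value)
})

test_that("the sample sign test matches its closed form", {
  expect_equal(sample_sign_test(rep(0.7, 10)), 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(sample_sign_test(c(rep(0.6, 5), rep(0.4, 5))), 1)
  expect_true(is.na(sample_sign_test(rep(0.5, 8))))
  # ties at the null are dropped
  expect_equal(sample_sign_test(c(rep(0.7, 10), 0.5)), 2 * 0.5^10,
               tolerance = 1e-12)
  # type-I error at nominal level under a symmetric null
  set.seed(10)
  rej <- mean(replicate(2000, {
    sample_sign_test(runif(25, 0, 1)) < 0.05
  }))
  expect_lt(rej, 0.07)
})

test_that("LMC histograms normalize over trials that cross", {
  trials <- sample_parity_trials(n_trials = 300, seed = 44)
  lmc <- lmc_distribution(trials)
  expect_equal(sum(lmc$hist$mass), 1, tolerance = 1e-12)
  expect_equal(lmc$n_with_lmc + lmc$n_no_lmc, 300)
  # all LMCs in one place -> all mass in that bin
  one <- manual_trials(
    xs = list(c(0.2, -0.2, -0.2, -0.2), c(0.3, -0.3, -0.3, -0.3)),
    ys = rep(list(c(-0.45, 0, 0.94, 1.02)), 2),
    turn = c("left", "left"))
  h <- lmc_distribution(one, breaks = seq(-1, 1.1, 0.1))
  expect_equal(sum(h$hist$mass), 1)
  expect_equal(h$hist$mass[abs(h$hist$lo - 0.9) < 1e-9], 0)
  expect_equal(h$hist$mass[abs(h$hist$lo + 0.5) < 1e-9], 1)
})

test_that("the crossing scan flips parity exactly at crossing locations", {
  # single trial with one crossing attributed at y = 0.5 (the sign flips
  # between the samples at 0.50 and 0.55)
  y <- seq(-1.05, 1.05, by = 0.05)
  x <- ifelse(y <= 0.5, 0.3, -0.3)
  one <- manual_trials(list(x), list(y), "left")
  sc <- crossing_scan(one, thresholds = c(0.4, 0.45, 0.5, 0.6, 0.9))
  expect_equal(sc$frac_even, c(1, 1, 0, 0, 0))
  expect_error(crossing_scan(one, thresholds = c(0.2, 0.5)), "yc")
  # a parity-biased generator stays even-rich across thresholds
  biased <- sample_parity_trials(parity_params(p_zero = 0.3, beta = 0.8),
                                 n_trials = 600, seed = 3)
  sc2 <- crossing_scan(biased, thresholds = seq(0.45, 0.95, 0.1))
  expect_true(all(sc2$frac_even > 0.5))
  # a fixed-wavelength generator oscillates: crossings every 0.2 from 0.4
  n <- 200
  xs <- list(); ys <- list()
  for (i in 1:n) {
    yy <- seq(-1.05, 1.05, by = 0.01)
    cross_at <- seq(0.4, 0.9, by = 0.2) + runif(1, 0, 0.004)
    s <- (-1)^findInterval(yy, cross_at)
    xs[[i]] <- s * 0.3
    ys[[i]] <- yy
  }
  wave <- manual_trials(xs, ys, rep("left", n))
  sc3 <- crossing_scan(wave, thresholds = c(0.45, 0.65, 0.85, 0.95))
  # counts by these thresholds: 1, 2, 3, 3 -> parity odd, even, odd, odd
  expect_equal(sc3$frac_even, c(0, 1, 0, 0))
})

test_that("interval resampling is deterministic and truncates at the arm end", {
  trials <- sample_parity_trials(n_trials = 120, seed = 9)
  a <- resample_interval_null(trials, n_resamples = 50, seed = 123)
  b <- resample_interval_null(trials, n_resamples = 50, seed = 123)
  expect_identical(a$null$p_even, b$null$p_even)
  expect_true(all(a$null$p_even >= 0 & a$null$p_even <= 1))
  # degenerate single-interval pool: rebuilt sequences are deterministic,
  # and truncation at each trial's own arm end zeroes the short trial
  ya <- c(-0.6, 0, 0.36, 0.96, 1.02) # crossings at 0.36 and 0.96, gap 0.60
  xa <- c(0.3, 0.3, 0.3, -0.3, 0.3)
  yb <- c(-0.6, 0, 0.40, 0.42, 0.44) # short trial, span 0.10 above yc
  xb <- rep(0.3, 5)
  two <- manual_trials(list(xa, xb), list(ya, yb), c("right", "right"))
  r <- resample_interval_null(two, n_resamples = 20, seed = 1, yc = 0.34)
  # pool = {0.60}: the long trial always rebuilds to 1 crossing (odd), the
  # short trial always to 0 (even), so every resampled PEven is exactly 0.5
  expect_true(all(r$null$p_even == 0.5))
  # individuals that never cross are skipped with a note
  nohit <- manual_trials(list(rep(0.3, 5)), list(ya), "right", id = "z9")
  r2 <- resample_interval_null(nohit, n_resamples = 5, seed = 1)
  expect_identical(r2$skipped, "z9")
  expect_equal(nrow(r2$summary), 0)
})
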