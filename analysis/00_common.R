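# Shared setup for the analysis scripts: study cohorts, cache, paths.
#
# Every cohort here is synthetic (no raw tracking data ships with the
# repository): agent-based cohorts emulate maze locomotion mechanistically,
# parametric cohorts emulate the trial-level crossing statistics of the
# fly lines. Heavy intermediates are cached under scratch/ so the numbered
# scripts can be run independently or in sequence.

suppressPackageStartupMessages({
  library(ymaze)
  library(dplyr)
})

RESULTS_DIR <- "results"
CACHE_DIR <- "scratch/cache"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(CACHE_DIR, showWarnings = FALSE, recursive = TRUE)

SEED <- 20260928L
YC <- 0.34
GEOM_SHORT <- maze_geometry("short")
GEOM_LONG <- maze_geometry("long")
YC_LONG <- yc_for_geometry(GEOM_LONG, YC)

cache <- function(name, expr) {
  path <- file.path(CACHE_DIR, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  value <- force(expr)
  saveRDS(value, path)
  value
}

# Agent-based cohorts: one wall-following cohort per maze length, one
# Brownian control. 12 agents x 30 simulated minutes each.
abm_cohort <- function(model, gain, geom, seed, group, n_agents = 12,
                       duration = 1800, min_trials = 20) {
  p <- agent_params(model, wall_attraction = gain)
  tr <- simulate_cohort(p, n_agents = n_agents, duration = duration,
                        geom = geom, seed = seed, group = group)
  ex <- apply_exclusions(segment_trials(tr, geom), min_trials = min_trials)
  list(trials = normalize_trials(ex$trials, geom), report = ex$report)
}

# Parametric cohorts: trial statistics dialled to each line's profile
# (zero-crossing rate and overall even fraction); 24 individuals x 120
# trials. Individuals differ in a "hugginess" trait h ~ U(0,1) that
# scales both their zero-crossing (wall-hugging) trial rate and their
# wall offset, so wall proximity is a per-individual characteristic the
# MAD analyses can pick up; cohort-level expectations stay at the dials.
parity_cohort <- function(p_zero, pct_even, lambda_post, seed, group,
                          arm_end = 1, n_ids = 24, offset_base = 0.24,
                          offset_gain = 0.16) {
  beta <- (pct_even / 100 - p_zero) / (1 - p_zero)
  set.seed(seed)
  h <- runif(n_ids)
  parts <- lapply(seq_len(n_ids), function(i) {
    tr <- sample_parity_trials(
      parity_params(p_zero = min(1, p_zero * (0.5 + h[i])), beta = beta,
                    lambda_post = lambda_post,
                    wall_offset = offset_base + offset_gain * h[i]),
      n_trials = 120, n_individuals = 1, arm_end = arm_end,
      seed = seed + 1000L + i, group = group)
    tr$trials$id <- sprintf("synth%03d", i)
    tr$points$id <- sprintf("synth%03d", i)
    tr$trials$trial <- tr$trials$trial + (i - 1L) * 120L
    tr$points$trial <- tr$points$trial + (i - 1L) * 120L
    tr
  })
  out <- parts[[1]]
  out$trials <- dplyr::bind_rows(lapply(parts, `[[`, "trials"))
  out$points <- dplyr::bind_rows(lapply(parts, `[[`, "points"))
  out
}

load_cohorts <- function() {
  list(
    wf_short = cache("wf_short", abm_cohort("wall_following", 6, GEOM_SHORT,
                                            SEED + 1, "wf_short"))$trials,
    wf_long = cache("wf_long", abm_cohort("wall_following", 6, GEOM_LONG,
                                          SEED + 2, "wf_long"))$trials,
    # Brownian diffusion reaches the cul-de-sac rarely: longer sessions,
    # laxer inclusion threshold
    brownian = cache("brownian", abm_cohort("brownian", 0, GEOM_SHORT,
                                            SEED + 3, "brownian",
                                            duration = 7200,
                                            min_trials = 3))$trials,
    # wild-type-like: 24% zero-crossing trials, 65.1% even
    wt_like = cache("wt_like", parity_cohort(0.240, 65.1, 3.6, SEED + 4,
                                             "wt_like")),
    # mechanosensory-mutant-like: 57% zero-crossing, 79.1% even, and
    # greater wall proximity than the wild-type-like cohort
    nompc_like = cache("nompc_like", parity_cohort(0.572, 79.1, 2.2,
                                                   SEED + 5, "nompc_like",
                                                   offset_base = 0.31)),
    # dopamine-mutant-like: 51% zero-crossing, 80.5% even
    dumb_like = cache("dumb_like", parity_cohort(0.509, 80.5, 2.4, SEED + 6,
                                                 "dumb_like",
                                                 offset_base = 0.31)),
    # long-arm parametric cohort: more crossings, similar even fraction
    wt_long_like = cache("wt_long_like", parity_cohort(0.17, 66, 5.2,
                                                       SEED + 7,
                                                       "wt_long_like",
                                                       arm_end = 2))
  )
}

say <- function(...) cat(sprintf(...), "\n")
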