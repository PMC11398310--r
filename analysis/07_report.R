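#!/usr/bin/env Rscript
# Assemble the per-cohort summaries and pairwise comparisons into the
# final report tables: results/07_summary.tsv, results/07_comparisons.tsv
# and a short narrative results/07_report.md.

source("analysis/00_common.R")

cohorts <- load_cohorts()
yc_of <- function(nm) if (nm == "wf_long") YC_LONG else YC

summaries <- lapply(names(cohorts), function(nm) {
  summarize_cohort(cohorts[[nm]], yc = yc_of(nm))
})
names(summaries) <- names(cohorts)

stats <- bind_rows(lapply(summaries, function(s) s$stats))
stats$group <- names(summaries)
write_table(stats, file.path(RESULTS_DIR, "07_summary.tsv"))

pairs <- list(c("nompc_like", "wt_like"), c("dumb_like", "wt_like"),
              c("wf_long", "wf_short"), c("wt_long_like", "wt_like"))
cmps <- bind_rows(lapply(pairs, function(pr) {
  cmp <- compare_cohorts(summaries[[pr[1]]], summaries[[pr[2]]])
  cmp$pair <- paste(pr, collapse = "_vs_")
  cmp
}))
write_table(cmps, file.path(RESULTS_DIR, "07_comparisons.tsv"))

cols <- c("group", "n_individuals", "n_trials", "mean_n_post", "pct_even",
          "pct_zero_crossing", "mad_up_median", "median_up_time_s")
d <- stats[, cols]
num <- vapply(d, is.numeric, logical(1))
d[num] <- lapply(d[num], function(v) round(v, 2))
md_table <- c(paste(cols, collapse = " | "),
              paste(rep("---", length(cols)), collapse = " | "),
              apply(d, 1, paste, collapse = " | "))

md <- c(
  "# Synthetic-cohort report",
  "",
  "All quantities recomputed from the per-trial tables by `ymaze`;",
  "cohorts are synthetic (see analysis/00_common.R for their dials).",
  "",
  md_table,
  "",
  "Zero-inflated cohorts (emulating sensory mutants) show higher even",
  "fractions driven by wall-hugging zero-crossing trials; arm length",
  "changes crossing counts but not parity structure."
)
writeLines(md, file.path(RESULTS_DIR, "07_report.md"))

say("Cohort summaries:")
print(as.data.frame(stats[, c("group", "n_individuals", "n_trials",
                              "mean_n_post", "pct_even",
                              "pct_zero_crossing")]))
say("Report: results/07_report.md; tables: results/07_*.tsv")
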