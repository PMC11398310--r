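#!/usr/bin/env Rscript
# Midline-crossing statistics: counts by region, parity (PEven), and the
# distribution of last midline-crossings (LMC).
#
# Writes per-cohort crossing summaries (results/03_crossings.tsv),
# per-individual PEven with binomial tests (results/03_peven.tsv), and
# pooled LMC histograms (results/03_lmc.tsv).

source("analysis/00_common.R")

cohorts <- load_cohorts()
yc_of <- function(nm) if (nm == "wf_long") YC_LONG else YC

summ <- list(); peven <- list(); lmc <- list()
for (nm in names(cohorts)) {
  tr <- cohorts[[nm]]
  ct <- crossing_table(tr, yc = yc_of(nm))
  pe <- p_even(tr, yc = yc_of(nm), table = ct)
  pe_nz <- p_even(tr, yc = yc_of(nm), exclude_zero = TRUE, table = ct)
  summ[[nm]] <- tibble::tibble(
    cohort = nm,
    mean_n_post = mean(ct$n_post), sd_n_post = sd(ct$n_post),
    mean_n_culdesac = mean(ct$n_culdesac),
    pct_zero = 100 * mean(ct$n_post == 0),
    pct_even = 100 * mean(ct$n_post %% 2 == 0),
    pct_even_excl_zero = 100 * mean(ct$n_post[ct$n_post >= 1] %% 2 == 0),
    sign_test_p = sample_sign_test(pe$p_even),
    sign_test_p_excl_zero = sample_sign_test(pe_nz$p_even),
    pct_individuals_sig = 100 * mean(pe$p_even > 0.5 & pe$binom_p <= 0.05,
                                     na.rm = TRUE)
  )
  pe$cohort <- nm
  peven[[nm]] <- pe
  h <- lmc_distribution(tr, yc = yc_of(nm), table = ct)
  h$hist$cohort <- nm
  lmc[[nm]] <- h$hist
}

write_table(bind_rows(summ), file.path(RESULTS_DIR, "03_crossings.tsv"))
write_table(bind_rows(peven), file.path(RESULTS_DIR, "03_peven.tsv"))
write_table(bind_rows(lmc), file.path(RESULTS_DIR, "03_lmc.tsv"))

s <- bind_rows(summ)
say("Crossing parity by cohort:")
print(as.data.frame(s[, c("cohort", "mean_n_post", "pct_zero", "pct_even",
                          "pct_even_excl_zero", "sign_test_p")]))
say("Parity-generator cohorts keep an even-crossing excess even after")
say("dropping zero-crossing trials (working-memory-like signature); the")
say("mechanistic wall-followers do not. Tables: results/03_*.tsv")
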