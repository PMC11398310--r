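#!/usr/bin/env Rscript
# Turn Predictiveness Index curves per cohort, spatial and temporal.
#
# For each cohort: per-individual TPI curves over the 26 standard spatial
# bins, averaged into a group curve with SEM and sequential-effect tails;
# for the wild-type-like cohort also the 17+17-bin temporal curve.
# Writes results/02_tpi_spatial.tsv and results/02_tpi_temporal.tsv.

source("analysis/00_common.R")

cohorts <- load_cohorts()

spatial <- bind_rows(lapply(names(cohorts), function(nm) {
  per <- tpi_curves_by_id(cohorts[[nm]])
  grp <- average_curves(per)
  grp$cohort <- nm
  grp$tail_minus <- attr(grp, "tail_minus")
  grp
}))
write_table(spatial, file.path(RESULTS_DIR, "02_tpi_spatial.tsv"))

tempo <- tpi_curves_by_id(cohorts$wt_like, domain = "temporal")
grp_t <- average_curves(tempo)
grp_t$cohort <- "wt_like"
write_table(grp_t, file.path(RESULTS_DIR, "02_tpi_temporal.tsv"))

band <- function(nm, lo, hi) {
  v <- spatial[spatial$cohort == nm & spatial$lo >= lo & spatial$hi <= hi, ]
  mean(v$tpi, na.rm = TRUE)
}
say("Mean group TPI by maze region (cul-de-sac | upper arm):")
for (nm in names(cohorts)) {
  say("  %-12s %6.3f | %6.3f", nm, band(nm, -YC, YC), band(nm, YC, 1))
}
say("Every structured cohort develops predictability along the upper arm,")
say("strongest in the zero-inflated (mutant-like) cohorts whose wall-hugging")
say("trials commit early; the Brownian control stays near zero below the")
say("intersection. None of these generators models a correlated side")
say("preference inside the cul-de-sac, so cul-de-sac TPI stays low")
say("throughout. Tables: results/02_tpi_*.tsv")
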