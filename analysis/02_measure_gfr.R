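#!/usr/bin/env Rscript
# Measured GFR stage: simulate timed iohexol concentration curves for every
# subject, then recompute clearance by the slope-intercept method with the
# one-pool correction, confirming the measurement pipeline recovers the
# cohort's true GFR from raw samples.

suppressPackageStartupMessages(library(gfragree))
cohort <- read_cohort_csv("results/analysis/cohort.csv")

curves <- generate_iohexol_curves(cohort, noise_cv = 0.03, seed = 18)
write.csv(curves, "results/analysis/iohexol_samples.csv", row.names = FALSE)

rec <- mgfr_from_samples(curves)
write.csv(rec, "results/analysis/mgfr_recovered.csv", row.names = FALSE)

ok <- !is.na(rec$mgfr)
ratio <- rec$mgfr[ok] / cohort$mgfr[ok]
message(sprintf("fitted %d/%d subjects (QC pass %.0f%%)",
                sum(ok), nrow(cohort), 100 * mean(rec$qc_pass[ok])))
message(sprintf("recovered/true mGFR: mean ratio %.3f, 95%% of subjects within %.1f%%",
                mean(ratio), 100 * quantile(abs(ratio - 1), 0.95)))
message("wrote results/analysis/iohexol_samples.csv, mgfr_recovered.csv")
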