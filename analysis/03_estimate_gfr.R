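#!/usr/bin/env Rscript
# Estimated GFR stage: evaluate every registered equation on the cohort,
# un-indexing published ml/min/1.73m2 outputs to absolute ml/min via each
# subject's Du Bois BSA.

suppressPackageStartupMessages(library(gfragree))
cohort <- read_cohort_csv("results/analysis/cohort.csv")

em <- egfr_matrix(cohort)
write.csv(em, "results/analysis/egfr_matrix.csv", row.names = FALSE)

means <- colMeans(em[, formula_ids()])
message(sprintf("evaluated %d equations; mean mGFR %.0f ml/min", length(means),
                mean(cohort$mgfr)))
message(sprintf("mean eGFR ranges from %.0f (%s) to %.0f (%s) ml/min",
                min(means), names(means)[which.min(means)],
                max(means), names(means)[which.max(means)]))
message("wrote results/analysis/egfr_matrix.csv")
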