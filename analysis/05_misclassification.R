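#!/usr/bin/env Rscript
# Clinical-impact stage: how often estimates land on the wrong side of the
# 30 ml/min treatment cut-off, the 30-40 ml/min undercall band, the
# distribution of absolute errors, and eligibility flags.

suppressPackageStartupMessages(library(gfragree))
cohort <- read_cohort_csv("results/analysis/cohort.csv")

mc <- misclassification_table(cohort)
write.csv(mc, "results/analysis/misclassification.csv", row.names = FALSE)

em <- egfr_matrix(cohort)
bands <- do.call(rbind, lapply(formula_ids(), function(fid) {
  f <- error_band_distribution(percent_differences(cohort$mgfr, em[[fid]]))
  data.frame(formula_id = fid, band = names(f), fraction = unname(f))
}))
write.csv(bands, "results/analysis/error_bands.csv", row.names = FALSE)

flags <- tolvaptan_flags(cohort$age, cohort$mgfr)
write.csv(cbind(id = cohort$id, flags),
          "results/analysis/tolvaptan_flags.csv", row.names = FALSE)

n_below <- mc$n_below[1]
message(sprintf("subjects with mGFR < 30 ml/min: %d", n_below))
for (i in seq_len(nrow(mc))) {
  message(sprintf("  %-18s estimates %d/%d (%.0f%%) of them at >= 30; undercalls %d/%d in the 30-40 band",
                  mc$formula_id[i], mc$n_below_est_above[i], mc$n_below[i],
                  mc$pct_below_est_above[i], mc$n_band_est_below[i],
                  mc$n_in_band[i]))
}
lt10 <- bands$fraction[bands$band == "<10%"]
message(sprintf("errors < 10%% of mGFR: %.0f-%.0f%% of estimations depending on equation",
                100 * min(lt10), 100 * max(lt10)))
message("wrote results/analysis/{misclassification,error_bands,tolvaptan_flags}.csv")
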