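#!/usr/bin/env Rscript
# Agreement stage: CCC, empirical TDI(0.90) and coverage probability at
# +/-10% for every equation against measured GFR, with conservative
# one-sided bootstrap bounds (B = 2000).

suppressPackageStartupMessages(library(gfragree))
cohort <- read_cohort_csv("results/analysis/cohort.csv")

tab <- agreement_table(cohort, seed = 19, B = 2000)
write.csv(tab, "results/analysis/agreement_table.csv", row.names = FALSE)

print(tab[, c("formula_id", "basis", "ccc", "ccc_bound",
              "tdi", "tdi_bound", "cp", "cp_bound")])
for (b in c("creatinine", "cystatin", "both")) {
  sel <- tab$basis == b
  message(sprintf("%s-based equations: TDI %d-%d%% (mean %.0f), CCC mean %.2f, cp mean %.0f",
                  b, min(tab$tdi[sel]), max(tab$tdi[sel]), mean(tab$tdi[sel]),
                  mean(tab$ccc[sel]), mean(tab$cp[sel])))
}
message("wrote results/analysis/agreement_table.csv")
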