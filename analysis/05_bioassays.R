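#!/usr/bin/env Rscript
# Dose-response quantification of resistance: per-population log-probit fits
# (with Abbott correction from the control rows), LC50/LC95 with Fieller
# fiducial limits, and resistance ratios against the susceptible reference
# with the dual significance rule.

suppressPackageStartupMessages(library(btiscan))

assays <- read.csv("results/data/bioassays.csv")
pops <- setdiff(unique(assays$population), "reference")
ref_fit <- suppressWarnings(
  fit_probit(assays[assays$population == "reference", ]))

rows <- lapply(pops, function(p) {
  fit <- suppressWarnings(fit_probit(assays[assays$population == p, ]))
  lc50 <- lethal_concentration(fit, 0.5)
  lc95 <- lethal_concentration(fit, 0.95)
  rr50 <- resistance_ratio(fit, ref_fit, 0.5)
  rr95 <- resistance_ratio(fit, ref_fit, 0.95)
  data.frame(population = p,
             lc50 = lc50[["lc"]], lc50_lo = lc50[["lower"]],
             lc50_hi = lc50[["upper"]],
             lc95 = lc95[["lc"]],
             rr50 = rr50$rr, rr50_lo = rr50$ci[["lower"]],
             rr50_hi = rr50$ci[["upper"]], rr50_sig = rr50$significant,
             rr95 = rr95$rr, rr95_sig = rr95$significant,
             heterogeneity = fit$heterogeneity)
})
out <- do.call(rbind, rows)
print(out, digits = 3)
write.table(out, "results/resistance_ratios.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.csv("results/data/bioassays_truth.csv")
cmp <- merge(out, truth, by = "population")
message(sprintf("median |LC50 error| = %.1f%%",
                100 * median(abs(cmp$lc50 / cmp$lc50_true - 1))))
message(sprintf("%d of %d populations significantly resistant (RR50 rule)",
                sum(out$rr50_sig), nrow(out)))
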