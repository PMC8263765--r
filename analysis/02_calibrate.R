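#!/usr/bin/env Rscript
# Fit per-gene standard curves from the calibration plate and persist the
# curve store. Each curve is delta-Ct regressed on log2(methylated
# fraction) over the six-point two-fold dilution series (100% .. 3.12%);
# an ideal-efficiency PCR has slope -1 cycle per two-fold step.

suppressPackageStartupMessages(library(cmdx))

curves <- read_calibration_plate("results/prospective/calibration_plate.csv")
write_curve_store(curves, "results/curves.json")

tab <- do.call(rbind, lapply(curves, function(cv)
  data.frame(gene = cv$gene, slope = round(cv$slope, 4),
             intercept = round(cv$intercept, 4),
             residual_rms = round(cv$residual_rms, 4))))
write.csv(tab, "results/calibration_curves.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat(sprintf("fitted %d curves; slopes span [%.3f, %.3f] cycles/log2\n",
            nrow(tab), min(tab$slope), max(tab$slope)))
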