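#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a per-gene calibration plate and two
# Ct-level cohorts shaped like the two study designs -- a prospective
# cohort (110 malignant + 120 benign aspirates, 12/230 inadequate) and a
# pilot cohort (72 malignant + 53 benign by cytology). Everything below is
# reproducible from the seeds written into the configs.

suppressPackageStartupMessages(library(cmdx))
dir.create("results", showWarnings = FALSE)

prospective <- cohort_config(seed = 20260101L)
pilot <- cohort_config(n_malignant = 72L, n_benign = 53L,
                       inadequate_rate = 0, seed = 20260102L)

write_demo_study("results/prospective", prospective)
write_demo_study("results/pilot", pilot)

md <- read.csv("results/prospective/metadata.csv")
cat(sprintf("prospective cohort: %d aspirates (%d malignant, %d benign), %d masked inadequate\n",
            nrow(md), sum(md$histology == "malignant"),
            sum(md$histology == "benign"), sum(md$inadequate)))
md2 <- read.csv("results/pilot/metadata.csv")
cat(sprintf("pilot cohort: %d aspirates (%d malignant, %d benign by design)\n",
            nrow(md2), sum(md2$histology == "malignant"),
            sum(md2$histology == "benign")))
cat("inputs written under results/prospective and results/pilot\n")
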