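#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multiphase-CT cohort.
#
# Four contrast phases per subject, two simulated readers' masks, and a
# clinical covariate table. Volumes go to results/cohort as NIfTI; the
# clinical table and manifest as CSV/JSON.

source("analysis/00_config.R")

cfg <- analysis_cohort_config()
cat("Generating", sum(cfg$counts), "subjects...\n")
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort")

tab <- generate_clinical_table(cohort)
cat("Cohort written to results/cohort:",
    nrow(tab), "subjects;",
    sum(tab$subtype == "ccRCC"), "ccRCC /",
    sum(tab$subtype == "pRCC"), "pRCC /",
    sum(tab$subtype == "cRCC"), "cRCC\n")
cat("Median lesion CMP attenuation by subtype (HU):\n")
print(round(tapply(tab$attenuation_CMP, tab$subtype, median), 1))
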