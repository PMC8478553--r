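# Shared configuration for the analysis stages. Desk-scale sizes: 82
# subjects at the 60:10:12 subtype imbalance (scaled from 209:25:29),
# 28-voxel isotropic grids, 2 learners x 25 repeats of bagged-LASSO
# selection, 100 cross-validation repeats.

library(rccradiomics)

ANALYSIS_SEED <- 20260925L

analysis_cohort_config <- function() {
  cohort_config(counts = c(ccRCC = 60L, pRCC = 10L, cRCC = 12L),
                grid = c(28L, 28L, 28L), radius_range = c(6, 9),
                seed = ANALYSIS_SEED)
}

analysis_selection_config <- function(seed_offset = 0L) {
  selection_config(n_learners = 2L, n_repeats = 25L,
                   seed = ANALYSIS_SEED + seed_offset)
}

ANALYSIS_CV_REPEATS <- 100L
PHASES5 <- c("NCP", "CMP", "NP", "EP", "ALLP")
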