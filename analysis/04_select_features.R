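#!/usr/bin/env Rscript
# Stage 4: ensemble bagged-LASSO stability selection on the ICC-retained
# features of each phase model. Per class, repeated stratified 5-fold
# LASSO fits on the one-vs-rest indicator; fits with validation R^2 > 0.8
# are kept and features with nonzero-coefficient frequency >= 0.2 selected.
# Reports go to results/selection_<phase>.csv.

source("analysis/00_config.R")

for (p in PHASES5) {
  df <- read.csv(sprintf("results/features_%s_r1.csv", p), check.names = FALSE)
  y <- factor(df$subtype, levels = c("ccRCC", "pRCC", "cRCC"))
  X <- as.matrix(df[, setdiff(colnames(df), c("id", "subtype"))])
  icc <- read.csv(sprintf("results/icc_%s.csv", p))
  X <- X[, icc$feature[icc$retained], drop = FALSE]
  sel <- suppressWarnings(run_stability_selection(
    X, y, analysis_selection_config(seed_offset = match(p, PHASES5))))
  tab <- data.frame(feature = colnames(X))
  for (cl in names(sel$per_class)) {
    tab[[paste0("freq_", cl)]] <- sel$per_class[[cl]]$frequency
  }
  tab$selected <- tab$feature %in% sel$selected
  write.csv(tab, sprintf("results/selection_%s.csv", p), row.names = FALSE)
  cat(sprintf("%-5s %d of %d ICC-retained features selected (status: %s)\n",
              p, length(sel$selected), ncol(X), sel$status))
}
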