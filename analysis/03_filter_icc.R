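#!/usr/bin/env Rscript
# Stage 3: inter-rater reproducibility filter. Per phase, compute the
# two-way random-effects absolute-agreement ICC between the two readers'
# feature matrices and retain features with ICC > 0.80.
# Reports go to results/icc_<phase>.csv.

source("analysis/00_config.R")

read_feats <- function(p, r) {
  df <- read.csv(sprintf("results/features_%s_r%d.csv", p, r),
                 check.names = FALSE)
  as.matrix(df[, setdiff(colnames(df), c("id", "subtype")), drop = FALSE])
}

for (p in PHASES5) {
  m1 <- read_feats(p, 1)
  m2 <- read_feats(p, 2)
  flt <- filter_features(m1, m2, threshold = 0.80)
  write.csv(flt$icc, sprintf("results/icc_%s.csv", p), row.names = FALSE)
  cat(sprintf("%-5s retained %3d / %3d features (median ICC %.3f)\n",
              p, length(flt$retained), ncol(m1),
              median(flt$icc$icc, na.rm = TRUE)))
}
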