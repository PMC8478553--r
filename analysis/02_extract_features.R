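#!/usr/bin/env Rscript
# Stage 2: extract the 105-feature vector per phase (and the 420-feature
# ALL-P concatenation) for both readers' masks. The cohort is regenerated
# from the shared seed, so this stage does not depend on stage 1's files.
# Feature matrices go to results/features_<phase>_r<rater>.csv.

source("analysis/00_config.R")

cohort <- generate_cohort(analysis_cohort_config())
cat("Extracting radiomic features for", length(cohort), "subjects...\n")
for (rater in 1:2) {
  t0 <- Sys.time()
  feats <- extract_cohort_features(cohort, rater = rater)
  for (p in PHASES5) {
    out <- data.frame(id = rownames(feats[[p]]),
                      subtype = as.character(feats$subtype),
                      feats[[p]], check.names = FALSE)
    write.csv(out, sprintf("results/features_%s_r%d.csv", p, rater),
              row.names = FALSE)
  }
  cat(sprintf("rater %d: %d x (4 x 105 + 420) features in %.0f s\n",
              rater, length(cohort),
              as.numeric(Sys.time() - t0, units = "secs")))
}
jsonlite::write_json(extraction_config(), "results/extraction_settings.json",
                     auto_unbox = TRUE, pretty = TRUE)
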