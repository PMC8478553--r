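#!/usr/bin/env Rscript
# Stage 5: fit and cross-validate the subtype models. For each phase: a
# one-vs-rest logistic model over the selected features, evaluated by 100
# repeats of stratified 5-fold cross-validation (3-class task and the three
# binary single-subtype tasks), plus the traditional clinical-variable
# control (Kruskal-Wallis / chi-squared screen at p < 0.05, then OvR
# logistic). Metrics go to results/model_metrics.csv and
# results/binary_metrics.csv; out-of-fold scores to results/scores_*.csv.

source("analysis/00_config.R")

classes <- c("ccRCC", "pRCC", "cRCC")
metric_rows <- list()
binary_rows <- list()

for (p in PHASES5) {
  df <- read.csv(sprintf("results/features_%s_r1.csv", p), check.names = FALSE)
  y <- factor(df$subtype, levels = classes)
  sel <- read.csv(sprintf("results/selection_%s.csv", p))
  if (!any(sel$selected)) {
    cat(sprintf("%-5s no features selected (no fit passed the R^2 bar); %s\n",
                p, "phase model skipped"))
    next
  }
  X <- as.matrix(df[, sel$feature[sel$selected], drop = FALSE])
  cv <- repeated_stratified_cv(X, y, k = 5L, repeats = ANALYSIS_CV_REPEATS,
                               seed = ANALYSIS_SEED + 100L)
  m <- per_class_metrics(cv$confusion)
  metric_rows[[p]] <- cbind(model = p, m$per_class,
                            accuracy = cv$mean_accuracy)
  cat(sprintf("%-5s 3-class mean CV accuracy %.3f\n", p, cv$mean_accuracy))

  # binary single-subtype tasks reuse the phase's selected features
  mean_scores <- matrix(NA_real_, length(y), length(classes),
                        dimnames = list(df$id, classes))
  for (cl in classes) {
    yb <- factor(ifelse(y == cl, cl, "rest"), levels = c("rest", cl))
    cvb <- repeated_stratified_cv(X, yb, k = 5L,
                                  repeats = ANALYSIS_CV_REPEATS,
                                  seed = ANALYSIS_SEED + 200L)
    aucs <- vapply(seq_len(ANALYSIS_CV_REPEATS), function(r) {
      roc_auc(cvb$scores[r, , cl], as.integer(y == cl))
    }, numeric(1))
    mb <- per_class_metrics(cvb$confusion)
    i <- match(cl, mb$per_class$class)
    binary_rows[[paste(p, cl)]] <- data.frame(
      model = p, task = paste0(cl, "_vs_rest"),
      sensitivity = mb$per_class$sensitivity[i],
      specificity = mb$per_class$specificity[i],
      ppv = mb$per_class$precision[i], npv = mb$per_class$npv[i],
      accuracy = mb$accuracy, auc = mean(aucs))
    mean_scores[, cl] <- colMeans(cvb$scores[, , cl, drop = FALSE][, , 1])
  }
  write.csv(data.frame(id = df$id, subtype = y, mean_scores),
            sprintf("results/scores_%s.csv", p), row.names = FALSE)
}

# traditional clinical control
clin <- read.csv("results/cohort/clinical.csv")
y <- factor(clin$subtype, levels = classes)
fit <- fit_traditional(clin, y)
cat("Traditional model variables:", paste(fit$variables, collapse = ", "), "\n")
cvt <- repeated_stratified_cv(fit$design, y, k = 5L,
                              repeats = ANALYSIS_CV_REPEATS,
                              seed = ANALYSIS_SEED + 300L)
mt <- per_class_metrics(cvt$confusion)
metric_rows[["Traditional"]] <- cbind(model = "Traditional", mt$per_class,
                                      accuracy = cvt$mean_accuracy)
write.csv(fit$screen, "results/clinical_screen.csv", row.names = FALSE)
tscores <- vapply(classes, function(cl) {
  colMeans(cvt$scores[, , cl, drop = FALSE][, , 1])
}, numeric(length(y)))
write.csv(data.frame(id = clin$id, subtype = y, tscores),
          "results/scores_Traditional.csv", row.names = FALSE)
cat(sprintf("Traditional mean CV accuracy %.3f\n", cvt$mean_accuracy))

write.csv(do.call(rbind, metric_rows), "results/model_metrics.csv",
          row.names = FALSE)
write.csv(do.call(rbind, binary_rows), "results/binary_metrics.csv",
          row.names = FALSE)
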