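#' Configuration of a full pipeline run
#'
#' @param cohort A [cohort_config()].
#' @param extraction An [extraction_config()].
#' @param icc_threshold Reproducibility retention threshold.
#' @param selection A [selection_config()].
#' @param cv_repeats Repeats of the stratified 5-fold evaluation.
#' @param phases Phase models to run (subset of NCP, CMP, NP, EP, ALLP).
#' @param binary_tasks Whether to run the three one-vs-rest binary tasks.
#' @param traditional Whether to fit the clinical control model.
#' @param outdir Output directory (NULL = no files written).
#' @param seed Global seed; every stage derives a named substream from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       extraction = extraction_config(),
                       icc_threshold = 0.80,
                       selection = selection_config(),
                       cv_repeats = 10L,
                       phases = c("NCP", "CMP", "NP", "EP", "ALLP"),
                       binary_tasks = TRUE,
                       traditional = TRUE,
                       outdir = NULL,
                       seed = 1L) {
  structure(list(cohort = cohort, extraction = extraction,
                 icc_threshold = icc_threshold, selection = selection,
                 cv_repeats = as.integer(cv_repeats), phases = phases,
                 binary_tasks = binary_tasks, traditional = traditional,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full subtype-prediction pipeline
#'
#' generate -> extract (both raters) -> ICC filter -> stability selection ->
#' one-vs-rest fit with repeated stratified cross-validation -> evaluation,
#' for each configured phase model, the three binary tasks, and the clinical
#' control model. Deterministic given the configuration; when `outdir` is
#' set, per-stage CSV/JSON reports and a manifest are written.
#'
#' @param cfg A [run_config()].
#' @return List with the cohort feature matrices, ICC reports, selection
#'   results, per-model `cv_result`s, metric tables, and a manifest.
#' @export
run_pipeline <- function(cfg = run_config()) {
  cfg$cohort$seed <- derive_seed(cfg$seed, 1L)
  cohort <- generate_cohort(cfg$cohort)
  y <- factor(vapply(cohort, `[[`, character(1), "subtype"),
              levels = RCC_CLASSES)
  clinical <- generate_clinical_table(cohort)

  feats_r1 <- extract_cohort_features(cohort, rater = 1L, cfg = cfg$extraction)
  feats_r2 <- extract_cohort_features(cohort, rater = 2L, cfg = cfg$extraction)

  icc_reports <- list()
  retained <- list()
  for (p in cfg$phases) {
    flt <- filter_features(feats_r1[[p]], feats_r2[[p]], cfg$icc_threshold)
    icc_reports[[p]] <- flt$icc
    retained[[p]] <- flt$retained
  }

  selections <- list()
  models <- list()
  for (p in cfg$phases) {
    Xp <- feats_r1[[p]][, retained[[p]], drop = FALSE]
    if (ncol(Xp) == 0) {
      selections[[p]] <- NULL
      next
    }
    scfg <- cfg$selection
    scfg$seed <- derive_seed(cfg$seed, 100L + match(p, cfg$phases))
    sel <- run_stability_selection(Xp, y, scfg)
    selections[[p]] <- sel
    Xsel <- Xp[, intersect(colnames(Xp), sel$selected), drop = FALSE]
    if (ncol(Xsel) == 0) next
    cv <- repeated_stratified_cv(Xsel, y, ovr_model_spec(), k = 5L,
                                 repeats = cfg$cv_repeats,
                                 seed = derive_seed(cfg$seed,
                                                    200L + match(p, cfg$phases)))
    models[[p]] <- list(features = colnames(Xsel), cv = cv,
                        metrics = per_class_metrics(cv$confusion))
  }

  binary <- list()
  if (isTRUE(cfg$binary_tasks)) {
    for (cl in RCC_CLASSES) {
      for (p in cfg$phases) {
        if (is.null(models[[p]])) next
        Xsel <- feats_r1[[p]][, models[[p]]$features, drop = FALSE]
        yb <- factor(ifelse(y == cl, cl, "rest"), levels = c("rest", cl))
        cv <- repeated_stratified_cv(Xsel, yb, ovr_model_spec(), k = 5L,
                                     repeats = cfg$cv_repeats,
                                     seed = derive_seed(cfg$seed,
                                                        300L + match(p, cfg$phases)))
        auc <- mean(vapply(seq_len(cfg$cv_repeats), function(r) {
          roc_auc(cv$scores[r, , cl], as.integer(y == cl))
        }, numeric(1)))
        binary[[paste(cl, p, sep = "_")]] <- list(cv = cv, auc = auc)
      }
    }
  }

  trad <- NULL
  if (isTRUE(cfg$traditional)) {
    ctab <- clinical[, setdiff(colnames(clinical), c("id", "subtype"))]
    scr <- screen_clinical_variables(clinical, y)
    kept <- scr$variable[scr$keep]
    if (length(kept)) {
      design <- clinical_design_matrix(clinical, kept)
      cv <- repeated_stratified_cv(design, y, ovr_model_spec(), k = 5L,
                                   repeats = cfg$cv_repeats,
                                   seed = derive_seed(cfg$seed, 400L))
      trad <- list(screen = scr, variables = kept, cv = cv,
                   metrics = per_class_metrics(cv$confusion))
    } else {
      trad <- list(screen = scr, variables = character(0), cv = NULL,
                   metrics = NULL)
    }
  }

  result <- list(cohort = cohort, clinical = clinical, subtype = y,
                 features = feats_r1, features_rater2 = feats_r2,
                 icc = icc_reports, retained = retained,
                 selections = selections, models = models,
                 binary = binary, traditional = trad,
                 config = cfg)
  if (!is.null(cfg$outdir)) write_pipeline_reports(result, cfg$outdir)
  result
}

write_pipeline_reports <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (p in names(result$icc)) {
    write.csv(result$icc[[p]],
              file.path(outdir, sprintf("icc_%s.csv", p)), row.names = FALSE)
  }
  for (p in names(result$selections)) {
    sel <- result$selections[[p]]
    freq <- sel$per_class[[1]]$frequency
    tab <- data.frame(feature = names(freq))
    for (cl in names(sel$per_class)) {
      tab[[paste0("freq_", cl)]] <- sel$per_class[[cl]]$frequency
    }
    tab$selected <- tab$feature %in% sel$selected
    write.csv(tab, file.path(outdir, sprintf("selection_%s.csv", p)),
              row.names = FALSE)
  }
  metrics_rows <- list()
  for (p in names(result$models)) {
    m <- result$models[[p]]$metrics
    df <- m$per_class
    df$model <- p
    df$accuracy <- m$accuracy
    metrics_rows[[p]] <- df
  }
  if (length(metrics_rows)) {
    write.csv(do.call(rbind, metrics_rows),
              file.path(outdir, "model_metrics.csv"), row.names = FALSE)
  }
  write.csv(result$clinical, file.path(outdir, "clinical.csv"),
            row.names = FALSE)
  manifest <- list(
    seed = result$config$seed,
    phases = result$config$phases,
    n_subjects = length(result$cohort),
    counts = as.list(table(result$subtype)),
    config_hash = sum(utf8ToInt(paste(deparse(result$config), collapse = "")))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
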