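#' Configuration of the bagged-LASSO stability selection
#'
#' Ten base learners each run `n_repeats` independent stratified 5-fold
#' cross-validations of a LASSO regression on a one-vs-rest 0/1 class
#' indicator; fits whose validation R-squared exceeds `r2_threshold` are
#' retained and a feature is selected when its nonzero-coefficient frequency
#' among retained fits reaches `frequency_cutoff`.
#'
#' @param n_learners Number of base learners (default 10).
#' @param n_repeats Complete k-fold cross-validations per learner
#'   (default 1000; scale down for desk-scale runs).
#' @param k Number of folds (default 5: train 80\%, validate 20\%).
#' @param r2_threshold Validation R-squared retention threshold.
#' @param frequency_cutoff Selection frequency cutoff (selected when
#'   frequency >= cutoff).
#' @param lambda_grid L1 penalty grid searched per fit by validation error.
#' @param seed Integer seed fixing the shuffle stream.
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(n_learners = 10L, n_repeats = 1000L, k = 5L,
                             r2_threshold = 0.8, frequency_cutoff = 0.2,
                             lambda_grid = 10^seq(-0.5, -3, length.out = 8),
                             seed = 1L) {
  stopifnot(n_learners >= 1, k >= 2, frequency_cutoff >= 0,
            frequency_cutoff <= 1, r2_threshold <= 1)
  structure(list(n_learners = as.integer(n_learners),
                 n_repeats = as.integer(n_repeats), k = as.integer(k),
                 r2_threshold = r2_threshold,
                 frequency_cutoff = frequency_cutoff,
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Stratified fold assignment
#'
#' Shuffles subjects within each class and deals them round-robin into k
#' folds, so per-fold class proportions deviate from the global ones by at
#' most one subject. Consumes the current RNG stream.
#'
#' @param y Factor of class labels.
#' @param k Number of folds.
#' @return Integer fold id per subject.
#' @export
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(sample.int(k), length(idx))
  }
  folds
}

standardize_train <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv,
       X = sweep(sweep(X, 2, mu), 2, sdv, `/`))
}

apply_standardize <- function(X, st) {
  sweep(sweep(X, 2, st$mu), 2, st$sd, `/`)
}

#' One LASSO fit on a training split, scored on a validation split
#'
#' Features are standardized on the training split only. The penalty is
#' chosen from `lambda_grid` as the largest (sparsest) value whose
#' validation mean squared error is within `lambda_tol` of the minimum --
#' the usual parsimony rule that keeps bagged nonzero-coefficient
#' frequencies discriminating. The fit is summarized by its validation
#' R-squared (1 - SS_res / SS_tot).
#'
#' @param X_train,y_train Training design matrix and numeric outcome.
#' @param X_val,y_val Validation split.
#' @param lambda_grid Decreasing penalty grid.
#' @param lambda_tol Relative MSE slack of the parsimony rule
#'   (0 = strict minimum; default 0.1).
#' @return List with `coef` (named, without intercept), `lambda`, `r2`;
#'   or `NULL` when the fold is degenerate (constant outcome in either
#'   split), which the caller logs as skipped.
#' @export
fit_lasso_fold <- function(X_train, y_train, X_val, y_val,
                           lambda_grid = 10^seq(-0.5, -3, length.out = 8),
                           lambda_tol = 0.1) {
  if (length(unique(y_train)) < 2 || length(unique(y_val)) < 2) return(NULL)
  st <- standardize_train(X_train)
  fit <- glmnet::glmnet(st$X, y_train, family = "gaussian", alpha = 1,
                        lambda = lambda_grid, standardize = FALSE)
  Xv <- apply_standardize(X_val, st)
  pred <- predict(fit, Xv)
  mse <- colMeans((matrix(y_val, nrow(Xv), ncol(pred)) - pred)^2)
  # lambdas are decreasing: the first index within tolerance is the sparsest
  best <- which(mse <= min(mse) * (1 + lambda_tol))[1]
  beta <- as.numeric(coef(fit)[-1, best])
  names(beta) <- colnames(X_train)
  ss_res <- sum((y_val - pred[, best])^2)
  ss_tot <- sum((y_val - mean(y_val))^2)
  list(coef = beta, lambda = fit$lambda[best], r2 = 1 - ss_res / ss_tot)
}

#' Ensemble bagged-LASSO stability selection
#'
#' For each class of `y` in turn (one-vs-rest 0/1 indicator), every base
#' learner runs `n_repeats` stratified shuffles, each a complete k-fold
#' cross-validation contributing k fits (train 80\%, validate 20\% at
#' k = 5). Fits with validation R-squared above the threshold are retained;
#' a feature's frequency is the fraction of retained fits in which its
#' coefficient is nonzero, and the selected set per class is
#' `frequency >= frequency_cutoff`. The overall selection is the union over
#' classes. Fully determined by `cfg$seed`.
#'
#' @param X Subjects x features matrix.
#' @param y Factor of subtype labels (>= 2 classes present).
#' @param cfg A [selection_config()].
#' @return Object of class `selection_result`: per-class frequency tables,
#'   retained/total fit counts, per-fit R-squared records, `selected`
#'   (union of class-wise selections), and `status`
#'   ("ok" or "no-fit-retained").
#' @export
run_stability_selection <- function(X, y, cfg = selection_config()) {
  y <- droplevels(as.factor(y))
  stopifnot(nrow(X) == length(y))
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (nrow(X) < 2 * cfg$k) stop("need at least 2k subjects")
  set.seed(cfg$seed)
  classes <- levels(y)
  per_class <- list()
  warned <- FALSE
  for (cl in classes) {
    ind <- as.numeric(y == cl)
    nz_counts <- numeric(ncol(X))
    n_retained <- 0L
    n_fits <- 0L
    r2s <- numeric(0)
    for (l in seq_len(cfg$n_learners)) {
      for (r in seq_len(cfg$n_repeats)) {
        folds <- stratified_folds(y, cfg$k)
        for (f in seq_len(cfg$k)) {
          tr <- folds != f
          fit <- fit_lasso_fold(X[tr, , drop = FALSE], ind[tr],
                                X[!tr, , drop = FALSE], ind[!tr],
                                cfg$lambda_grid)
          if (is.null(fit)) next
          n_fits <- n_fits + 1L
          r2s <- c(r2s, fit$r2)
          if (fit$r2 > cfg$r2_threshold) {
            n_retained <- n_retained + 1L
            nz_counts <- nz_counts + (fit$coef != 0)
          }
        }
      }
    }
    freq <- if (n_retained > 0) nz_counts / n_retained else
      setNames(rep(0, ncol(X)), colnames(X))
    names(freq) <- colnames(X)
    per_class[[cl]] <- list(frequency = freq, n_retained = n_retained,
                            n_fits = n_fits, r2 = r2s,
                            selected = names(freq)[freq >= cfg$frequency_cutoff &
                                                     n_retained > 0])
    if (n_retained == 0L) warned <- TRUE
  }
  selected <- unique(unlist(lapply(per_class, `[[`, "selected")))
  status <- if (length(selected) == 0 || warned) "no-fit-retained" else "ok"
  if (length(selected) == 0) {
    warning("stability selection retained no fits above the R-squared ",
            "threshold; returning an empty selection")
  }
  structure(list(per_class = per_class, selected = selected,
                 config = cfg, status = status),
            class = "selection_result")
}
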