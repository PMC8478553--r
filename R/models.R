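#' Fit a one-vs-rest multinomial classifier from binary logistic sub-models
#'
#' One unpenalized binary logistic regression per class (class vs rest) over
#' standardized features; prediction is the argmax of the three linear
#' scores. Quasi-separation (non-convergence or exploding coefficients) in a
#' sub-model triggers a tiny ridge refit, recorded in the model object.
#'
#' @param X Subjects x features numeric matrix.
#' @param y Factor of class labels; every level must be present.
#' @param ridge_lambda Penalty used by the fallback refit.
#' @return Object of class `ovr_model`.
#' @export
fit_ovr_logistic <- function(X, y, ridge_lambda = 1e-2) {
  y <- as.factor(y)
  X <- as.matrix(X)
  missing_cl <- levels(y)[!(levels(y) %in% unique(as.character(y)))]
  if (length(missing_cl)) {
    stop("class absent from training data: ", paste(missing_cl, collapse = ", "))
  }
  st <- standardize_train(X)
  sub <- list()
  fallback <- character(0)
  for (cl in levels(y)) {
    ind <- as.numeric(y == cl)
    ok <- TRUE
    fit <- withCallingHandlers(
      glm.fit(cbind(1, st$X), ind, family = binomial(),
              control = list(epsilon = 1e-8, maxit = 100)),
      warning = function(w) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      })
    beta <- fit$coefficients
    if (!ok || !fit$converged || any(!is.finite(beta)) ||
        (length(beta) > 1 && max(abs(beta[-1])) > 50)) {
      Xr <- st$X
      if (ncol(Xr) < 2) Xr <- cbind(Xr, 0) # glmnet needs >= 2 columns
      # glmnet warns about small positive classes; expected here (rare
      # subtypes in 5-fold splits), so keep the fallback quiet
      g <- suppressWarnings(
        glmnet::glmnet(Xr, ind, family = "binomial", alpha = 0,
                       lambda = ridge_lambda, standardize = FALSE))
      beta <- as.numeric(coef(g))[seq_len(ncol(st$X) + 1)]
      fallback <- c(fallback, cl)
    }
    sub[[cl]] <- beta
  }
  structure(list(classes = levels(y), coef = sub, standardize = st[c("mu", "sd")],
                 features = colnames(X), fallback = fallback),
            class = "ovr_model")
}

#' Per-class linear scores of a fitted OvR model
#'
#' @param object An `ovr_model`.
#' @param newdata Subjects x features matrix with the model's feature roster.
#' @param ... Unused.
#' @return Matrix of per-class linear predictors (log-odds scale).
#' @export
predict_ovr_scores <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$standardize$mu), 2, object$standardize$sd, `/`)
  scores <- vapply(object$classes, function(cl) {
    b <- object$coef[[cl]]
    drop(cbind(1, Xs) %*% b)
  }, numeric(nrow(Xs)))
  if (nrow(Xs) == 1) scores <- matrix(scores, nrow = 1,
                                      dimnames = list(NULL, object$classes))
  scores
}

#' @export
predict.ovr_model <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  scores <- predict_ovr_scores(object, newdata)
  if (type == "scores") return(scores)
  # argmax; exact ties resolve toward the earlier (more prevalent) class
  cls <- object$classes[apply(scores, 1, which.max)]
  factor(cls, levels = object$classes)
}

#' Model specification for cross-validation
#'
#' A pair of closures (`fit`, `scores`) consumed by
#' [repeated_stratified_cv()]. The default wraps [fit_ovr_logistic()].
#'
#' @param fit `function(X, y) -> model`.
#' @param scores `function(model, X) -> per-class score matrix`.
#' @return List with `fit` and `scores`.
#' @export
ovr_model_spec <- function(fit = fit_ovr_logistic,
                           scores = predict_ovr_scores) {
  list(fit = fit, scores = scores)
}

#' Repeated stratified k-fold cross-validation
#'
#' Per repeat: one stratified k-fold partition of the cohort; the model is
#' fit on k-1 folds and scored on the held-out fold, so every subject is
#' predicted exactly once per repeat. Reported metrics are means over
#' repeats; the pooled confusion matrix accumulates counts over all repeats.
#'
#' @param X Subjects x features matrix.
#' @param y Factor of labels; every class must have at least k members.
#' @param model_spec An [ovr_model_spec()].
#' @param k Folds (default 5).
#' @param repeats Number of repeated partitions.
#' @param seed Integer seed.
#' @return Object of class `cv_result`: `predictions` (long data.frame),
#'   `scores` (repeats x subjects x classes array), `per_repeat`
#'   (data.frame of per-repeat accuracy), `confusion` (pooled counts),
#'   `mean_accuracy`.
#' @export
repeated_stratified_cv <- function(X, y, model_spec = ovr_model_spec(),
                                   k = 5L, repeats = 10L, seed = 1L) {
  y <- droplevels(as.factor(y))
  X <- as.matrix(X)
  if (any(table(y) < k)) {
    stop("cannot stratify: a class has fewer members than folds")
  }
  set.seed(seed)
  n <- length(y)
  classes <- levels(y)
  all_pred <- vector("list", repeats)
  score_arr <- array(NA_real_, dim = c(repeats, n, length(classes)),
                     dimnames = list(NULL, rownames(X), classes))
  acc <- numeric(repeats)
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(predicted = classes, pathology = classes))
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(y, k)
    pred <- factor(rep(classes[1], n), levels = classes)
    for (f in seq_len(k)) {
      tr <- folds != f
      model <- model_spec$fit(X[tr, , drop = FALSE], y[tr])
      sc <- model_spec$scores(model, X[!tr, , drop = FALSE])
      score_arr[r, !tr, ] <- sc
      pred[!tr] <- factor(classes[apply(sc, 1, which.max)], levels = classes)
    }
    acc[r] <- mean(pred == y)
    cm <- confusion_matrix3(pred, y, classes = classes)
    pooled <- pooled + cm
    all_pred[[r]] <- data.frame(repeat_id = r, subject = seq_len(n),
                                fold = folds, predicted = pred, truth = y)
  }
  structure(list(predictions = do.call(rbind, all_pred), scores = score_arr,
                 per_repeat = data.frame(repeat_id = seq_len(repeats),
                                         accuracy = acc),
                 confusion = pooled, mean_accuracy = mean(acc),
                 classes = classes, k = k, repeats = repeats),
            class = "cv_result")
}

#' Binary task labels for a single-subtype experiment
#'
#' @param y Factor or character vector of subtype labels.
#' @param positive_class The class coded 1; all others are 0.
#' @return Integer 0/1 vector.
#' @export
build_binary_task <- function(y, positive_class) {
  y <- as.character(y)
  known <- unique(y)
  if (!positive_class %in% RCC_CLASSES && !positive_class %in% known) {
    stop("unknown class: ", positive_class)
  }
  as.integer(y == positive_class)
}

#' Screen clinical variables by subtype association
#'
#' Continuous variables are tested with the Kruskal-Wallis test across the
#' three subtypes; categorical variables with the chi-squared test on the
#' contingency table. Variables with p < alpha are kept. Categorical
#' variables whose contingency table has an expected count of zero are
#' flagged and excluded with a warning.
#'
#' @param table Clinical data.frame (columns beyond `id`/`subtype` are
#'   candidate variables).
#' @param y Factor of subtype labels.
#' @param alpha Screening level (default 0.05).
#' @return data.frame: variable, type, p, keep.
#' @export
screen_clinical_variables <- function(table, y, alpha = 0.05) {
  vars <- setdiff(colnames(table), c("id", "subtype"))
  rows <- lapply(vars, function(v) {
    x <- table[[v]]
    if (is.numeric(x)) {
      p <- kruskal.test(x, y)$p.value
      type <- "continuous"
    } else {
      tab <- base::table(x, y)
      suppressWarnings(ct <- chisq.test(tab))
      if (any(ct$expected == 0)) {
        warning("variable '", v, "' has empty expected cells; excluded")
        return(data.frame(variable = v, type = "categorical", p = NA_real_,
                          keep = FALSE))
      }
      p <- ct$p.value
      type <- "categorical"
    }
    data.frame(variable = v, type = type, p = p, keep = is.finite(p) & p < alpha)
  })
  do.call(rbind, rows)
}

#' Fit the traditional clinical-variable control model
#'
#' Screens the clinical covariates at p < alpha and fits a one-vs-rest
#' logistic model over the surviving variables (factors expanded to
#' indicator columns).
#'
#' @param table Clinical data.frame.
#' @param y Factor of subtype labels.
#' @param alpha Screening level.
#' @return List with `screen` (screening table), `design` (model matrix),
#'   `model` (`ovr_model`).
#' @export
fit_traditional <- function(table, y, alpha = 0.05) {
  scr <- screen_clinical_variables(table, y, alpha)
  kept <- scr$variable[scr$keep]
  if (!length(kept)) stop("no clinical variable passed the screen")
  design <- clinical_design_matrix(table, kept)
  model <- fit_ovr_logistic(design, y)
  list(screen = scr, design = design, model = model, variables = kept)
}

#' Expand selected clinical variables into a numeric design matrix
#'
#' @param table Clinical data.frame.
#' @param vars Variables to include.
#' @return Numeric matrix (factors as 0/1 indicator columns, reference
#'   level dropped).
#' @export
clinical_design_matrix <- function(table, vars) {
  cols <- lapply(vars, function(v) {
    x <- table[[v]]
    if (is.numeric(x)) {
      m <- matrix(x, ncol = 1, dimnames = list(NULL, v))
    } else {
      f <- as.factor(x)
      lv <- levels(f)[-1]
      m <- vapply(lv, function(l) as.numeric(f == l), numeric(length(f)))
      if (is.null(dim(m))) m <- matrix(m, ncol = length(lv))
      colnames(m) <- paste0(v, "_", lv)
    }
    m
  })
  do.call(cbind, cols)
}
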