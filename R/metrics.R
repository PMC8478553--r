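#' 3x3 confusion matrix (rows = predicted, columns = pathology)
#'
#' @param predicted,pathology Equal-length label vectors.
#' @param classes Class order; defaults to (ccRCC, pRCC, cRCC).
#' @return Integer matrix with `counts[i, j] = #(predicted = class_i &
#'   pathology = class_j)`.
#' @export
confusion_matrix3 <- function(predicted, pathology,
                              classes = c("ccRCC", "pRCC", "cRCC")) {
  predicted <- as.character(predicted)
  pathology <- as.character(pathology)
  if (length(predicted) != length(pathology)) {
    stop("label vectors must have equal length")
  }
  unknown <- setdiff(unique(c(predicted, pathology)), classes)
  if (length(unknown)) stop("unknown label: ", paste(unknown, collapse = ", "))
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(predicted = classes, pathology = classes))
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      cm[i, j] <- sum(predicted == classes[i] & pathology == classes[j])
    }
  }
  cm
}

#' Per-class classification metrics from a confusion matrix
#'
#' Sensitivity, specificity, precision, negative predictive value, and f1
#' per class, plus overall accuracy (trace / total). Cells with a zero
#' denominator are reported as `NA`.
#'
#' @param cm Square confusion matrix, rows = predicted, columns = truth.
#' @return List with `per_class` (data.frame) and `accuracy`.
#' @export
per_class_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  classes <- colnames(cm)
  if (is.null(classes)) classes <- paste0("class", seq_len(ncol(cm)))
  rows <- lapply(seq_along(classes), function(c) {
    tp <- cm[c, c]
    fn <- sum(cm[-c, c])
    fp <- sum(cm[c, -c])
    tn <- sum(cm[-c, -c])
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
      2 * prec * sens / (prec + sens)
    } else NA_real_
    data.frame(class = classes[c], sensitivity = sens, specificity = spec,
               precision = prec, npv = npv, f1 = f1)
  })
  list(per_class = do.call(rbind, rows),
       accuracy = sum(diag(cm)) / total)
}

#' Round half-up to a number of decimals
#'
#' Display rounding matching conventional table formatting (0.845 -> 0.85),
#' unlike banker's rounding.
#' @param x Numeric.
#' @param digits Decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Area under the ROC curve via the Mann-Whitney statistic
#'
#' AUC equals the probability that a random positive scores above a random
#' negative, ties counted one half; computed from midranks.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 (or logical, or two-level factor) labels.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  lab <- normalize_binary(labels)
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

normalize_binary <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) stop("labels must be binary 0/1")
  labels
}

# placement values: V10[i] = P(score of positive i beats a random negative)
delong_placements <- function(scores, lab) {
  xs <- scores[lab == 1]
  ys <- scores[lab == 0]
  m <- length(xs); n <- length(ys)
  v10 <- vapply(xs, function(x) (sum(x > ys) + 0.5 * sum(x == ys)) / n,
                numeric(1))
  v01 <- vapply(ys, function(y) (sum(xs > y) + 0.5 * sum(xs == y)) / m,
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same subjects.
#' The variance of the AUC difference is built from the empirical covariance
#' of the per-positive and per-negative placement values; z is referred to
#' the standard normal (two-sided).
#'
#' @param scores_a,scores_b Score vectors from the two models, same subjects.
#' @param labels Binary labels.
#' @return List: `auc_a`, `auc_b`, `z`, `p`, `se_diff`, `degenerate`
#'   (TRUE when the difference has zero variance, in which case p = 1).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  lab <- normalize_binary(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(lab)) {
    stop("score vectors and labels must align")
  }
  pa <- delong_placements(scores_a, lab)
  pb <- delong_placements(scores_b, lab)
  m <- sum(lab == 1); n <- sum(lab == 0)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1,
                se_diff = 0, degenerate = TRUE))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = 2 * pnorm(-abs(z)), se_diff = sqrt(var_diff), degenerate = FALSE)
}

#' Confusion matrices of the published three-subtype models
#'
#' The reported test-set confusion matrices (rows = predicted, columns =
#' pathology; class order ccRCC, pRCC, cRCC) of the five radiomic phase
#' models and the traditional clinical model, used as inputs when
#' reproducing the reported per-class metrics.
#'
#' @return Named list of six 3x3 integer matrices
#'   (NCP, CMP, NP, EP, ALLP, Traditional).
#' @export
reported_confusion_matrices <- function() {
  mk <- function(v) matrix(as.integer(v), 3, 3, byrow = TRUE,
                           dimnames = list(predicted = RCC_CLASSES,
                                           pathology = RCC_CLASSES))
  list(
    NCP = mk(c(129, 13, 9, 38, 6, 3, 40, 6, 17)),
    CMP = mk(c(165, 4, 3, 17, 10, 9, 25, 11, 17)),
    NP = mk(c(159, 11, 10, 34, 4, 6, 14, 10, 13)),
    EP = mk(c(146, 9, 8, 31, 8, 10, 30, 8, 11)),
    ALLP = mk(c(175, 5, 4, 16, 15, 6, 16, 5, 19)),
    Traditional = mk(c(201, 18, 20, 3, 3, 3, 3, 4, 6))
  )
}
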