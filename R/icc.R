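#' Two-way random-effects, absolute-agreement, single-measurement ICC
#'
#' ICC(2,1) from the two-way ANOVA decomposition of an n-subject x 2-rater
#' table: (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E)) with
#' k = 2 raters. The consistency form (MS_R - MS_E)/(MS_R + (k-1) MS_E)
#' drops the rater variance term.
#'
#' @param x1,x2 Per-subject feature values from rater 1 and rater 2; equal
#'   length n >= 3, finite.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return ICC estimate in (-Inf, 1], or `NA` when the table has zero total
#'   variance (undefined; treated downstream as not reproducible).
#' @export
icc_two_rater <- function(x1, x2, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  if (length(x1) != length(x2)) stop("rater vectors must have equal length")
  n <- length(x1)
  if (n < 3) stop("at least 3 subjects are required")
  if (any(!is.finite(x1)) || any(!is.finite(x2))) stop("values must be finite")
  k <- 2
  y <- cbind(x1, x2)
  if (all(y == y[1, 1])) return(NA_real_)
  grand <- mean(y)
  row_means <- rowMeans(y)
  col_means <- colMeans(y)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  den <- if (type == "agreement") {
    msr + (k - 1) * mse + (k / n) * (msc - mse)
  } else {
    msr + (k - 1) * mse
  }
  if (den <= 0) return(NA_real_)
  (msr - mse) / den
}

#' Filter features by inter-rater reproducibility
#'
#' Computes the per-feature ICC between the two raters' feature matrices and
#' retains features with ICC strictly above the threshold. Features whose
#' ICC is undefined (zero variance) are treated as not reproducible.
#'
#' @param matrix_r1,matrix_r2 Subjects x features matrices with identical
#'   rosters and subject order.
#' @param threshold Retention threshold (strict inequality); default 0.80.
#' @param type ICC form passed to [icc_two_rater()].
#' @return List with `icc` (data.frame: feature, icc, retained) and
#'   `retained` (character vector of feature names).
#' @export
filter_features <- function(matrix_r1, matrix_r2, threshold = 0.80,
                            type = "agreement") {
  if (!identical(colnames(matrix_r1), colnames(matrix_r2))) {
    stop("feature rosters differ between raters")
  }
  if (nrow(matrix_r1) != nrow(matrix_r2)) {
    stop("subject sets differ between raters")
  }
  icc <- vapply(seq_len(ncol(matrix_r1)), function(j) {
    icc_two_rater(matrix_r1[, j], matrix_r2[, j], type = type)
  }, numeric(1))
  retained_flag <- !is.na(icc) & icc > threshold
  tab <- data.frame(feature = colnames(matrix_r1), icc = icc,
                    retained = retained_flag, stringsAsFactors = FALSE)
  list(icc = tab, retained = tab$feature[retained_flag])
}
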