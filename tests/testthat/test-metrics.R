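test_that("confusion matrix counts match definitions and a loop oracle", {
  cls <- c("ccRCC", "pRCC", "cRCC")
  perfect <- confusion_matrix3(rep(cls, each = 10), rep(cls, each = 10))
  expect_equal(unname(diag(perfect)), rep(10L, 3))
  expect_equal(sum(perfect), 30L)

  truth <- rep(cls, times = c(209, 25, 29))
  all_cc <- confusion_matrix3(rep("ccRCC", 263), truth)
  expect_equal(unname(all_cc[1, ]), c(209L, 25L, 29L))
  expect_equal(sum(all_cc[2:3, ]), 0L)

  set.seed(41)
  pred <- sample(cls, 200, replace = TRUE)
  path <- sample(cls, 200, replace = TRUE)
  expect_equal(confusion_matrix3(pred, path), oracle_confusion(pred, path, cls))
  expect_error(confusion_matrix3(c("ccRCC", "AML"), c("ccRCC", "pRCC")),
               "unknown label")
})

test_that("per-class metrics reproduce the reported ALL-P table values", {
  cm <- reported_confusion_matrices()$ALLP
  m <- per_class_metrics(cm)
  expect_equal(round_half_up(m$accuracy), 0.80)
  pc <- m$per_class
  expect_equal(round_half_up(pc$sensitivity), c(0.85, 0.60, 0.66))
  expect_equal(round_half_up(pc$specificity), c(0.83, 0.91, 0.91))
  expect_equal(round_half_up(pc$precision[1]), 0.95)
})

test_that("per-class metrics equal a per-sample expansion oracle", {
  cls <- c("ccRCC", "pRCC", "cRCC")
  set.seed(42)
  pred <- sample(cls, 150, replace = TRUE, prob = c(.6, .2, .2))
  path <- sample(cls, 150, replace = TRUE, prob = c(.7, .1, .2))
  cm <- confusion_matrix3(pred, path)
  m <- per_class_metrics(cm)
  for (c in seq_along(cls)) {
    tp <- sum(pred == cls[c] & path == cls[c])
    fn <- sum(pred != cls[c] & path == cls[c])
    fp <- sum(pred == cls[c] & path != cls[c])
    tn <- sum(pred != cls[c] & path != cls[c])
    expect_equal(m$per_class$sensitivity[c], tp / (tp + fn))
    expect_equal(m$per_class$specificity[c], tn / (tn + fp))
    expect_equal(m$per_class$precision[c], tp / (tp + fp))
    expect_equal(m$per_class$npv[c], tn / (tn + fn))
    prec <- tp / (tp + fp); sens <- tp / (tp + fn)
    expect_equal(m$per_class$f1[c], 2 * prec * sens / (prec + sens))
  }
  expect_equal(m$accuracy, mean(pred == path))
  # identity matrix: every metric 1
  ident <- per_class_metrics(diag(5L, 3))
  expect_true(all(as.matrix(ident$per_class[, -1]) == 1))
  expect_equal(ident$accuracy, 1)
})

test_that("zero-denominator metric cells come back as NA sentinels", {
  cm <- matrix(c(10L, 0L, 0L, 0L, 0L, 0L, 3L, 0L, 4L), 3, 3,
               dimnames = list(predicted = c("ccRCC", "pRCC", "cRCC"),
                               pathology = c("ccRCC", "pRCC", "cRCC")))
  m <- per_class_metrics(cm)
  expect_true(is.na(m$per_class$precision[2])) # never predicted pRCC
  expect_true(is.na(m$per_class$sensitivity[2])) # no pRCC in truth either
})

test_that("AUC equals exhaustive pair enumeration and handles ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(43)
  scores <- sample(seq(0, 5, by = 0.5), 30, replace = TRUE) # forced ties
  labels <- rbinom(30, 1, 0.4)
  expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(scores), labels), roc_auc(scores, labels))
  expect_equal(roc_auc(qlogis((scores + 1) / 8), labels),
               roc_auc(scores, labels))
})

test_that("AUC and DeLong agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  n <- 80
  labels <- rbinom(n, 1, 0.35)
  sa <- labels * 1.2 + rnorm(n)
  sb <- labels * 0.4 + rnorm(n)
  ra <- pROC::roc(labels, sa, quiet = TRUE, direction = "<")
  expect_equal(roc_auc(sa, labels), as.numeric(pROC::auc(ra)))
  dl <- delong_test(sa, sb, labels)
  ref <- pROC::roc.test(ra, pROC::roc(labels, sb, quiet = TRUE,
                                      direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(dl$p, ref$p.value, tolerance = 1e-10)
  expect_equal(abs(dl$z), abs(unname(ref$statistic)), tolerance = 1e-10)
})

test_that("DeLong self-comparison is exactly p = 1 and flagged degenerate", {
  set.seed(45)
  s <- rnorm(40)
  lab <- rbinom(40, 1, 0.5)
  dl <- delong_test(s, s, lab)
  expect_equal(dl$p, 1)
  expect_true(dl$degenerate)
  expect_equal(dl$auc_a, dl$auc_b)
})

test_that("DeLong SE agrees with a bootstrap oracle on a small fixed case", {
  set.seed(46)
  n <- 12
  lab <- rep(c(1, 0), each = 6)
  sa <- c(rnorm(6, 1.0), rnorm(6, 0))
  sb <- c(rnorm(6, 0.6), rnorm(6, 0))
  dl <- delong_test(sa, sb, lab)
  boots <- replicate(4000, {
    i <- c(sample(1:6, replace = TRUE), sample(7:12, replace = TRUE))
    roc_auc(sa[i], lab[i]) - roc_auc(sb[i], lab[i])
  })
  expect_equal(dl$se_diff, sd(boots), tolerance = 0.15)
})

test_that("DeLong type-I error is calibrated under the null", {
  set.seed(47)
  nsim <- 500
  rejected <- vapply(seq_len(nsim), function(i) {
    lab <- rep(c(1, 0), each = 100)
    sa <- rnorm(200) # both scores useless and independent
    sb <- rnorm(200)
    delong_test(sa, sb, lab)$p < 0.05
  }, logical(1))
  expect_gt(mean(rejected), 0.03)
  expect_lt(mean(rejected), 0.07)
})

test_that("display rounding is half-up at 2 decimals", {
  expect_equal(round_half_up(0.845), 0.85)
  expect_equal(round_half_up(0.8449), 0.84)
  expect_equal(round_half_up(0.005), 0.01)
})
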