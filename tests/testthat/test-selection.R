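test_that("a noiseless linear signal is recovered with validation R2 ~ 1", {
  set.seed(61)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2 * X[, 3]
  tr <- seq_len(40); va <- 41:60
  fit <- fit_lasso_fold(X[tr, ], y[tr], X[va, ], y[va],
                        lambda_grid = 10^seq(-1, -4, length.out = 6))
  expect_gt(abs(fit$coef["f3"]), 0)
  expect_gt(fit$r2, 0.99)
})

test_that("an overwhelming penalty shrinks everything to zero", {
  set.seed(62)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] + rnorm(n, 0, .1)
  fit <- fit_lasso_fold(X[1:40, ], y[1:40], X[41:50, ], y[41:50],
                        lambda_grid = 1e6)
  expect_true(all(fit$coef == 0))
  expect_lte(fit$r2, 0.05)
})

test_that("degenerate folds (constant outcome) are skipped", {
  X <- matrix(rnorm(40), 20, 2)
  expect_null(fit_lasso_fold(X[1:15, ], rep(1, 15), X[16:20, ], rnorm(5)))
  expect_null(fit_lasso_fold(X[1:15, ], rnorm(15), X[16:20, ], rep(0, 5)))
})

test_that("LASSO coefficients match an independent coordinate-descent oracle", {
  set.seed(63)
  n <- 20; p <- 5
  X <- scale(matrix(rnorm(n * p), n, p))
  X <- X * sqrt(n / (n - 1)) # population-sd scaling to match glmnet
  y <- X[, 2] - 0.5 * X[, 4] + rnorm(n, 0, 0.3)
  for (lam in c(0.05, 0.2)) {
    g <- glmnet::glmnet(X, y, alpha = 1, lambda = c(0.8, 0.4, lam),
                        standardize = FALSE, thresh = 1e-14)
    got <- as.numeric(coef(g)[, 3])
    want <- oracle_lasso_cd(X, y, lam)
    expect_equal(got[-1], want$beta, tolerance = 1e-6)
    expect_equal(got[1], want$intercept, tolerance = 1e-6)
  }
})

test_that("stability selection recovers a planted feature and is seeded", {
  set.seed(64)
  n <- 100
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  cls <- rep(c("A", "B"), each = n / 2)
  X[, 4] <- (cls == "A") + rnorm(n, 0, 0.25) # strong planted signal
  y <- factor(cls)
  cfg <- selection_config(n_learners = 2L, n_repeats = 10L, seed = 99L)
  res <- run_stability_selection(X, y, cfg)
  expect_s3_class(res, "selection_result")
  expect_true("f4" %in% res$selected)
  expect_gt(res$per_class$A$frequency["f4"], 0.9)
  noise_freq <- res$per_class$A$frequency[paste0("f", c(1:3, 5:10))]
  expect_lt(median(noise_freq), cfg$frequency_cutoff)
  # determinism
  res2 <- run_stability_selection(X, y, cfg)
  expect_identical(res$per_class$A$frequency, res2$per_class$A$frequency)
  # frequencies are proper fractions and invariant to column order
  expect_true(all(res$per_class$A$frequency >= 0 &
                    res$per_class$A$frequency <= 1))
  perm <- c(7, 2, 9, 4, 1, 3, 10, 5, 8, 6)
  res3 <- run_stability_selection(X[, perm], y, cfg)
  expect_equal(res3$per_class$A$frequency[colnames(X)],
               res$per_class$A$frequency)
})

test_that("frequency cutoff 0 selects every feature ever active", {
  set.seed(65)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  cls <- rep(c("A", "B"), each = n / 2)
  X[, 1] <- (cls == "A") + rnorm(n, 0, 0.2)
  cfg <- selection_config(n_learners = 1L, n_repeats = 5L,
                          frequency_cutoff = 0, seed = 4L)
  res <- run_stability_selection(X, factor(cls), cfg)
  active <- names(which(res$per_class$A$frequency > 0 |
                          res$per_class$B$frequency > 0))
  expect_setequal(res$selected, unique(c(active, res$selected)))
  expect_true("f1" %in% res$selected)
})

test_that("selection matches an independently scripted nested-loop oracle", {
  set.seed(66)
  n <- 20
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  cls <- rep(c("A", "B"), each = n / 2)
  X[, 2] <- 2 * (cls == "A") + rnorm(n, 0, 0.3)
  y <- factor(cls)
  cfg <- selection_config(n_learners = 2L, n_repeats = 3L, seed = 31L)
  res <- run_stability_selection(X, y, cfg)
  # oracle: replay the same seed stream with an explicit loop
  set.seed(cfg$seed)
  for (cl in levels(y)) {
    ind <- as.numeric(y == cl)
    nz <- numeric(ncol(X)); kept <- 0L
    for (l in 1:2) for (r in 1:3) {
      folds <- stratified_folds(y, 5L)
      for (f in 1:5) {
        tr <- folds != f
        fit <- fit_lasso_fold(X[tr, , drop = FALSE], ind[tr],
                              X[!tr, , drop = FALSE], ind[!tr],
                              cfg$lambda_grid)
        if (is.null(fit)) next
        if (fit$r2 > 0.8) { kept <- kept + 1L; nz <- nz + (fit$coef != 0) }
      }
    }
    if (kept > 0) {
      expect_equal(unname(res$per_class[[cl]]$frequency), unname(nz / kept))
    }
    expect_equal(res$per_class[[cl]]$n_retained, kept)
  }
})

test_that("pure-noise outcomes select less as the R2 bar rises", {
  set.seed(67)
  n <- 50
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- factor(rep(c("A", "B"), each = n / 2))
  sizes <- vapply(c(0.1, 0.5, 0.9), function(th) {
    cfg <- selection_config(n_learners = 1L, n_repeats = 5L,
                            r2_threshold = th, seed = 8L)
    res <- suppressWarnings(run_stability_selection(X, y, cfg))
    length(res$selected)
  }, numeric(1))
  expect_true(sizes[3] <= sizes[1])
  # warning (not an exception) when nothing is retained
  cfg <- selection_config(n_learners = 1L, n_repeats = 2L,
                          r2_threshold = 0.999999, seed = 8L)
  expect_warning(res <- run_stability_selection(X, y, cfg), "empty")
  expect_length(res$selected, 0L)
  expect_equal(res$status, "no-fit-retained")
})
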