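make_clusters <- function(n_per = 20, sep = 8, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  X <- do.call(rbind, lapply(1:3, function(i) {
    cbind(rnorm(n_per, centers[i, 1]), rnorm(n_per, centers[i, 2]))
  }))
  colnames(X) <- c("u", "v")
  y <- factor(rep(c("ccRCC", "pRCC", "cRCC"), each = n_per),
              levels = c("ccRCC", "pRCC", "cRCC"))
  list(X = X, y = y)
}

test_that("OvR logistic separates a separable 3-class toy exactly", {
  d <- make_clusters()
  m <- fit_ovr_logistic(d$X, d$y)
  pred <- predict(m, d$X)
  expect_equal(mean(pred == d$y), 1.0)
  # row permutation leaves the model unchanged
  perm <- sample(seq_along(d$y))
  m2 <- fit_ovr_logistic(d$X[perm, ], d$y[perm])
  expect_equal(m$coef, m2$coef, tolerance = 1e-6)
  # a class missing from training is an explicit error naming it
  keep <- d$y != "cRCC"
  expect_error(fit_ovr_logistic(d$X[keep, ], d$y[keep]), "cRCC")
})

test_that("logistic coefficient recovery at n = 500", {
  set.seed(77)
  n <- 500
  x <- rnorm(n)
  beta <- 1.2
  p <- 1 / (1 + exp(-(0.3 + beta * x)))
  y <- factor(ifelse(rbinom(n, 1, p) == 1, "A", "B"), levels = c("A", "B"))
  m <- fit_ovr_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
  # coefficient on the standardized scale -> back to raw
  b_raw <- m$coef[["A"]][2] / m$standardize$sd
  se <- summary(glm(I(y == "A") ~ x, family = binomial()))$coefficients["x", 2]
  expect_lt(abs(b_raw - beta), se)
})

test_that("repeated stratified CV partitions every subject once per repeat", {
  d <- make_clusters(n_per = 10, sep = 3, seed = 2)
  cv <- repeated_stratified_cv(d$X, d$y, k = 5L, repeats = 3L, seed = 9L)
  for (r in 1:3) {
    pr <- cv$predictions[cv$predictions$repeat_id == r, ]
    expect_equal(sort(pr$subject), 1:30)
    expect_equal(unname(table(pr$fold)), array(rep(6L, 5)),
                 ignore_attr = TRUE)
    # stratification: each fold holds 2 of each class
    for (f in 1:5) {
      expect_equal(unname(table(pr$truth[pr$fold == f])),
                   array(rep(2L, 3)), ignore_attr = TRUE)
    }
  }
  expect_equal(sum(cv$confusion), 90L)
  # determinism
  cv2 <- repeated_stratified_cv(d$X, d$y, k = 5L, repeats = 3L, seed = 9L)
  expect_identical(cv$predictions, cv2$predictions)
  expect_error(repeated_stratified_cv(d$X[1:12, ], d$y[1:12], k = 5L),
               "stratify")
})

test_that("shuffled labels give chance-level AUC on average", {
  # average over independently shuffled datasets (a single dataset's CV AUC
  # is itself a random quantity centred near 0.5 with a slight pessimism
  # bias typical of cross-validated null discrimination)
  set.seed(31)
  n <- 60
  mean_aucs <- vapply(1:20, function(d) {
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- factor(sample(rep(c("pos", "neg"), each = n / 2)),
                levels = c("neg", "pos"))
    cv <- repeated_stratified_cv(X, y, k = 5L, repeats = 10L,
                                 seed = 100L + d)
    mean(vapply(1:10, function(r) {
      roc_auc(cv$scores[r, , "pos"], as.integer(y == "pos"))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(mean_aucs) - 0.5), 0.06)
})

test_that("binary task encoding is exclusive and exhaustive", {
  y <- c("ccRCC", "pRCC", "cRCC")
  expect_equal(build_binary_task(y, "ccRCC"), c(1L, 0L, 0L))
  y2 <- rep(c("ccRCC", "pRCC", "cRCC"), times = c(209, 25, 29))
  b <- build_binary_task(y2, "pRCC")
  expect_equal(sum(b), 25L)
  expect_equal(sum(1 - b), 238L)
  b2 <- build_binary_task(y2, "cRCC")
  expect_true(all(b + b2 <= 1))
  expect_error(build_binary_task(y, "oncocytoma"), "unknown class")
})

test_that("clinical screening applies the right test per variable type", {
  # the reported sex x subtype contingency: chi-squared p = 0.024
  sex <- rep(rep(c("Male", "Female"), 3), c(136, 71, 18, 7, 12, 17))
  subtype <- rep(c("ccRCC", "pRCC", "cRCC"), c(207, 25, 29))
  tab <- data.frame(sex = sex)
  p <- screen_clinical_variables(tab, factor(subtype))
  expect_equal(p$type, "categorical")
  expect_lt(p$p, 0.05)
  expect_lt(abs(p$p - 0.024), 0.002) # printed as 0.024
  expect_true(p$keep)

  # a constant variable cannot discriminate
  tab2 <- data.frame(const = rep(1.5, 261), sex = sex)
  scr <- screen_clinical_variables(tab2, factor(subtype))
  expect_false(scr$keep[scr$variable == "const"])

  # Kruskal-Wallis with ties equals the rank-based computation
  x <- c(1, 2, 2, 3, 5, 5, 5, 7, 9)
  g <- factor(c("a", "a", "b", "b", "b", "c", "c", "c", "a"))
  r <- rank(x)
  n <- length(x)
  H <- (12 / (n * (n + 1))) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  kw <- kruskal.test(x, g)
  expect_equal(unname(kw$statistic), H, tolerance = 1e-12)
  scr3 <- screen_clinical_variables(data.frame(v = x), g)
  expect_equal(scr3$p, kw$p.value)
})

test_that("traditional model recovers a planted clinical covariate", {
  set.seed(91)
  n <- 150
  y <- factor(rep(c("ccRCC", "pRCC", "cRCC"), times = c(100, 25, 25)),
              levels = c("ccRCC", "pRCC", "cRCC"))
  mu <- c(ccRCC = 105, pRCC = 54, cRCC = 85)
  tab <- data.frame(
    attenuation_CMP = rnorm(n, mu[as.character(y)], 8),
    age = rnorm(n, 52, 12),
    noise = rnorm(n)
  )
  fit <- fit_traditional(tab, y)
  expect_true("attenuation_CMP" %in% fit$variables)
  expect_false("noise" %in% fit$variables)
  # the planted covariate dominates the standardized coefficients
  b <- fit$model$coef[["ccRCC"]][-1]
  expect_equal(names(which.max(abs(b))), "attenuation_CMP")
  # deterministic refit
  fit2 <- fit_traditional(tab, y)
  expect_identical(fit$model$coef, fit2$model$coef)
})

test_that("pure-noise covariates yield majority-class CV accuracy", {
  set.seed(92)
  n <- 120
  y <- factor(rep(c("ccRCC", "pRCC", "cRCC"), times = c(80, 20, 20)),
              levels = c("ccRCC", "pRCC", "cRCC"))
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("z", 1:4)))
  cv <- repeated_stratified_cv(X, y, k = 5L, repeats = 30L, seed = 3L)
  expect_lt(abs(cv$mean_accuracy - 80 / 120), 0.08)
})
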