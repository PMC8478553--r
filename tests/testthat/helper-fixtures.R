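# Shared fixtures, built once per test run and cached in an environment.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small random ROI: 5^3 grid, irregular mask, several gray levels
random_roi_5 <- function(seed = 42, ng_spread = 60) {
  set.seed(seed)
  v <- array(runif(125, 0, ng_spread), c(5, 5, 5))
  m <- array(runif(125) < 0.7, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  discretize(v, m, bin_width = 10)
}

# desk-scale cohort shared across cohort/icc/pipeline tests
mini_cohort <- function() {
  fixture("mini_cohort", function() {
    cfg <- cohort_config(counts = c(ccRCC = 10L, pRCC = 4L, cRCC = 4L),
                         grid = c(24L, 24L, 24L), radius_range = c(5.5, 8),
                         seed = 7L)
    generate_cohort(cfg)
  })
}

mini_features <- function() {
  fixture("mini_features", function() {
    extract_cohort_features(mini_cohort(), rater = 1L)
  })
}

mini_features_r2 <- function() {
  fixture("mini_features_r2", function() {
    extract_cohort_features(mini_cohort(), rater = 2L)
  })
}

# mid-size cohort for the accuracy-ordering acceptance check: signal split
# across phases, 100 cross-validation repeats on the extracted matrices
ordering_cohort_features <- function() {
  fixture("ordering_features", function() {
    cfg <- cohort_config(counts = c(ccRCC = 60L, pRCC = 10L, cRCC = 12L),
                         grid = c(28L, 28L, 28L), radius_range = c(6, 9),
                         seed = 19L)
    coh <- generate_cohort(cfg)
    f <- extract_cohort_features(coh, rater = 1L)
    f
  })
}
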