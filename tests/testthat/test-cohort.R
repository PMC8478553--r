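test_that("cohort generation honours configured counts and structure", {
  coh <- mini_cohort()
  expect_length(coh, 18L)
  subtypes <- vapply(coh, `[[`, character(1), "subtype")
  expect_equal(unname(table(factor(subtypes, c("ccRCC", "pRCC", "cRCC")))),
               array(c(10L, 4L, 4L)), ignore_attr = TRUE)
  s <- coh[[1]]
  expect_named(s$volumes, c("NCP", "CMP", "NP", "EP"))
  expect_length(s$masks, 2L)
  expect_equal(s$masks[[1]]$rater_id, 1L)
  expect_equal(s$masks[[2]]$rater_id, 2L)
  expect_true(all(vapply(s$volumes, function(v) all(is.finite(v$voxels)),
                         logical(1))))
  expect_true(any(s$masks[[1]]$voxels))
})

test_that("single-subject config produces one complete ccRCC subject", {
  cfg <- cohort_config(counts = c(ccRCC = 1L, pRCC = 0L, cRCC = 0L),
                       grid = c(24L, 24L, 24L), radius_range = c(5, 7),
                       seed = 3L)
  coh <- generate_cohort(cfg)
  expect_length(coh, 1L)
  expect_equal(coh[[1]]$subtype, "ccRCC")
  expect_length(coh[[1]]$volumes, 4L)
  expect_length(coh[[1]]$masks, 2L)
})

test_that("degenerate configurations are rejected", {
  expect_error(cohort_config(counts = c(0L, 0L, 0L)), "zero total")
  expect_error(cohort_config(grid = c(0L, 24L, 24L)), "nonpositive grid")
  expect_error(cohort_config(cystic_prob = c(2, .5, .5)), "probabilities")
  cfg <- cohort_config(counts = c(1L, 0L, 0L), grid = c(16L, 16L, 16L),
                       radius_range = c(10, 12))
  expect_error(generate_cohort(cfg), "larger than grid")
})

test_that("identical seeds give bit-identical cohorts, different seeds differ", {
  cfg <- cohort_config(counts = c(ccRCC = 2L, pRCC = 1L, cRCC = 1L),
                       grid = c(20L, 20L, 20L), radius_range = c(4.5, 6),
                       seed = 5L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  cfg$seed <- 6L
  c3 <- generate_cohort(cfg)
  expect_false(identical(c1[[1]]$volumes$CMP$voxels,
                         c3[[1]]$volumes$CMP$voxels))
  # same summary statistics within tolerance across seeds
  m1 <- mean(c1[[1]]$volumes$CMP$voxels[c1[[1]]$ideal_mask])
  m3 <- mean(c3[[1]]$volumes$CMP$voxels[c3[[1]]$ideal_mask])
  expect_lt(abs(m1 - m3), 30)
})

test_that("lesion attenuation matches the configured phase means", {
  # Monte-Carlo check of the generator's own noise model: the mean lesion
  # CMP attenuation over ccRCC subjects concentrates on the configured
  # value. Inclusions are disabled: a hypodense cyst deliberately lowers
  # the measured mean below the configured solid-tissue attenuation.
  cfg <- cohort_config(counts = c(ccRCC = 100L, pRCC = 0L, cRCC = 0L),
                       grid = c(20L, 20L, 20L), radius_range = c(4.5, 6.5),
                       cystic_prob = c(0, 0, 0),
                       calcification_prob = c(0, 0, 0),
                       seed = 41L)
  coh <- generate_cohort(cfg)
  cmp_means <- vapply(coh, function(s) {
    mean(s$volumes$CMP$voxels[s$masks[[1]]$voxels])
  }, numeric(1))
  expect_lt(abs(mean(cmp_means) - 105.31), 3)
  ncp_means <- vapply(coh, function(s) {
    mean(s$volumes$NCP$voxels[s$masks[[1]]$voxels])
  }, numeric(1))
  expect_lt(abs(mean(ncp_means) - 33.89), 3)
})

test_that("zero noise amplitude plants the exact configured mean", {
  cfg <- cohort_config(counts = c(1L, 0L, 0L), grid = c(20L, 20L, 20L),
                       radius_range = c(5, 6), noise_sd = 0, seed = 2L)
  g <- generate_lesion_volume("pRCC", "CMP", cfg, seed = 9L)
  expect_true(all(abs(g$volume$voxels[g$mask] - 53.61) < 1e-9))
})

test_that("mask perturbation is boundary-local, bounded, and seeded", {
  m <- array(FALSE, c(12, 12, 12)); m[2:11, 2:11, 2:11] <- TRUE
  p0 <- perturb_mask(m, 0L, seed = 1L)
  expect_identical(p0$voxels, m)
  expect_equal(p0$rater_id, 2L)
  p1 <- perturb_mask(m, 1L, seed = 1L)
  expect_identical(p1$voxels, perturb_mask(m, 1L, seed = 1L)$voxels)
  # interior (erosion of the original) is untouched
  core <- erode_mask(m, 1L)
  expect_true(all(p1$voxels[core]))
  # volume change bounded by the boundary shell size
  shell <- sum(mask_boundary(m)) + sum(dilate_mask(m, 1L) & !m)
  expect_lte(abs(sum(p1$voxels) - sum(m)), shell)
  expect_error(perturb_mask(m, -1L), "nonnegative")
})

test_that("clinical table reflects per-subtype profiles and recomputed HU", {
  coh <- mini_cohort()
  tab <- generate_clinical_table(coh)
  expect_equal(nrow(tab), length(coh))
  expect_true(all(tab$sex %in% c("Male", "Female")))
  expect_true(all(tab$growth %in% c("inside", "middle", "outside")))
  # attenuation columns equal direct mask-mean recomputation
  recomputed <- vapply(coh, function(s) {
    mean(s$volumes$NP$voxels[s$masks[[1]]$voxels])
  }, numeric(1))
  expect_equal(tab$attenuation_NP, recomputed, tolerance = 1e-12)
  expect_error(generate_clinical_table(list()), "empty")
})

test_that("large ccRCC cohorts reproduce the configured male fraction", {
  cfg <- cohort_config(counts = c(ccRCC = 300L, pRCC = 0L, cRCC = 0L),
                       grid = c(12L, 12L, 12L), radius_range = c(2.5, 3.5),
                       seed = 17L)
  tab <- generate_clinical_table(generate_cohort(cfg))
  male_frac <- mean(tab$sex == "Male")
  expect_lt(abs(male_frac - 136 / 207), 0.08)
})

test_that("planted CMP contrast separates ccRCC from pRCC at small n", {
  cfg <- cohort_config(counts = c(ccRCC = 50L, pRCC = 10L, cRCC = 10L),
                       grid = c(16L, 16L, 16L), radius_range = c(3.5, 5),
                       seed = 29L)
  coh <- generate_cohort(cfg)
  tab <- generate_clinical_table(coh)
  cc <- tab$attenuation_CMP[tab$subtype == "ccRCC"]
  pp <- tab$attenuation_CMP[tab$subtype == "pRCC"]
  expect_lt(wilcox.test(cc, pp)$p.value, 0.01)
})

test_that("cohort export writes volumes, masks, table, and manifest", {
  coh <- mini_cohort()[1:2]
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "S001_CMP.nii.gz")))
  expect_true(file.exists(file.path(dir, "S001_mask_r1.nii.gz")))
  back <- RNifti::readNifti(file.path(dir, "S001_CMP.nii.gz"))
  expect_equal(as.array(back), coh[[1]]$volumes$CMP$voxels,
               ignore_attr = TRUE, tolerance = 1e-6)
  man2 <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man2$S001$subtype, "ccRCC")
})
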