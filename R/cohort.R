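#' Default per-subtype, per-phase median lesion attenuation (HU)
#'
#' Median attenuation of the lesion in each contrast phase for the three RCC
#' subtypes, used as the generator's default lesion means. Rows are phases
#' (NCP, CMP, NP, EP), columns subtypes (ccRCC, pRCC, cRCC).
#'
#' @return 4x4 numeric matrix (phases x subtypes).
#' @export
default_phase_means <- function() {
  m <- rbind(
    NCP = c(33.89, 35.35, 26.61),
    CMP = c(105.31, 53.61, 85.21),
    NP  = c(86.98, 61.90, 77.81),
    EP  = c(69.93, 60.71, 65.95)
  )
  colnames(m) <- RCC_CLASSES
  m
}

#' Configuration for the synthetic multiphase-CT cohort generator
#'
#' Defines the statistical structure of the generated cohort: subtype counts
#' with the unbalanced ccRCC:pRCC:cRCC frequencies of a consecutive clinical
#' series, per-subtype per-phase lesion attenuation, subtype-specific texture
#' correlation length (which plants a texture signal recoverable by the
#' radiomic stages), inclusion probabilities for cystic and calcified
#' components, and the magnitude of the simulated second reader's contour
#' perturbation.
#'
#' @param counts Named integer vector of subjects per subtype
#'   (ccRCC, pRCC, cRCC).
#' @param grid Integer length-3 volume dimensions (voxels).
#' @param spacing Numeric length-3 voxel size in mm.
#' @param phase_means 4x4 matrix of lesion mean HU, phases x subtypes.
#' @param subject_sd Between-subject SD of the per-phase lesion mean (HU).
#' @param texture_jitter SD of the per-subject log-normal multiplier on the
#'   texture correlation length (within-subtype texture heterogeneity).
#' @param noise_sd Within-lesion texture field amplitude (HU).
#' @param texture_sigma Named per-subtype Gaussian correlation length of the
#'   lesion texture field, in voxels.
#' @param background_hu,background_sd Mean and texture amplitude of the
#'   surrounding tissue plateau.
#' @param radius_range Per-axis lesion semi-axis range in voxels.
#' @param margin_mm Contour retraction from the true lesion margin applied to
#'   exported rater masks (mm); emulates drawing the ROI inside the tumour
#'   boundary to avoid perinephric fat and normal parenchyma.
#' @param cystic_prob,calcification_prob Named per-subtype probabilities of a
#'   hypodense cystic / hyperdense calcified inclusion.
#' @param rater_magnitude Boundary perturbation (voxels) for the simulated
#'   second rater.
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(counts = c(ccRCC = 209L, pRCC = 25L, cRCC = 29L),
                          grid = c(64L, 64L, 64L),
                          spacing = c(1, 1, 1),
                          phase_means = default_phase_means(),
                          subject_sd = 8,
                          texture_jitter = 0.25,
                          noise_sd = 12,
                          texture_sigma = c(ccRCC = 2.0, pRCC = 1.1, cRCC = 1.5),
                          background_hu = 15,
                          background_sd = 5,
                          radius_range = c(9, 14),
                          margin_mm = 2,
                          cystic_prob = c(ccRCC = 161 / 207, pRCC = 11 / 25,
                                          cRCC = 9 / 29),
                          calcification_prob = c(ccRCC = 42 / 204, pRCC = 4 / 25,
                                                 cRCC = 2 / 29),
                          rater_magnitude = 1L,
                          seed = 1L) {
  counts <- as.integer(counts)
  names(counts) <- RCC_CLASSES
  if (any(counts < 0)) stop("subtype counts must be nonnegative")
  if (sum(counts) < 1L) stop("configuration error: zero total subjects")
  if (any(grid <= 0)) stop("configuration error: nonpositive grid dimensions")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (any(cystic_prob < 0 | cystic_prob > 1) ||
      any(calcification_prob < 0 | calcification_prob > 1)) {
    stop("inclusion probabilities must lie in [0, 1]")
  }
  names(cystic_prob) <- RCC_CLASSES
  names(calcification_prob) <- RCC_CLASSES
  names(texture_sigma) <- RCC_CLASSES
  structure(list(
    counts = counts, grid = as.integer(grid), spacing = as.numeric(spacing),
    phase_means = phase_means, subject_sd = subject_sd,
    texture_jitter = texture_jitter, noise_sd = noise_sd,
    texture_sigma = texture_sigma, background_hu = background_hu,
    background_sd = background_sd, radius_range = radius_range,
    margin_mm = margin_mm, cystic_prob = cystic_prob,
    calcification_prob = calcification_prob,
    rater_magnitude = as.integer(rater_magnitude), seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate one lesion-bearing phase volume
#'
#' Builds a 3D attenuation volume containing an ellipsoidal lesion whose mean
#' HU is the configured per-subtype per-phase value plus spatially correlated
#' Gaussian noise. The correlation length of the noise field depends on the
#' subtype, so texture features carry subtype information beyond first-order
#' attenuation. Background tissue sits on a distinct HU plateau.
#'
#' @param subtype One of ccRCC, pRCC, cRCC.
#' @param phase One of NCP, CMP, NP, EP.
#' @param cfg A [cohort_config()].
#' @param seed Integer seed.
#' @param geometry Optional precomputed lesion geometry (see
#'   [lesion_geometry()]); drawn from `seed` when `NULL`.
#' @param mean_shift Additive subject-level offset of the lesion mean (HU).
#' @return List with elements `volume` (a `phase_volume`: voxels, spacing,
#'   phase) and `mask` (logical array, the ideal full-extent lesion mask).
#' @export
generate_lesion_volume <- function(subtype, phase, cfg = cohort_config(),
                                   seed = 1L, geometry = NULL,
                                   mean_shift = 0) {
  subtype <- match.arg(subtype, RCC_CLASSES)
  phase <- match.arg(phase, CT_PHASES)
  set.seed(seed)
  d <- cfg$grid
  if (is.null(geometry)) geometry <- lesion_geometry(cfg)
  if (any(2 * geometry$radii + 2 >= d)) {
    stop("configuration error: lesion larger than grid")
  }
  mask <- ellipsoid_mask(d, geometry$center, geometry$radii)

  mu <- cfg$phase_means[phase, subtype] + mean_shift
  sigma_mult <- if (is.null(geometry$sigma_mult)) 1 else geometry$sigma_mult
  sigma_t <- cfg$texture_sigma[[subtype]] * sigma_mult

  field <- array(rnorm(prod(d)), dim = d)
  field <- gaussian_smooth_3d(field, sigma_t)
  fsd <- sd(field[mask])
  if (is.na(fsd) || fsd == 0) fsd <- 1
  lesion_noise <- field / fsd * cfg$noise_sd

  bg <- array(rnorm(prod(d)), dim = d)
  bg <- gaussian_smooth_3d(bg, 1)
  bsd <- sd(bg)
  if (bsd == 0) bsd <- 1
  vox <- cfg$background_hu + bg / bsd * cfg$background_sd
  vox[mask] <- mu + lesion_noise[mask]
  # recentre lesion voxels exactly on mu so the configured mean is the
  # lesion-voxel mean up to rater-mask cropping
  vox[mask] <- vox[mask] - mean(vox[mask]) + mu

  # optional inclusions
  if (isTRUE(geometry$cystic)) {
    inc <- ellipsoid_mask(d, geometry$cyst_center, geometry$cyst_radii) & mask
    vox[inc] <- vox[inc] - 45
  }
  if (isTRUE(geometry$calcified)) {
    inc <- ellipsoid_mask(d, geometry$calc_center, geometry$calc_radii) & mask
    vox[inc] <- vox[inc] + 150
  }

  volume <- structure(list(voxels = vox, spacing = cfg$spacing, phase = phase),
                      class = "phase_volume")
  list(volume = volume, mask = mask)
}

#' Draw the per-subject lesion geometry
#'
#' Consumes the current RNG stream. Semi-axes are uniform within
#' `cfg$radius_range`; the lesion is centred near the grid centre; cyst and
#' calcification sites fall inside the lesion core.
#'
#' @param cfg A [cohort_config()].
#' @param subtype Optional subtype used for the inclusion probabilities;
#'   when `NULL` no inclusions are drawn.
#' @return List of geometry parameters.
#' @export
lesion_geometry <- function(cfg, subtype = NULL) {
  d <- cfg$grid
  radii <- runif(3, cfg$radius_range[1], cfg$radius_range[2])
  center <- d / 2 + runif(3, -2, 2)
  geom <- list(radii = radii, center = center,
               cystic = FALSE, calcified = FALSE)
  if (!is.null(subtype)) {
    jit <- if (is.null(cfg$texture_jitter)) 0 else cfg$texture_jitter
    geom$sigma_mult <- exp(rnorm(1, 0, jit))
    geom$cystic <- runif(1) < cfg$cystic_prob[[subtype]]
    geom$calcified <- runif(1) < cfg$calcification_prob[[subtype]]
    # always draw the inclusion geometry so the RNG stream length does not
    # depend on the Bernoulli outcomes
    off <- runif(3, -0.3, 0.3) * radii
    geom$cyst_center <- center + off
    geom$cyst_radii <- pmax(1.5, radii * runif(1, 0.2, 0.35))
    off2 <- runif(3, -0.4, 0.4) * radii
    geom$calc_center <- center + off2
    geom$calc_radii <- pmax(1, radii * runif(1, 0.08, 0.15))
  }
  geom
}

ellipsoid_mask <- function(d, center, radii) {
  z <- (seq_len(d[1]) - center[1]) / radii[1]
  y <- (seq_len(d[2]) - center[2]) / radii[2]
  x <- (seq_len(d[3]) - center[3]) / radii[3]
  q <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  q <= 1
}

#' Perturb a rater mask at its boundary
#'
#' Simulates a second reader's independent contour by randomly dilating or
#' eroding boundary voxels. Each pass flips a random subset of current
#' boundary voxels (outward additions and inward removals), so the total
#' displacement anywhere is at most `magnitude` voxels and the mask interior
#' is untouched.
#'
#' @param mask A `rater_mask` (list with `voxels`, `rater_id`) or a binary
#'   array.
#' @param magnitude Maximum boundary displacement in voxels; 0 returns the
#'   input mask unchanged (rater id still set to 2).
#' @param seed Integer seed.
#' @return A `rater_mask` with `rater_id = 2`.
#' @export
perturb_mask <- function(mask, magnitude = 1L, seed = 1L) {
  if (magnitude < 0) stop("magnitude must be nonnegative")
  vox <- if (is.list(mask)) mask$voxels else mask
  m <- vox > 0
  if (!any(m)) stop("mask is empty")
  set.seed(seed)
  if (magnitude >= 1) {
    for (it in seq_len(magnitude)) {
      inner_b <- which(mask_boundary(m))
      outer_b <- which(dilate_mask(m, 1L) & !m)
      add <- outer_b[runif(length(outer_b)) < 0.25]
      rem <- inner_b[runif(length(inner_b)) < 0.25]
      m[add] <- TRUE
      m[rem] <- FALSE
      if (!any(m)) { # never empty the mask entirely
        m[inner_b[1]] <- TRUE
      }
    }
  }
  structure(list(voxels = m, rater_id = 2L), class = "rater_mask")
}

#' Generate a seeded synthetic multiphase-CT cohort
#'
#' Produces `sum(cfg$counts)` subjects, each with four phase volumes sharing
#' one lesion geometry, two rater masks (the exported mask is the ideal
#' lesion eroded by the configured margin; the corticomedullary-phase
#' contours are reused for the noncontrast phase), and a clinical record.
#' Identical configuration and seed give a bit-identical cohort.
#'
#' @param cfg A [cohort_config()].
#' @return List of `subject` objects, each with `id`, `subtype`, `volumes`
#'   (named list over phases), `masks` (rater 1 and 2), and `clinical`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  n_total <- sum(cfg$counts)
  subtypes <- rep(RCC_CLASSES, times = cfg$counts)
  margin_vox <- round(cfg$margin_mm / min(cfg$spacing))

  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    st <- subtypes[i]
    sseed <- derive_seed(cfg$seed, i)
    set.seed(sseed)
    geom <- lesion_geometry(cfg, st)
    shifts <- rnorm(4, 0, cfg$subject_sd)
    names(shifts) <- CT_PHASES
    clinical_draws <- draw_clinical_categoricals(st)

    volumes <- list()
    ideal_mask <- NULL
    for (p in CT_PHASES) {
      g <- generate_lesion_volume(st, p, cfg,
                                  seed = derive_seed(sseed, match(p, CT_PHASES)),
                                  geometry = geom, mean_shift = shifts[[p]])
      volumes[[p]] <- g$volume
      ideal_mask <- g$mask
    }
    m1 <- if (margin_vox >= 1) erode_mask(ideal_mask, margin_vox) else ideal_mask
    if (!any(m1)) m1 <- ideal_mask # tiny lesion: fall back to full extent
    mask1 <- structure(list(voxels = m1, rater_id = 1L), class = "rater_mask")
    mask2 <- perturb_mask(mask1, cfg$rater_magnitude,
                          seed = derive_seed(sseed, 77L))

    clinical <- build_clinical_record(st, geom, volumes, mask1, cfg,
                                      clinical_draws)
    subjects[[i]] <- structure(list(
      id = sprintf("S%03d", i), subtype = st, volumes = volumes,
      masks = list(mask1, mask2), ideal_mask = ideal_mask,
      clinical = clinical
    ), class = "subject")
  }
  subjects
}

# Table-level per-subtype probabilities of the categorical clinical fields
clinical_probs <- function() {
  list(
    sex = rbind(ccRCC = c(Male = 136, Female = 71),
                pRCC = c(18, 7), cRCC = c(12, 17)),
    side = rbind(ccRCC = c(Right = 114, Left = 93),
                 pRCC = c(10, 15), cRCC = c(13, 16)),
    symptoms = rbind(ccRCC = c(No = 91, Yes = 116),
                     pRCC = c(10, 15), cRCC = c(17, 12)),
    growth = rbind(ccRCC = c(outside = 70, middle = 90, inside = 47),
                   pRCC = c(7, 10, 8), cRCC = c(10, 13, 6)),
    t_stage = rbind(ccRCC = c(T1 = 144, T2 = 25, T3 = 17, T4 = 21),
                    pRCC = c(15, 5, 2, 3), cRCC = c(21, 6, 1, 1)),
    n_stage = rbind(ccRCC = c(N0 = 186, N1 = 22),
                    pRCC = c(19, 6), cRCC = c(28, 1)),
    m_stage = rbind(ccRCC = c(M0 = 194, M1 = 13),
                    pRCC = c(23, 2), cRCC = c(27, 2)),
    tnm = rbind(ccRCC = c(I = 130, II = 26, III = 13, IV = 28),
                pRCC = c(13, 2, 6, 4), cRCC = c(20, 6, 2, 1))
  )
}

draw_clinical_categoricals <- function(subtype) {
  probs <- clinical_probs()
  draws <- list()
  for (v in names(probs)) {
    tab <- probs[[v]]
    p <- tab[subtype, ] / sum(tab[subtype, ])
    draws[[v]] <- sample(colnames(tab), 1, prob = p)
  }
  draws$age <- round(rnorm(1, 52.5, 12))
  draws
}

build_clinical_record <- function(subtype, geom, volumes, mask1, cfg, draws) {
  att <- vapply(CT_PHASES, function(p) {
    mean(volumes[[p]]$voxels[mask1$voxels])
  }, numeric(1))
  rec <- list(
    sex = draws$sex, age = draws$age, side = draws$side,
    diameter = 2 * max(geom$radii) * max(cfg$spacing),
    symptoms = draws$symptoms, growth = draws$growth,
    cystic = if (isTRUE(geom$cystic)) "Yes" else "No",
    calcification = if (isTRUE(geom$calcified)) "Yes" else "No",
    t_stage = draws$t_stage, n_stage = draws$n_stage, m_stage = draws$m_stage,
    tnm_stage = draws$tnm,
    attenuation_NCP = att[["NCP"]], attenuation_CMP = att[["CMP"]],
    attenuation_NP = att[["NP"]], attenuation_EP = att[["EP"]]
  )
  rec
}

#' Assemble the cohort's clinical covariate table
#'
#' One row per subject. Categorical fields follow the per-subtype frequency
#' profile of the emulated series; lesion attenuations are recomputed from
#' the subject's own volumes as the mean HU inside the rater-1 mask.
#'
#' @param cohort List of subjects from [generate_cohort()].
#' @return `data.frame` with subject id, subtype, and all clinical fields.
#' @export
generate_clinical_table <- function(cohort) {
  if (length(cohort) == 0) stop("cohort is empty")
  rows <- lapply(cohort, function(s) {
    data.frame(id = s$id, subtype = s$subtype,
               as.data.frame(s$clinical, stringsAsFactors = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a cohort to disk
#'
#' Volumes and masks are written as NIfTI, the clinical table as CSV, and a
#' manifest (subject id, subtype, file paths) as JSON.
#'
#' @param cohort List of subjects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (s in cohort) {
    entry <- list(subtype = s$subtype, volumes = list(), masks = list())
    for (p in CT_PHASES) {
      f <- file.path(dir, sprintf("%s_%s.nii.gz", s$id, p))
      RNifti::writeNifti(
        RNifti::asNifti(s$volumes[[p]]$voxels,
                        pixdim = s$volumes[[p]]$spacing), f)
      entry$volumes[[p]] <- basename(f)
    }
    for (r in 1:2) {
      f <- file.path(dir, sprintf("%s_mask_r%d.nii.gz", s$id, r))
      RNifti::writeNifti(
        RNifti::asNifti(array(as.integer(s$masks[[r]]$voxels),
                              dim = dim(s$masks[[r]]$voxels))), f)
      entry$masks[[as.character(r)]] <- basename(f)
    }
    manifest[[s$id]] <- entry
  }
  tab <- generate_clinical_table(cohort)
  write.csv(tab, file.path(dir, "clinical.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
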