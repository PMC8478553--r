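#' Extraction settings
#'
#' @param bin_width Discretization bin width in HU.
#' @param glcm_distance GLCM/GLRLM neighbour distance in voxels.
#' @return List of settings.
#' @export
extraction_config <- function(bin_width = 25, glcm_distance = 1L) {
  list(bin_width = bin_width, glcm_distance = as.integer(glcm_distance))
}

#' Extract the 105-feature single-phase radiomic vector
#'
#' 18 first-order + 13 shape + 23 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM +
#' 5 NGTDM features of the masked lesion.
#'
#' @param volume A `phase_volume` (or 3D array).
#' @param mask A `rater_mask` (or binary array) on the same grid.
#' @param cfg An [extraction_config()].
#' @return Named numeric vector of exactly 105 finite values, with a
#'   `phase` attribute when the volume carries one.
#' @export
extract_single_phase <- function(volume, mask, cfg = extraction_config()) {
  roi <- discretize(volume, mask, cfg$bin_width)
  out <- c(
    first_order_features(roi),
    shape_features(mask, roi$spacing),
    glcm_features(roi, cfg$glcm_distance),
    glrlm_features(roi),
    glszm_features(roi),
    gldm_features(roi),
    ngtdm_features(roi)
  )
  attributes(out) <- list(names = names(out))
  if (is.list(volume) && !is.null(volume$phase)) attr(out, "phase") <- volume$phase
  stopifnot(length(out) == 105L, all(is.finite(out)))
  out
}

#' Concatenate four single-phase vectors into the 420-feature ALL-P vector
#'
#' Names are prefixed by phase; output order is canonical (NCP, CMP, NP, EP)
#' regardless of input order.
#'
#' @param vectors Named list (or list with `phase` attributes) of exactly
#'   four 105-feature vectors, one per phase.
#' @return Named numeric vector of 420 features.
#' @export
combine_phases <- function(vectors) {
  if (is.null(names(vectors)) || any(!nzchar(names(vectors)))) {
    names(vectors) <- vapply(vectors, function(v) {
      p <- attr(v, "phase")
      if (is.null(p)) "" else p
    }, character(1))
  }
  if (!setequal(names(vectors), CT_PHASES) || length(vectors) != 4L) {
    stop("need exactly one feature vector per phase (NCP, CMP, NP, EP)")
  }
  out <- unlist(lapply(CT_PHASES, function(p) {
    v <- vectors[[p]]
    names(v) <- paste0(p, "_", names(v))
    v
  }))
  stopifnot(length(out) == 420L, !anyDuplicated(names(out)))
  out
}

#' Extract per-phase and ALL-P feature matrices for a cohort
#'
#' @param cohort List of subjects from [generate_cohort()].
#' @param rater Which rater's mask to use (1 or 2).
#' @param cfg An [extraction_config()].
#' @param phases Phases to extract.
#' @return List of feature matrices (subjects x features) named by phase,
#'   plus `ALLP` (420 columns) when all four phases are extracted, and the
#'   label vector `subtype`.
#' @export
extract_cohort_features <- function(cohort, rater = 1L,
                                    cfg = extraction_config(),
                                    phases = CT_PHASES) {
  vecs <- lapply(cohort, function(s) {
    mask <- s$masks[[rater]]
    per_phase <- lapply(phases, function(p) {
      extract_single_phase(s$volumes[[p]], mask, cfg)
    })
    names(per_phase) <- phases
    per_phase
  })
  out <- list()
  for (p in phases) {
    m <- do.call(rbind, lapply(vecs, `[[`, p))
    rownames(m) <- vapply(cohort, `[[`, character(1), "id")
    colnames(m) <- paste0(p, "_", colnames(m))
    out[[p]] <- m
  }
  if (setequal(phases, CT_PHASES)) {
    out$ALLP <- do.call(rbind, lapply(vecs, combine_phases))
    rownames(out$ALLP) <- rownames(out[[phases[1]]])
  }
  out$subtype <- factor(vapply(cohort, `[[`, character(1), "subtype"),
                        levels = RCC_CLASSES)
  out
}
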