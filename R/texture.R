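# 3D texture-matrix features over the discretized ROI.
#
# Conventions: GLCM and GLRLM use the 13 unique direction pairs of the
# 26-neighbourhood at distance 1, with symmetric accumulation (GLCM) and
# direction-wise feature averaging; GLSZM zones, GLDM dependences and NGTDM
# neighbourhoods use full 26-connectivity. Degenerate single-level ROIs give
# limit values (entropy 0, correlation 1, NGTDM contrast 0), never NaN.

#' The 13 unique 3D direction offsets (z, y, x)
#'
#' Half of the 26-neighbourhood, one representative per +/- pair.
#' @return 13x3 integer matrix.
#' @export
direction_offsets_13 <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- g[, "dx"] > 0 |
    (g[, "dx"] == 0 & g[, "dy"] > 0) |
    (g[, "dx"] == 0 & g[, "dy"] == 0 & g[, "dz"] > 0)
  unname(g[keep, , drop = FALSE])
}

offsets_26 <- function() {
  o <- direction_offsets_13()
  rbind(o, -o)
}

# neighbour level lookup: out[p] = lev[p + off], NA beyond the grid
shift_levels <- function(lev, off) {
  d <- dim(lev)
  out <- array(NA_integer_, d)
  zi <- seq_len(d[1]) + off[1]
  yi <- seq_len(d[2]) + off[2]
  xi <- seq_len(d[3]) + off[3]
  okz <- zi >= 1 & zi <= d[1]; oky <- yi >= 1 & yi <= d[2]
  okx <- xi >= 1 & xi <= d[3]
  out[which(okz), which(oky), which(okx)] <-
    lev[zi[okz], yi[oky], xi[okx]]
  out
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Symmetric, normalized co-occurrence of level pairs at the given offset
#' (distance in voxels times the unit direction).
#'
#' @param roi A `discretized_roi`.
#' @param off Integer length-3 offset (z, y, x).
#' @return Ng x Ng matrix summing to 1, or NULL if the direction has no
#'   voxel pairs.
#' @export
glcm_matrix <- function(roi, off) {
  lev <- roi$levels
  nb <- shift_levels(lev, off)
  ok <- !is.na(lev) & !is.na(nb)
  if (!any(ok)) return(NULL)
  a <- lev[ok]; b <- nb[ok]
  Ng <- roi$Ng
  C <- matrix(tabulate((a - 1L) * Ng + b, nbins = Ng * Ng), Ng, Ng, byrow = TRUE)
  P <- C + t(C)
  P / sum(P)
}

glcm_features_single <- function(p) {
  Ng <- nrow(p)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  gi <- seq_len(Ng)
  mux <- sum(gi * px); muy <- sum(gi * py)
  sx <- sqrt(sum((gi - mux)^2 * px)); sy <- sqrt(sum((gi - muy)^2 * py))
  # sum and difference distributions
  k_diff <- 0:(Ng - 1)
  pdiff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * Ng)
  psum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  HX <- ent(px); HY <- ent(py); HXY <- ent(p)
  pxy <- outer(px, py)
  okm <- p > 0 & pxy > 0
  HXY1 <- -sum(p[okm] * log2(pxy[okm]))
  HXY2 <- ent(pxy)
  da <- sum(k_diff * pdiff)
  corr <- if (sx * sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 1
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  # maximal correlation coefficient via the transition matrix Q
  mcc <- {
    nz <- which(px > 0)
    if (length(nz) < 2) 1 else {
      psub <- p[nz, nz, drop = FALSE]
      pxs <- px[nz]; pys <- py[nz]
      Q <- (psub / pxs) %*% t(psub / matrix(pys, nrow(psub), ncol(psub),
                                            byrow = TRUE))
      evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, evq[2]))
    }
  }
  inv_var <- { off_diag <- i != j
    if (any(off_diag)) sum(p[off_diag] / (i - j)[off_diag]^2) else 0 }
  c(
    glcm_Autocorrelation = sum(i * j * p),
    glcm_JointAverage = mux,
    glcm_ClusterProminence = sum((i + j - mux - muy)^4 * p),
    glcm_ClusterShade = sum((i + j - mux - muy)^3 * p),
    glcm_ClusterTendency = sum((i + j - mux - muy)^2 * p),
    glcm_Contrast = sum((i - j)^2 * p),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = ent(pdiff),
    glcm_DifferenceVariance = sum((k_diff - da)^2 * pdiff),
    glcm_JointEnergy = sum(p^2),
    glcm_JointEntropy = HXY,
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_Idm = sum(p / (1 + (i - j)^2)),
    glcm_MCC = mcc,
    glcm_Idmn = sum(p / (1 + (i - j)^2 / Ng^2)),
    glcm_Id = sum(p / (1 + abs(i - j))),
    glcm_Idn = sum(p / (1 + abs(i - j) / Ng)),
    glcm_InverseVariance = inv_var,
    glcm_MaximumProbability = max(p),
    glcm_SumEntropy = ent(psum),
    glcm_SumSquares = sum((i - mux)^2 * p)
  )
}

#' GLCM features (23), averaged over the 13 directions
#'
#' @param roi A `discretized_roi`.
#' @param distance Neighbour distance in voxels (default 1).
#' @return Named numeric vector of 23 features.
#' @export
glcm_features <- function(roi, distance = 1L) {
  offs <- direction_offsets_13() * distance
  mats <- lapply(seq_len(nrow(offs)), function(r) glcm_matrix(roi, offs[r, ]))
  mats <- Filter(Negate(is.null), mats)
  if (!length(mats)) mats <- list(matrix(1, 1, 1)) # isolated single voxel
  fl <- lapply(mats, glcm_features_single)
  Reduce(`+`, fl) / length(fl)
}

#' Gray-level run-length matrix for one direction
#'
#' @param roi A `discretized_roi`.
#' @param off Integer length-3 unit direction (z, y, x).
#' @return Ng x Lmax matrix of run counts.
#' @export
glrlm_matrix <- function(roi, off) {
  lev <- roi$levels
  idx <- which(!is.na(lev), arr.ind = TRUE)
  levs <- lev[!is.na(lev)]
  ax <- which(off != 0)[1]
  t_par <- idx[, ax] * off[ax]
  # line key: starting point of the line through each voxel
  key <- idx - t_par %*% t(off)
  d <- dim(lev)
  M <- max(d) + 3
  keyh <- (key[, 1] + M) + (key[, 2] + M) * (3 * M) + (key[, 3] + M) * (9 * M^2)
  ord <- order(keyh, t_par)
  kh <- keyh[ord]; tp <- t_par[ord]; lv <- levs[ord]
  n <- length(kh)
  new_run <- c(TRUE, kh[-1] != kh[-n] | tp[-1] != tp[-n] + 1L |
                 lv[-1] != lv[-n])
  run_id <- cumsum(new_run)
  run_len <- tabulate(run_id)
  run_lev <- lv[new_run]
  Ng <- roi$Ng
  Lmax <- max(run_len)
  matrix(tabulate((run_lev - 1L) * Lmax + run_len, nbins = Ng * Lmax),
         Ng, Lmax, byrow = TRUE)
}

glrlm_features_single <- function(R, Np) {
  Nr <- sum(R)
  g <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  l <- t(matrix(seq_len(ncol(R)), ncol(R), nrow(R)))
  p <- R / Nr
  mug <- sum(g * p); mul <- sum(l * p)
  pe <- p[p > 0]
  c(
    glrlm_ShortRunEmphasis = sum(R / l^2) / Nr,
    glrlm_LongRunEmphasis = sum(R * l^2) / Nr,
    glrlm_GrayLevelNonUniformity = sum(rowSums(R)^2) / Nr,
    glrlm_GrayLevelNonUniformityNormalized = sum(rowSums(R)^2) / Nr^2,
    glrlm_RunLengthNonUniformity = sum(colSums(R)^2) / Nr,
    glrlm_RunLengthNonUniformityNormalized = sum(colSums(R)^2) / Nr^2,
    glrlm_RunPercentage = Nr / Np,
    glrlm_GrayLevelVariance = sum((g - mug)^2 * p),
    glrlm_RunVariance = sum((l - mul)^2 * p),
    glrlm_RunEntropy = -sum(pe * log2(pe)),
    glrlm_LowGrayLevelRunEmphasis = sum(R / g^2) / Nr,
    glrlm_HighGrayLevelRunEmphasis = sum(R * g^2) / Nr,
    glrlm_ShortRunLowGrayLevelEmphasis = sum(R / (g^2 * l^2)) / Nr,
    glrlm_ShortRunHighGrayLevelEmphasis = sum(R * g^2 / l^2) / Nr,
    glrlm_LongRunLowGrayLevelEmphasis = sum(R * l^2 / g^2) / Nr,
    glrlm_LongRunHighGrayLevelEmphasis = sum(R * g^2 * l^2) / Nr
  )
}

#' GLRLM features (16), averaged over the 13 directions
#'
#' @param roi A `discretized_roi`.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(roi) {
  Np <- length(roi$values)
  offs <- direction_offsets_13()
  fl <- lapply(seq_len(nrow(offs)), function(r) {
    glrlm_features_single(glrlm_matrix(roi, offs[r, ]), Np)
  })
  Reduce(`+`, fl) / length(fl)
}

#' Gray-level size-zone matrix (26-connected zones)
#'
#' @param roi A `discretized_roi`.
#' @return Ng x Smax matrix of zone counts.
#' @export
glszm_matrix <- function(roi) {
  zones <- roi_zones(roi)
  Ng <- roi$Ng
  Smax <- max(zones$size)
  matrix(tabulate((zones$level - 1L) * Smax + zones$size, nbins = Ng * Smax),
         Ng, Smax, byrow = TRUE)
}

# connected components of equal-level voxels under 26-connectivity
roi_zones <- function(roi) {
  lev <- roi$levels
  mask_idx <- which(!is.na(lev))
  nvox <- length(mask_idx)
  pos <- integer(length(lev))
  pos[mask_idx] <- seq_len(nvox)
  lv <- lev[mask_idx]
  edges <- NULL
  for (r in seq_len(13)) {
    off <- direction_offsets_13()[r, ]
    nb <- shift_levels(lev, off)
    same <- which(!is.na(lev) & !is.na(nb) & lev == nb)
    if (!length(same)) next
    d <- dim(lev)
    nb_lin <- same + off[1] + off[2] * d[1] + off[3] * d[1] * d[2]
    edges <- rbind(edges, cbind(pos[same], pos[nb_lin]))
  }
  if (is.null(edges)) {
    memb <- seq_len(nvox)
  } else {
    gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, nvox - igraph::vcount(gr)))
    memb <- igraph::components(gr)$membership
  }
  size <- as.integer(table(memb))
  level <- vapply(split(lv, memb), function(x) x[1], integer(1))
  list(level = as.integer(level), size = size)
}

#' GLSZM features (16)
#'
#' @param roi A `discretized_roi`.
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(roi) {
  Z <- glszm_matrix(roi)
  Np <- length(roi$values)
  Nz <- sum(Z)
  g <- matrix(seq_len(nrow(Z)), nrow(Z), ncol(Z))
  s <- t(matrix(seq_len(ncol(Z)), ncol(Z), nrow(Z)))
  p <- Z / Nz
  mug <- sum(g * p); mus <- sum(s * p)
  pe <- p[p > 0]
  c(
    glszm_SmallAreaEmphasis = sum(Z / s^2) / Nz,
    glszm_LargeAreaEmphasis = sum(Z * s^2) / Nz,
    glszm_GrayLevelNonUniformity = sum(rowSums(Z)^2) / Nz,
    glszm_GrayLevelNonUniformityNormalized = sum(rowSums(Z)^2) / Nz^2,
    glszm_SizeZoneNonUniformity = sum(colSums(Z)^2) / Nz,
    glszm_SizeZoneNonUniformityNormalized = sum(colSums(Z)^2) / Nz^2,
    glszm_ZonePercentage = Nz / Np,
    glszm_GrayLevelVariance = sum((g - mug)^2 * p),
    glszm_ZoneVariance = sum((s - mus)^2 * p),
    glszm_ZoneEntropy = -sum(pe * log2(pe)),
    glszm_LowGrayLevelZoneEmphasis = sum(Z / g^2) / Nz,
    glszm_HighGrayLevelZoneEmphasis = sum(Z * g^2) / Nz,
    glszm_SmallAreaLowGrayLevelEmphasis = sum(Z / (g^2 * s^2)) / Nz,
    glszm_SmallAreaHighGrayLevelEmphasis = sum(Z * g^2 / s^2) / Nz,
    glszm_LargeAreaLowGrayLevelEmphasis = sum(Z * s^2 / g^2) / Nz,
    glszm_LargeAreaHighGrayLevelEmphasis = sum(Z * g^2 * s^2) / Nz
  )
}

#' Gray-level dependence matrix (alpha = 0, 26-neighbourhood)
#'
#' Dependence of a voxel = number of in-mask 26-neighbours with the same
#' gray level; matrix column j = dependence + 1.
#'
#' @param roi A `discretized_roi`.
#' @return Ng x (max dependence + 1) matrix of counts.
#' @export
gldm_matrix <- function(roi) {
  lev <- roi$levels
  dep <- array(0L, dim(lev))
  for (r in seq_len(nrow(offsets_26()))) {
    off <- offsets_26()[r, ]
    nb <- shift_levels(lev, off)
    dep <- dep + (!is.na(nb) & !is.na(lev) & nb == lev)
  }
  ok <- !is.na(lev)
  g <- lev[ok]; j <- dep[ok] + 1L
  Ng <- roi$Ng
  Jmax <- max(j)
  matrix(tabulate((g - 1L) * Jmax + j, nbins = Ng * Jmax), Ng, Jmax,
         byrow = TRUE)
}

#' GLDM features (14)
#'
#' @param roi A `discretized_roi`.
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(roi) {
  D <- gldm_matrix(roi)
  Nd <- sum(D)
  g <- matrix(seq_len(nrow(D)), nrow(D), ncol(D))
  j <- t(matrix(seq_len(ncol(D)), ncol(D), nrow(D)))
  p <- D / Nd
  mug <- sum(g * p); muj <- sum(j * p)
  pe <- p[p > 0]
  c(
    gldm_SmallDependenceEmphasis = sum(D / j^2) / Nd,
    gldm_LargeDependenceEmphasis = sum(D * j^2) / Nd,
    gldm_GrayLevelNonUniformity = sum(rowSums(D)^2) / Nd,
    gldm_DependenceNonUniformity = sum(colSums(D)^2) / Nd,
    gldm_DependenceNonUniformityNormalized = sum(colSums(D)^2) / Nd^2,
    gldm_GrayLevelVariance = sum((g - mug)^2 * p),
    gldm_DependenceVariance = sum((j - muj)^2 * p),
    gldm_DependenceEntropy = -sum(pe * log2(pe)),
    gldm_LowGrayLevelEmphasis = sum(D / g^2) / Nd,
    gldm_HighGrayLevelEmphasis = sum(D * g^2) / Nd,
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(D / (g^2 * j^2)) / Nd,
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(D * g^2 / j^2) / Nd,
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(D * j^2 / g^2) / Nd,
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(D * g^2 * j^2) / Nd
  )
}

#' NGTDM per-level table
#'
#' For every masked voxel with at least one in-mask 26-neighbour, the
#' absolute difference between its level and the mean level of those
#' neighbours is accumulated per gray level.
#'
#' @param roi A `discretized_roi`.
#' @return data.frame with columns `level`, `n`, `s`, `p`.
#' @export
ngtdm_table <- function(roi) {
  lev <- roi$levels
  nsum <- array(0, dim(lev))
  ncnt <- array(0L, dim(lev))
  for (r in seq_len(nrow(offsets_26()))) {
    off <- offsets_26()[r, ]
    nb <- shift_levels(lev, off)
    has <- !is.na(nb)
    nsum[has] <- nsum[has] + nb[has]
    ncnt <- ncnt + has
  }
  ok <- !is.na(lev) & ncnt > 0
  g <- lev[ok]
  avg <- nsum[ok] / ncnt[ok]
  adiff <- abs(g - avg)
  Ng <- roi$Ng
  n_i <- tabulate(g, nbins = Ng)
  s_i <- vapply(seq_len(Ng), function(i) sum(adiff[g == i]), numeric(1))
  Nvp <- sum(n_i)
  data.frame(level = seq_len(Ng), n = n_i, s = s_i,
             p = if (Nvp > 0) n_i / Nvp else 0)
}

#' NGTDM features (5)
#'
#' @param roi A `discretized_roi`.
#' @return Named numeric vector: coarseness, contrast, busyness, complexity,
#'   strength.
#' @export
ngtdm_features <- function(roi) {
  tab <- ngtdm_table(roi)
  p <- tab$p; s <- tab$s; iv <- tab$level
  Nvp <- sum(tab$n)
  nz <- p > 0
  Ngp <- sum(nz)
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (Ngp > 1 && Nvp > 0) {
    sum(outer(p[nz], p[nz]) * outer(iv[nz], iv[nz], `-`)^2) /
      (Ngp * (Ngp - 1)) * sum(s) / Nvp
  } else 0
  busy_den <- sum(abs(outer(iv[nz] * p[nz], iv[nz] * p[nz], `-`)))
  busyness <- if (busy_den > 0) coarse_den / busy_den else 0
  complexity <- if (Nvp > 0 && Ngp > 0) {
    ii <- outer(iv[nz], iv[nz], `-`)
    ps <- p[nz] * s[nz]
    num <- outer(ps, ps, `+`)
    den <- outer(p[nz], p[nz], `+`)
    sum(abs(ii) * num / den) / Nvp
  } else 0
  strength <- if (sum(s) > 0) {
    sum(outer(p[nz], p[nz], `+`) * outer(iv[nz], iv[nz], `-`)^2) / sum(s)
  } else 0
  c(ngtdm_Coarseness = coarseness,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness,
    ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}
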