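# Independent brute-force oracles: plain-loop implementations used to verify
# the vectorized package code. Deliberately naive and written against the
# definitions, not against the package internals.

ALL_OFFSETS_26 <- local({
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  as.matrix(g[rowSums(abs(g)) > 0, ])
})

HALF_OFFSETS_13 <- local({
  g <- ALL_OFFSETS_26
  g[g[, "dx"] > 0 | (g[, "dx"] == 0 & g[, "dy"] > 0) |
      (g[, "dx"] == 0 & g[, "dy"] == 0 & g[, "dz"] > 0), , drop = FALSE]
})

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# per-voxel loop discretization
oracle_discretize_levels <- function(vox, mask, bw) {
  vals <- vox[mask]
  mn <- min(vals)
  lev <- array(NA_integer_, dim(vox))
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    lev[p[1], p[2], p[3]] <-
      as.integer(floor((vox[p[1], p[2], p[3]] - mn) / bw)) + 1L
  }
  lev
}

# symmetric normalized GLCM by explicit pair enumeration
oracle_glcm <- function(lev, off, Ng) {
  d <- dim(lev)
  C <- matrix(0, Ng, Ng)
  idx <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    q <- p + off
    if (!in_grid(q, d)) next
    b <- lev[q[1], q[2], q[3]]
    if (is.na(b)) next
    a <- lev[p[1], p[2], p[3]]
    C[a, b] <- C[a, b] + 1
    C[b, a] <- C[b, a] + 1
  }
  if (sum(C) == 0) return(NULL)
  C / sum(C)
}

# run-length matrix by walking each line
oracle_glrlm <- function(lev, off, Ng) {
  d <- dim(lev)
  runs <- list()
  idx <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    prev <- p - off
    a <- lev[p[1], p[2], p[3]]
    prev_same <- in_grid(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
      lev[prev[1], prev[2], prev[3]] == a
    if (prev_same) next # not a run start
    len <- 1L
    q <- p + off
    while (in_grid(q, d) && !is.na(lev[q[1], q[2], q[3]]) &&
           lev[q[1], q[2], q[3]] == a) {
      len <- len + 1L
      q <- q + off
    }
    runs[[length(runs) + 1L]] <- c(a, len)
  }
  lmax <- max(vapply(runs, `[`, numeric(1), 2))
  R <- matrix(0, Ng, lmax)
  for (rn in runs) R[rn[1], rn[2]] <- R[rn[1], rn[2]] + 1
  R
}

# size-zone matrix by BFS over 26-connected equal-level voxels
oracle_glszm <- function(lev, Ng) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  idx <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (seen[p[1], p[2], p[3]]) next
    a <- lev[p[1], p[2], p[3]]
    queue <- list(p)
    seen[p[1], p[2], p[3]] <- TRUE
    size <- 0L
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      for (k in seq_len(nrow(ALL_OFFSETS_26))) {
        q <- cur + ALL_OFFSETS_26[k, ]
        if (!in_grid(q, d)) next
        if (seen[q[1], q[2], q[3]]) next
        b <- lev[q[1], q[2], q[3]]
        if (is.na(b) || b != a) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
    zones[[length(zones) + 1L]] <- c(a, size)
  }
  smax <- max(vapply(zones, `[`, numeric(1), 2))
  Z <- matrix(0, Ng, smax)
  for (z in zones) Z[z[1], z[2]] <- Z[z[1], z[2]] + 1
  Z
}

# dependence matrix by per-voxel neighbour counting (alpha = 0)
oracle_gldm <- function(lev, Ng) {
  d <- dim(lev)
  idx <- which(!is.na(lev), arr.ind = TRUE)
  recs <- matrix(0L, nrow(idx), 2)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    a <- lev[p[1], p[2], p[3]]
    dep <- 0L
    for (k in seq_len(nrow(ALL_OFFSETS_26))) {
      q <- p + ALL_OFFSETS_26[k, ]
      if (!in_grid(q, d)) next
      b <- lev[q[1], q[2], q[3]]
      if (!is.na(b) && b == a) dep <- dep + 1L
    }
    recs[r, ] <- c(a, dep + 1L)
  }
  D <- matrix(0, Ng, max(recs[, 2]))
  for (r in seq_len(nrow(recs))) {
    D[recs[r, 1], recs[r, 2]] <- D[recs[r, 1], recs[r, 2]] + 1
  }
  D
}

# NGTDM s/n table by per-voxel neighbour averaging
oracle_ngtdm <- function(lev, Ng) {
  d <- dim(lev)
  idx <- which(!is.na(lev), arr.ind = TRUE)
  n_i <- numeric(Ng)
  s_i <- numeric(Ng)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    a <- lev[p[1], p[2], p[3]]
    nb <- c()
    for (k in seq_len(nrow(ALL_OFFSETS_26))) {
      q <- p + ALL_OFFSETS_26[k, ]
      if (!in_grid(q, d)) next
      b <- lev[q[1], q[2], q[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (!length(nb)) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  list(n = n_i, s = s_i)
}

# coordinate-descent LASSO: minimizes (1/2n)||y - Xb||^2 + lambda ||b||_1
# (X assumed standardized, intercept = mean(y))
oracle_lasso_cd <- function(X, y, lambda, tol = 1e-12, maxit = 100000L) {
  n <- nrow(X); p <- ncol(X)
  b <- numeric(p)
  b0 <- mean(y)
  r <- y - b0
  xs <- colSums(X^2) / n
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      rho <- sum(X[, j] * r) / n + xs[j] * b[j]
      bj <- sign(rho) * max(0, abs(rho) - lambda) / xs[j]
      if (bj != b[j]) {
        r <- r - X[, j] * (bj - b[j])
        delta <- max(delta, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (delta < tol) break
  }
  list(intercept = b0, beta = b)
}

# AUC by exhaustive positive x negative pair enumeration
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (x in pos) for (y in neg) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(pos) * length(neg))
}

# confusion matrix by nested loops
oracle_confusion <- function(pred, truth, classes) {
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(predicted = classes, pathology = classes))
  for (i in seq_along(pred)) {
    cm[match(pred[i], classes), match(truth[i], classes)] <-
      cm[match(pred[i], classes), match(truth[i], classes)] + 1L
  }
  cm
}

# marching-tetrahedra mesh statistics by per-cell loops (same geometric
# convention as the package: Kuhn split, midpoint cuts, Taubin smoothing),
# written with explicit loops and an independent adjacency construction
oracle_mesh_stats <- function(mask, sp = c(1, 1, 1), smooth_iters = 20L) {
  KUHN <- list(c(0, 1, 3, 7), c(0, 1, 5, 7), c(0, 2, 3, 7),
               c(0, 2, 6, 7), c(0, 4, 5, 7), c(0, 4, 6, 7))
  BITS <- cbind(c(0, 1, 0, 1, 0, 1, 0, 1),
                c(0, 0, 1, 1, 0, 0, 1, 1),
                c(0, 0, 0, 0, 1, 1, 1, 1))
  d <- dim(mask)
  pm <- array(FALSE, d + 2L)
  pm[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask > 0
  tris <- list()
  orient <- function(tri, ref, outward) {
    n <- pracma::cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    s <- sum(n * (colMeans(tri) - ref))
    if ((outward && s < 0) || (!outward && s > 0)) tri[c(1, 3, 2), ] else tri
  }
  pd <- d + 2L
  for (i in 1:(pd[1] - 1)) for (j in 1:(pd[2] - 1)) for (k in 1:(pd[3] - 1)) {
    cv <- logical(8)
    for (v in 1:8) cv[v] <- pm[i + BITS[v, 1], j + BITS[v, 2], k + BITS[v, 3]]
    if (!any(cv)) next
    for (tet in KUHN) {
      vv <- cv[tet + 1]
      P <- lapply(tet + 1, function(v) {
        c(i - 1 + BITS[v, 1], j - 1 + BITS[v, 2], k - 1 + BITS[v, 3])
      })
      nin <- sum(vv)
      if (nin %in% c(0, 4)) next
      if (nin %in% c(1, 3)) {
        lone <- if (nin == 1) which(vv) else which(!vv)
        s <- P[[lone]]
        oth <- setdiff(1:4, lone)
        tri <- rbind((s + P[[oth[1]]]) / 2, (s + P[[oth[2]]]) / 2,
                     (s + P[[oth[3]]]) / 2)
        tris[[length(tris) + 1L]] <- orient(tri, s, outward = (nin == 1))
      } else {
        ins <- which(vv); outs <- which(!vv)
        p1 <- P[[ins[1]]]; p2 <- P[[ins[2]]]
        q1 <- P[[outs[1]]]; q2 <- P[[outs[2]]]
        m11 <- (p1 + q1) / 2; m12 <- (p1 + q2) / 2
        m21 <- (p2 + q1) / 2; m22 <- (p2 + q2) / 2
        ref <- (p1 + p2) / 2
        tris[[length(tris) + 1L]] <- orient(rbind(m11, m12, m22), ref, TRUE)
        tris[[length(tris) + 1L]] <- orient(rbind(m11, m22, m21), ref, TRUE)
      }
    }
  }
  # index the soup
  allv <- do.call(rbind, tris)
  key <- apply(round(allv * 2), 1, paste, collapse = ",")
  uk <- unique(key)
  verts <- allv[!duplicated(key), , drop = FALSE]
  verts <- sweep(verts, 2, sp, `*`)
  faces <- matrix(match(key, uk), ncol = 3, byrow = TRUE)
  # adjacency lists
  nb <- vector("list", nrow(verts))
  for (r in seq_len(nrow(faces))) {
    f <- faces[r, ]
    for (a in 1:3) for (b in 1:3) if (a != b) nb[[f[a]]] <- c(nb[[f[a]]], f[b])
  }
  nb <- lapply(nb, unique)
  v <- verts
  if (smooth_iters > 0) {
    for (it in seq_len(smooth_iters)) {
      for (fac in c(0.5, -0.53)) {
        avg <- t(vapply(nb, function(a) colMeans(v[a, , drop = FALSE]),
                        numeric(3)))
        v <- v + fac * (avg - v)
      }
    }
  }
  A <- 0; V6 <- 0
  for (r in seq_len(nrow(faces))) {
    tri <- v[faces[r, ], , drop = FALSE]
    cr <- pracma::cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    A <- A + 0.5 * sqrt(sum(cr^2))
    V6 <- V6 + sum(tri[1, ] * pracma::cross(tri[2, ], tri[3, ]))
  }
  list(area = A, volume = abs(V6 / 6))
}

# loop-based feature formulas computed from an oracle matrix ---------------

oracle_glcm_features <- function(p) {
  Ng <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:Ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:Ng) { sx2 <- sx2 + (i - mux)^2 * px[i]
                    sy2 <- sy2 + (i - muy)^2 * py[i] }
  ac <- 0; cp <- 0; cs <- 0; ct <- 0; contr <- 0; idm <- 0; idmn <- 0
  id <- 0; idn <- 0; invv <- 0; joint_e <- 0; joint_h <- 0; ssq <- 0
  cor_num <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    q <- p[i, j]
    ac <- ac + i * j * q
    cp <- cp + (i + j - mux - muy)^4 * q
    cs <- cs + (i + j - mux - muy)^3 * q
    ct <- ct + (i + j - mux - muy)^2 * q
    contr <- contr + (i - j)^2 * q
    idm <- idm + q / (1 + (i - j)^2)
    idmn <- idmn + q / (1 + (i - j)^2 / Ng^2)
    id <- id + q / (1 + abs(i - j))
    idn <- idn + q / (1 + abs(i - j) / Ng)
    if (i != j) invv <- invv + q / (i - j)^2
    joint_e <- joint_e + q^2
    if (q > 0) joint_h <- joint_h - q * log2(q)
    ssq <- ssq + (i - mux)^2 * q
    cor_num <- cor_num + i * j * q
  }
  corr <- if (sx2 * sy2 > 0) (cor_num - mux * muy) / sqrt(sx2 * sy2) else 1
  pdiff <- numeric(Ng); psum <- numeric(2 * Ng - 1)
  for (i in 1:Ng) for (j in 1:Ng) {
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
  }
  da <- 0; for (k in seq_along(pdiff)) da <- da + (k - 1) * pdiff[k]
  dv <- 0; dh <- 0
  for (k in seq_along(pdiff)) {
    dv <- dv + (k - 1 - da)^2 * pdiff[k]
    if (pdiff[k] > 0) dh <- dh - pdiff[k] * log2(pdiff[k])
  }
  sh <- 0
  for (k in seq_along(psum)) if (psum[k] > 0) sh <- sh - psum[k] * log2(psum[k])
  hx <- 0; hy <- 0
  for (i in 1:Ng) {
    if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
    if (py[i] > 0) hy <- hy - py[i] * log2(py[i])
  }
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    pq <- px[i] * py[j]
    if (p[i, j] > 0 && pq > 0) hxy1 <- hxy1 - p[i, j] * log2(pq)
    if (pq > 0) hxy2 <- hxy2 - pq * log2(pq)
  }
  imc1 <- if (max(hx, hy) > 0) (joint_h - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - joint_h))))
  nz <- which(px > 0)
  mcc <- if (length(nz) < 2) 1 else {
    Q <- matrix(0, length(nz), length(nz))
    for (a in seq_along(nz)) for (b in seq_along(nz)) {
      s <- 0
      for (k in seq_along(nz)) {
        s <- s + p[nz[a], nz[k]] * p[nz[b], nz[k]] / (px[nz[a]] * py[nz[k]])
      }
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  c(glcm_Autocorrelation = ac, glcm_JointAverage = mux,
    glcm_ClusterProminence = cp, glcm_ClusterShade = cs,
    glcm_ClusterTendency = ct, glcm_Contrast = contr,
    glcm_Correlation = corr, glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = dh, glcm_DifferenceVariance = dv,
    glcm_JointEnergy = joint_e, glcm_JointEntropy = joint_h,
    glcm_Imc1 = imc1, glcm_Imc2 = imc2, glcm_Idm = idm, glcm_MCC = mcc,
    glcm_Idmn = idmn, glcm_Id = id, glcm_Idn = idn,
    glcm_InverseVariance = invv, glcm_MaximumProbability = max(p),
    glcm_SumEntropy = sh, glcm_SumSquares = ssq)
}

oracle_rl_style_features <- function(M, Np, prefix, dims) {
  # shared form of the GLRLM/GLSZM rosters: dims = c(size-ish axis name...)
  N <- sum(M)
  Ng <- nrow(M); L <- ncol(M)
  sre <- 0; lre <- 0; lgl <- 0; hgl <- 0; srl <- 0; srh <- 0; lrl <- 0
  lrh <- 0; gv <- 0; rv <- 0; ent <- 0
  mug <- 0; mul <- 0
  for (g in 1:Ng) for (l in 1:L) {
    q <- M[g, l] / N
    mug <- mug + g * q; mul <- mul + l * q
  }
  for (g in 1:Ng) for (l in 1:L) {
    m <- M[g, l]; q <- m / N
    sre <- sre + m / l^2; lre <- lre + m * l^2
    lgl <- lgl + m / g^2; hgl <- hgl + m * g^2
    srl <- srl + m / (g^2 * l^2); srh <- srh + m * g^2 / l^2
    lrl <- lrl + m * l^2 / g^2; lrh <- lrh + m * g^2 * l^2
    gv <- gv + (g - mug)^2 * q; rv <- rv + (l - mul)^2 * q
    if (q > 0) ent <- ent - q * log2(q)
  }
  gn <- sum(rowSums(M)^2); rn <- sum(colSums(M)^2)
  out <- c(sre / N, lre / N, gn / N, gn / N^2, rn / N, rn / N^2, N / Np,
           gv, rv, ent, lgl / N, hgl / N, srl / N, srh / N, lrl / N, lrh / N)
  names(out) <- paste0(prefix, dims)
  out
}

oracle_glrlm_features_from <- function(R, Np) {
  oracle_rl_style_features(R, Np, "glrlm_", c(
    "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage",
    "GrayLevelVariance", "RunVariance", "RunEntropy",
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
    "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"))
}

oracle_glszm_features_from <- function(Z, Np) {
  oracle_rl_style_features(Z, Np, "glszm_", c(
    "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "ZonePercentage",
    "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
    "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
    "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
    "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))
}

oracle_gldm_features_from <- function(D) {
  Nd <- sum(D)
  Ng <- nrow(D); J <- ncol(D)
  sde <- 0; lde <- 0; lgl <- 0; hgl <- 0; sdl <- 0; sdh <- 0; ldl <- 0
  ldh <- 0; gv <- 0; dv <- 0; ent <- 0; mug <- 0; muj <- 0
  for (g in 1:Ng) for (j in 1:J) {
    q <- D[g, j] / Nd
    mug <- mug + g * q; muj <- muj + j * q
  }
  for (g in 1:Ng) for (j in 1:J) {
    m <- D[g, j]; q <- m / Nd
    sde <- sde + m / j^2; lde <- lde + m * j^2
    lgl <- lgl + m / g^2; hgl <- hgl + m * g^2
    sdl <- sdl + m / (g^2 * j^2); sdh <- sdh + m * g^2 / j^2
    ldl <- ldl + m * j^2 / g^2; ldh <- ldh + m * g^2 * j^2
    gv <- gv + (g - mug)^2 * q; dv <- dv + (j - muj)^2 * q
    if (q > 0) ent <- ent - q * log2(q)
  }
  c(gldm_SmallDependenceEmphasis = sde / Nd,
    gldm_LargeDependenceEmphasis = lde / Nd,
    gldm_GrayLevelNonUniformity = sum(rowSums(D)^2) / Nd,
    gldm_DependenceNonUniformity = sum(colSums(D)^2) / Nd,
    gldm_DependenceNonUniformityNormalized = sum(colSums(D)^2) / Nd^2,
    gldm_GrayLevelVariance = gv, gldm_DependenceVariance = dv,
    gldm_DependenceEntropy = ent,
    gldm_LowGrayLevelEmphasis = lgl / Nd,
    gldm_HighGrayLevelEmphasis = hgl / Nd,
    gldm_SmallDependenceLowGrayLevelEmphasis = sdl / Nd,
    gldm_SmallDependenceHighGrayLevelEmphasis = sdh / Nd,
    gldm_LargeDependenceLowGrayLevelEmphasis = ldl / Nd,
    gldm_LargeDependenceHighGrayLevelEmphasis = ldh / Nd)
}

oracle_ngtdm_features_from <- function(n_i, s_i) {
  Nvp <- sum(n_i)
  p <- n_i / Nvp
  nz <- which(p > 0)
  Ngp <- length(nz)
  den <- sum(p * s_i)
  coars <- if (den > 0) 1 / den else 1e6
  contr <- 0
  if (Ngp > 1) {
    acc <- 0
    for (i in nz) for (j in nz) acc <- acc + p[i] * p[j] * (i - j)^2
    contr <- acc / (Ngp * (Ngp - 1)) * sum(s_i) / Nvp
  }
  bden <- 0
  for (i in nz) for (j in nz) bden <- bden + abs(i * p[i] - j * p[j])
  busy <- if (bden > 0) den / bden else 0
  comp <- 0
  for (i in nz) for (j in nz) {
    comp <- comp + abs(i - j) * (p[i] * s_i[i] + p[j] * s_i[j]) / (p[i] + p[j])
  }
  comp <- comp / Nvp
  stren <- 0
  if (sum(s_i) > 0) {
    for (i in nz) for (j in nz) stren <- stren + (p[i] + p[j]) * (i - j)^2
    stren <- stren / sum(s_i)
  }
  c(ngtdm_Coarseness = coars, ngtdm_Contrast = contr, ngtdm_Busyness = busy,
    ngtdm_Complexity = comp, ngtdm_Strength = stren)
}
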