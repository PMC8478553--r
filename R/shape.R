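#' 3D shape features of a binary mask
#'
#' Thirteen mesh- and moment-based shape descriptors. The lesion surface is
#' extracted by marching tetrahedra on the binary mask (isovalue 0.5, voxel
#' centres as sample points, zero padding outside the grid): each grid cell
#' is split into six Kuhn tetrahedra and the interface crosses cut edges at
#' their midpoints, giving a watertight, outward-oriented triangle mesh.
#' Taubin smoothing then removes the voxel staircase, which would otherwise
#' overestimate the area of oblique surfaces. Surface area is the
#' triangle-area sum and mesh volume the divergence-theorem integral over
#' the smoothed mesh. Axis lengths
#' come from the eigenvalues of the physical-coordinate covariance of the
#' mask voxels (length = 4 sqrt(lambda)); maximum diameters are the largest
#' pairwise surface-voxel distances in 3D and in each coordinate plane.
#'
#' @param mask A `rater_mask` or binary 3D array.
#' @param spacing Numeric length-3 voxel size (mm).
#' @return Named numeric vector of 13 features, plus attribute
#'   `voxel_volume` (voxel-count volume, a diagnostic outside the roster).
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  mvox <- if (is.list(mask)) mask$voxels else mask
  m <- mvox > 0
  if (!any(m)) stop("mask is empty")
  d <- dim(m)
  sp <- as.numeric(spacing)

  mesh <- mesh_surface(m, sp)
  A <- mesh$area
  V <- mesh$volume
  sphericity <- pi^(1 / 3) * (6 * V)^(2 / 3) / A

  idx <- which(m, arr.ind = TRUE)
  coords <- sweep(idx, 2, sp, `*`) # physical (z, y, x)

  # principal axis lengths from population covariance of voxel coordinates
  if (nrow(coords) > 1) {
    cc <- sweep(coords, 2, colMeans(coords))
    covm <- crossprod(cc) / nrow(cc)
    ev <- sort(pmax(eigen(covm, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else {
    ev <- c(0, 0, 0)
  }
  axis_len <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  b <- which(mask_boundary(m), arr.ind = TRUE)
  bc <- sweep(b, 2, sp, `*`)
  max3d <- max_pairwise_dist(bc)
  # plane diameters: slice = fixed z (y-x plane), column = fixed y (z-x),
  # row = fixed x (z-y)
  max2d_slice <- max_plane_dist(bc, fix = 1)
  max2d_col <- max_plane_dist(bc, fix = 2)
  max2d_row <- max_plane_dist(bc, fix = 3)

  out <- c(
    shape_MeshVolume = V,
    shape_SurfaceArea = A,
    shape_SurfaceVolumeRatio = A / V,
    shape_Sphericity = sphericity,
    shape_Maximum3DDiameter = max3d,
    shape_Maximum2DDiameterSlice = max2d_slice,
    shape_Maximum2DDiameterColumn = max2d_col,
    shape_Maximum2DDiameterRow = max2d_row,
    shape_MajorAxisLength = axis_len[1],
    shape_MinorAxisLength = axis_len[2],
    shape_LeastAxisLength = axis_len[3],
    shape_Elongation = elong,
    shape_Flatness = flat
  )
  attr(out, "voxel_volume") <- sum(m) * prod(sp)
  out
}

# Kuhn decomposition of the unit cell: vertex id = bz + 2*by + 4*bx,
# six tetrahedra sharing the 0-7 diagonal.
KUHN_TETS <- list(c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
                  c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))
VBITS <- cbind(bz = c(0, 1, 0, 1, 0, 1, 0, 1),
               by = c(0, 0, 1, 1, 0, 0, 1, 1),
               bx = c(0, 0, 0, 0, 1, 1, 1, 1))

#' Marching-tetrahedra surface mesh statistics
#'
#' Builds the watertight triangle mesh of the mask boundary (isovalue 0.5,
#' edge midpoints, outward-oriented), optionally applies Taubin lambda/mu
#' smoothing to remove the voxel staircase (which otherwise overestimates
#' the area of oblique surfaces), and integrates area and enclosed volume.
#'
#' @param m Logical 3D array.
#' @param sp Voxel spacing.
#' @param smooth_iters Taubin smoothing iterations (0 = raw mesh).
#' @return List with total surface `area` and enclosed mesh `volume`.
#' @keywords internal
mesh_surface <- function(m, sp, smooth_iters = 20L) {
  soup <- mt_triangle_soup(m, sp)
  if (nrow(soup$p1) == 0) return(list(area = 0, volume = 0))
  mesh <- index_mesh(soup)
  mesh$verts <- sweep(mesh$verts, 2, sp, `*`)
  if (smooth_iters > 0) {
    mesh$verts <- taubin_smooth(mesh$verts, mesh$faces, iters = smooth_iters)
  }
  v1 <- mesh$verts[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$verts[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$verts[mesh$faces[, 3], , drop = FALSE]
  u <- v2 - v1; w <- v3 - v1
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  area <- sum(0.5 * sqrt(rowSums(cr^2)))
  cr23 <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
                v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
                v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  vol <- abs(sum(rowSums(v1 * cr23)) / 6)
  list(area = area, volume = vol)
}

# Oriented triangle soup of the marching-tetrahedra isosurface, in index
# units (coordinates are multiples of 0.5; spacing applied by the caller).
# Triangles are wound so normals point away from the mask interior.
mt_triangle_soup <- function(m, sp) {
  d <- dim(m)
  pd <- d + 2L
  pm <- array(FALSE, pd)
  pm[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)] <- m
  pv <- as.vector(pm)

  fg <- which(pm, arr.ind = TRUE)
  # candidate cells: any cell sharing a corner with a foreground voxel
  nz <- pd[1]; nzy <- pd[1] * pd[2]
  lins <- integer(0)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    lins <- c(lins, (fg[, 1] - dz) + (fg[, 2] - 1L - dy) * nz +
                (fg[, 3] - 1L - dx) * nzy)
  }
  lin <- unique(lins)
  base <- cbind(((lin - 1L) %% nz) + 1L,
                (((lin - 1L) %/% nz) %% pd[2]) + 1L,
                ((lin - 1L) %/% nzy) + 1L)

  # corner values for the 8 cell vertices
  vals <- matrix(FALSE, nrow = length(lin), ncol = 8)
  for (v in 1:8) {
    off <- VBITS[v, 1] + VBITS[v, 2] * nz + VBITS[v, 3] * nzy
    vals[, v] <- pv[lin + off]
  }

  # index-unit coordinates of a tet vertex for given cells
  vcoord <- function(vid, cells) {
    cbind(base[cells, 1] - 1 + VBITS[vid + 1, 1],
          base[cells, 2] - 1 + VBITS[vid + 1, 2],
          base[cells, 3] - 1 + VBITS[vid + 1, 3])
  }
  t1 <- list(); t2 <- list(); t3 <- list()
  nblk <- 0L
  # append triangles (a, b, c) wound so the normal points from `ref` toward
  # the triangle (outward when ref is interior, flipped when ref is exterior)
  push <- function(a, b, c, ref, outward = TRUE) {
    u <- b - a; w <- c - a
    n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
    cen <- (a + b + c) / 3
    s <- rowSums(n * (cen - ref))
    flip <- if (outward) s < 0 else s > 0
    bb <- b; bb[flip, ] <- c[flip, ]; cc <- c; cc[flip, ] <- b[flip, ]
    nblk <<- nblk + 1L
    t1[[nblk]] <<- a; t2[[nblk]] <<- bb; t3[[nblk]] <<- cc
  }

  for (tet in KUHN_TETS) {
    tv <- vals[, tet + 1L, drop = FALSE]
    nin <- rowSums(tv)

    # one vertex on one side of the interface (corner cut)
    for (side in c(1L, 3L)) {
      cells <- which(nin == side)
      if (!length(cells)) next
      tvc <- tv[cells, , drop = FALSE]
      lone_pos <- if (side == 1L) max.col(tvc + 0, ties.method = "first") else
        max.col(1 - tvc, ties.method = "first")
      for (lp in 1:4) {
        cc <- cells[lone_pos == lp]
        if (!length(cc)) next
        s <- vcoord(tet[lp], cc)
        oth <- setdiff(1:4, lp)
        m1 <- (s + vcoord(tet[oth[1]], cc)) / 2
        m2 <- (s + vcoord(tet[oth[2]], cc)) / 2
        m3 <- (s + vcoord(tet[oth[3]], cc)) / 2
        # side 1: lone vertex is inside -> normal away from it;
        # side 3: lone vertex is outside -> normal toward it
        push(m1, m2, m3, s, outward = (side == 1L))
      }
    }

    # two-two split: planar parallelogram interface
    cells <- which(nin == 2L)
    if (length(cells)) {
      tvc <- tv[cells, , drop = FALSE]
      pairs <- list(c(1, 2), c(1, 3), c(1, 4))
      for (pr in pairs) {
        qr <- setdiff(1:4, pr)
        for (inv in c(FALSE, TRUE)) {
          selc <- if (!inv) cells[tvc[, pr[1]] & tvc[, pr[2]]] else
            cells[(!tvc[, pr[1]]) & (!tvc[, pr[2]])]
          if (!length(selc)) next
          p1 <- vcoord(tet[pr[1]], selc); p2 <- vcoord(tet[pr[2]], selc)
          q1 <- vcoord(tet[qr[1]], selc); q2 <- vcoord(tet[qr[2]], selc)
          m11 <- (p1 + q1) / 2; m12 <- (p1 + q2) / 2
          m21 <- (p2 + q1) / 2; m22 <- (p2 + q2) / 2
          # inside pair is pr when !inv, qr when inv
          ref <- if (!inv) (p1 + p2) / 2 else (q1 + q2) / 2
          push(m11, m12, m22, ref, outward = TRUE)
          push(m11, m22, m21, ref, outward = TRUE)
        }
      }
    }
  }
  if (nblk == 0L) {
    z <- matrix(numeric(0), 0, 3)
    return(list(p1 = z, p2 = z, p3 = z))
  }
  list(p1 = do.call(rbind, t1), p2 = do.call(rbind, t2),
       p3 = do.call(rbind, t3))
}

# collapse a triangle soup on the half-integer lattice into an indexed mesh
index_mesh <- function(soup) {
  pts <- rbind(soup$p1, soup$p2, soup$p3)
  ip <- round(pts * 2)
  M <- max(ip) + 2
  key <- ip[, 1] + ip[, 2] * M + ip[, 3] * M^2
  uk <- unique(key)
  vid <- match(key, uk)
  verts <- pts[!duplicated(key), , drop = FALSE]
  ntri <- nrow(soup$p1)
  faces <- cbind(vid[seq_len(ntri)],
                 vid[ntri + seq_len(ntri)],
                 vid[2 * ntri + seq_len(ntri)])
  list(verts = verts, faces = faces)
}

# Taubin lambda/mu smoothing: alternating shrink/expand umbrella steps,
# which removes voxel-scale staircase without the volume loss of plain
# Laplacian smoothing
taubin_smooth <- function(verts, faces, iters = 20L, lambda = 0.5,
                          mu = -0.53) {
  n <- nrow(verts)
  e1 <- c(faces[, 1], faces[, 2], faces[, 3],
          faces[, 2], faces[, 3], faces[, 1])
  e2 <- c(faces[, 2], faces[, 3], faces[, 1],
          faces[, 1], faces[, 2], faces[, 3])
  ekey <- (e1 - 1) * n + e2
  keep <- !duplicated(ekey)
  e1 <- e1[keep]; e2 <- e2[keep]
  deg <- tabulate(e1, nbins = n)
  deg[deg == 0] <- 1
  v <- verts
  for (it in seq_len(iters)) {
    for (fac in c(lambda, mu)) {
      avg <- rowsum(v[e2, , drop = FALSE], e1, reorder = TRUE) / deg
      v <- v + fac * (avg - v)
    }
  }
  v
}

max_pairwise_dist <- function(coords) {
  n <- nrow(coords)
  if (n == 1) return(0)
  block <- 512L
  best <- 0
  for (i0 in seq(1, n, by = block)) {
    i1 <- min(i0 + block - 1L, n)
    a <- coords[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(coords^2), `+`) -
      2 * tcrossprod(a, coords)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

max_plane_dist <- function(coords, fix) {
  groups <- split(seq_len(nrow(coords)), coords[, fix])
  best <- 0
  keep <- setdiff(1:3, fix)
  for (g in groups) {
    if (length(g) < 2) next
    best <- max(best, max_pairwise_dist(coords[g, keep, drop = FALSE]))
  }
  best
}
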