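#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cov fitted glm.fit median pnorm predict quantile
#'   rbinom rnorm runif sd var binomial chisq.test kruskal.test setNames
#' @importFrom utils write.csv read.csv
NULL

RCC_CLASSES <- c("ccRCC", "pRCC", "cRCC")
CT_PHASES <- c("NCP", "CMP", "NP", "EP")

#' Separable 3D Gaussian smoothing
#'
#' Smooths a 3D array with an isotropic Gaussian kernel by three axis-wise
#' passes. Edges use replicate padding so the field keeps its variance near
#' the boundary.
#'
#' @param arr 3D numeric array.
#' @param sigma Kernel standard deviation in voxels; `sigma <= 0` returns the
#'   input unchanged.
#' @return Smoothed array of the same dimensions.
#' @keywords internal
gaussian_smooth_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  kern <- exp(-x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  d <- dim(arr)
  smooth_axis1 <- function(a) {
    # a: array, smooth along first dim with replicate padding
    dd <- dim(a)
    m <- matrix(a, nrow = dd[1])
    top <- m[rep(1L, r), , drop = FALSE]
    bot <- m[rep(dd[1], r), , drop = FALSE]
    padded <- rbind(top, m, bot)
    out <- matrix(0, nrow = dd[1], ncol = ncol(m))
    for (i in seq_along(kern)) {
      out <- out + kern[i] * padded[i:(i + dd[1] - 1L), , drop = FALSE]
    }
    array(out, dim = dd)
  }
  a <- smooth_axis1(arr)
  a <- aperm(smooth_axis1(aperm(a, c(2, 1, 3))), c(2, 1, 3))
  a <- aperm(smooth_axis1(aperm(a, c(3, 2, 1))), c(3, 2, 1))
  a
}

#' Binary erosion with a 6-connected structuring element
#'
#' @param mask Logical or 0/1 3D array.
#' @param iterations Number of single-voxel erosion passes.
#' @return Logical array.
#' @keywords internal
erode_mask <- function(mask, iterations = 1L) {
  m <- mask > 0
  if (iterations < 1L) return(m)
  d <- dim(m)
  for (it in seq_len(iterations)) {
    out <- m
    # a voxel survives if all 6 face neighbours (grid-clipped as background)
    # are foreground
    shifted <- function(dz, dy, dx) {
      s <- array(FALSE, d)
      zi <- seq_len(d[1]) + dz; yi <- seq_len(d[2]) + dy; xi <- seq_len(d[3]) + dx
      okz <- zi >= 1 & zi <= d[1]; oky <- yi >= 1 & yi <= d[2]; okx <- xi >= 1 & xi <= d[3]
      s[which(okz), which(oky), which(okx)] <- m[zi[okz], yi[oky], xi[okx]]
      s
    }
    out <- m & shifted(1, 0, 0) & shifted(-1, 0, 0) &
      shifted(0, 1, 0) & shifted(0, -1, 0) &
      shifted(0, 0, 1) & shifted(0, 0, -1)
    m <- out
  }
  m
}

#' Binary dilation with a 6-connected structuring element
#'
#' @param mask Logical or 0/1 3D array.
#' @param iterations Number of single-voxel dilation passes.
#' @return Logical array.
#' @keywords internal
dilate_mask <- function(mask, iterations = 1L) {
  m <- mask > 0
  if (iterations < 1L) return(m)
  d <- dim(m)
  for (it in seq_len(iterations)) {
    shifted <- function(dz, dy, dx) {
      s <- array(FALSE, d)
      zi <- seq_len(d[1]) + dz; yi <- seq_len(d[2]) + dy; xi <- seq_len(d[3]) + dx
      okz <- zi >= 1 & zi <= d[1]; oky <- yi >= 1 & yi <= d[2]; okx <- xi >= 1 & xi <= d[3]
      s[which(okz), which(oky), which(okx)] <- m[zi[okz], yi[oky], xi[okx]]
      s
    }
    m <- m | shifted(1, 0, 0) | shifted(-1, 0, 0) |
      shifted(0, 1, 0) | shifted(0, -1, 0) |
      shifted(0, 0, 1) | shifted(0, 0, -1)
  }
  m
}

#' Boundary voxels of a binary mask
#'
#' Foreground voxels with at least one 6-connected background neighbour
#' (grid edges count as background).
#' @keywords internal
mask_boundary <- function(mask) {
  m <- mask > 0
  m & !erode_mask(m, 1L)
}

# deterministic per-stage seed derivation: keeps every stream below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 2000000000L + 7919L * (as.integer(offset) %% 100000L)) %% 2147483587L + 1L
}
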