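#' Discretize a masked region of interest into gray levels
#'
#' Fixed-bin-width discretization anchored at the ROI minimum:
#' `level(v) = floor((v - min_ROI) / bin_width) + 1`. This makes texture
#' features invariant to adding a constant to all voxels, while keeping the
#' HU scale meaningful through the bin width.
#'
#' @param volume A `phase_volume` (or bare 3D numeric array).
#' @param mask A `rater_mask` (or bare binary array) on the same grid.
#' @param bin_width Bin width in HU; default 25.
#' @return Object of class `discretized_roi`: `levels` (integer array, NA
#'   outside the mask), `values` (raw HU inside the mask), `mask` (logical
#'   array), `Ng`, `bin_width`, `spacing`.
#' @export
discretize <- function(volume, mask, bin_width = 25) {
  vox <- if (is.list(volume)) volume$voxels else volume
  spacing <- if (is.list(volume) && !is.null(volume$spacing)) volume$spacing else c(1, 1, 1)
  mvox <- if (is.list(mask)) mask$voxels else mask
  m <- mvox > 0
  if (!identical(dim(vox), dim(m))) stop("volume and mask grids are misaligned")
  if (!any(m)) stop("mask is empty")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be positive")
  vals <- vox[m]
  if (any(!is.finite(vals))) stop("non-finite voxel values inside the mask")
  lev <- array(NA_integer_, dim = dim(vox))
  lev[m] <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
  structure(list(levels = lev, values = vals, mask = m,
                 Ng = max(lev[m]), bin_width = bin_width,
                 spacing = spacing),
            class = "discretized_roi")
}

#' First-order intensity statistics of an ROI
#'
#' Eighteen descriptors of the raw HU distribution inside the mask. Entropy
#' and uniformity use the discretized gray-level histogram; all others use
#' raw values. Variance, skewness, and kurtosis use population (n) moments;
#' kurtosis is the uncorrected fourth standardized moment (3 for a normal
#' distribution). Constant ROIs give 0 skewness and kurtosis rather than NaN.
#'
#' @param roi A `discretized_roi` from [discretize()].
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(roi) {
  v <- roi$values
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  p <- tabulate(roi$levels[roi$mask], nbins = roi$Ng) / n
  pp <- p[p > 0]
  q <- quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  inner <- v[v >= q[1] & v <= q[4]]
  voxvol <- prod(roi$spacing)
  c(
    firstorder_Mean = mu,
    firstorder_Median = median(v),
    firstorder_Minimum = min(v),
    firstorder_Maximum = max(v),
    firstorder_Range = max(v) - min(v),
    firstorder_Variance = m2,
    firstorder_Skewness = skew,
    firstorder_Kurtosis = kurt,
    firstorder_Energy = sum(v^2),
    firstorder_TotalEnergy = voxvol * sum(v^2),
    firstorder_Entropy = -sum(pp * log2(pp)),
    firstorder_Uniformity = sum(p^2),
    firstorder_MeanAbsoluteDeviation = mean(abs(v - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(v^2)),
    firstorder_10Percentile = q[1],
    firstorder_90Percentile = q[4],
    firstorder_InterquartileRange = q[3] - q[2]
  )
}
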