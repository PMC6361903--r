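#' The 33-feature radiomic catalog
#'
#' Names of the features extracted per site: 8 first-order intensity
#' features, 22 gray-level co-occurrence (GLCM) texture features aggregated
#' in 2.5D, and 3 shape features.
#'
#' @return Character vector of length 33.
#' @export
feature_names <- function() {
  c(
    # first-order intensity
    "GlobalEntropy", "GlobalUniformity", "GlobalMax", "InterQuartileRange",
    "GlobalMean", "Kurtosis", "GlobalStdDev", "Skewness",
    # GLCM 2.5D
    "AutoCorrelation", "Contrast", "Energy", "InformationMeasureCorr1",
    "InverseVariance", "SumVariance", "ClusterProminence", "Correlation",
    "Entropy", "InformationMeasureCorr2", "MaxProbability", "Variance",
    "ClusterShade", "DifferenceEntropy", "Homogeneity", "InverseDiffNorm",
    "SumAverage", "ClusterTendency", "Dissimilarity", "Homogeneity2",
    "InverseDiffMomentNorm", "SumEntropy",
    # shape
    "Max3DDiameter", "Volume", "Roundness"
  )
}

.glcm_feature_names <- function() feature_names()[9:30]

#' Gray-level discretization
#'
#' Quantizes the SUV values of a segmented region into `n_bins` equal-width
#' bins spanning `[min, max]` of the region. The maximum value maps to the
#' top level. A constant region collapses to a single level (`Ng = 1`).
#' The same discretization feeds both the intensity histogram features and
#' the co-occurrence matrices, and is computed once per lesion (all
#' components and slices pooled), so levels are comparable across slices.
#'
#' @param x numeric vector of region SUVs (non-empty).
#' @param n_bins number of gray levels (>= 2).
#' @return Integer vector of levels in `1..Ng` with attribute `n_levels`.
#' @examples
#' discretize(c(2.5, 5, 7.5, 10), 2)  # 1 1 2 2
#' @export
discretize <- function(x, n_bins = 64L) {
  if (length(x) == 0) stop("cannot discretize an empty region")
  if (n_bins < 2) stop("n_bins must be >= 2")
  lo <- min(x); hi <- max(x)
  if (lo == hi)
    return(structure(rep(1L, length(x)), n_levels = 1L))
  lv <- pmin(as.integer(n_bins), floor((x - lo) / (hi - lo) * n_bins) + 1L)
  structure(as.integer(lv), n_levels = as.integer(n_bins))
}

# Offsets (drow, dcol) for the four in-plane directions at distance 1.
.glcm_offsets <- list(
  "0"   = c(0L, 1L),
  "45"  = c(-1L, 1L),
  "90"  = c(-1L, 0L),
  "135" = c(-1L, -1L)
)

# Raw symmetric co-occurrence counts for one offset on a level matrix with
# NA outside the mask.
.glcm_counts_offset <- function(lv, ng, dr, dc) {
  n <- nrow(lv); m <- ncol(lv)
  r0 <- seq.int(max(1L, 1L - dr), min(n, n - dr))
  c0 <- seq.int(max(1L, 1L - dc), min(m, m - dc))
  if (length(r0) == 0 || length(c0) == 0) return(matrix(0, ng, ng))
  a <- lv[r0, c0, drop = FALSE]
  b <- lv[r0 + dr, c0 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, ng, ng))
  cnt <- matrix(tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng), ng, ng,
                byrow = TRUE)
  cnt + t(cnt)  # symmetric accumulation
}

#' Slice-wise gray-level co-occurrence matrix
#'
#' Accumulates symmetric co-occurrence counts at voxel distance 1 over the
#' requested in-plane directions (default all four: 0, 45, 90, 135 degrees)
#' on one 2-D slice, counting a pair only when both voxels are in the mask,
#' then normalizes to probabilities summing to 1. Directions are pooled into
#' a single matrix before normalization.
#'
#' @param levels integer matrix of gray levels with `NA` outside the mask.
#' @param n_levels number of gray levels Ng (matrix is Ng x Ng).
#' @param directions subset of `c("0","45","90","135")`.
#' @return An object of class `glcm` (`p`: Ng x Ng probability matrix,
#'   `n_levels`), or `NULL` when the slice has no valid pair (the slice is
#'   then skipped by the 2.5D aggregation).
#' @export
glcm_slice <- function(levels, n_levels,
                       directions = c("0", "45", "90", "135")) {
  directions <- match.arg(directions, names(.glcm_offsets), several.ok = TRUE)
  ng <- as.integer(n_levels)
  total <- matrix(0, ng, ng)
  for (d in directions) {
    off <- .glcm_offsets[[d]]
    total <- total + .glcm_counts_offset(levels, ng, off[1], off[2])
  }
  s <- sum(total)
  if (s == 0) return(NULL)
  structure(list(p = total / s, n_levels = ng), class = "glcm")
}

# log2 with the 0 log 0 = 0 convention
.plog2 <- function(x) ifelse(x > 0, log2(x), 0)

#' GLCM texture features
#'
#' Computes the 22 co-occurrence features from a normalized symmetric GLCM.
#' Entropies use log base 2 (bits). Degenerate cases follow the
#' constant-image limit and never return NaN: expressions of 0/0 type
#' (information correlation 1 with zero marginal entropy; correlation with
#' zero marginal variance) return 0, and the empty off-diagonal sum of the
#' inverse variance returns 0.
#'
#' With indices \eqn{i, j = 1..N_g}, marginals \eqn{p_x, p_y} and joint
#' entropy \eqn{HXY = -\sum p_{ij} \log_2 p_{ij}}, the inverse variance is
#' \eqn{2 \sum_i \sum_{j>i} p_{ij}/(i-j)^2}, the first information measure of
#' correlation is \eqn{(HXY - HXY_1)/HX} and the second is
#' \eqn{\sqrt{1 - e^{-2(HXY_2 - HXY)}}}.
#'
#' @param g a `glcm` from [glcm_slice()].
#' @return Named numeric vector of the 22 GLCM features.
#' @export
glcm_features <- function(g) {
  p <- g$p
  ng <- g$n_levels
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  lv <- seq_len(ng)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sigx <- sqrt(sum((lv - mux)^2 * px)); sigy <- sqrt(sum((lv - muy)^2 * py))

  HXY <- -sum(p * .plog2(p))
  pxpy <- outer(px, py)
  HXY1 <- -sum(p * .plog2(pxpy))
  HXY2 <- -sum(pxpy * .plog2(pxpy))
  HX <- -sum(px * .plog2(px))

  # diagonal-band marginals p_{x+y}(k), k = 2..2Ng and p_{x-y}(k), k = 0..Ng-1
  psum <- as.vector(tapply(p, i + j, sum))
  ksum <- sort(unique(as.vector(i + j)))
  pdiff <- as.vector(tapply(p, abs(i - j), sum))
  kdiff <- sort(unique(as.vector(abs(i - j))))

  sum_average <- sum(ksum * psum)
  sum_entropy <- -sum(psum * .plog2(psum))
  sum_variance <- sum((ksum - sum_average)^2 * psum)
  diff_entropy <- -sum(pdiff * .plog2(pdiff))

  upper <- j > i
  inv_var <- if (any(upper)) 2 * sum(p[upper] / (i[upper] - j[upper])^2) else 0

  corr <- if (sigx > 0 && sigy > 0)
    (sum(i * j * p) - mux * muy) / (sigx * sigy) else 0
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))

  c(
    AutoCorrelation       = sum(i * j * p),
    Contrast              = sum((i - j)^2 * p),
    Energy                = sum(p^2),
    InformationMeasureCorr1 = imc1,
    InverseVariance       = inv_var,
    SumVariance           = sum_variance,
    ClusterProminence     = sum((i + j - mux - muy)^4 * p),
    Correlation           = corr,
    Entropy               = HXY,
    InformationMeasureCorr2 = imc2,
    MaxProbability        = max(p),
    Variance              = sum((i - mux)^2 * p),
    ClusterShade          = sum((i + j - mux - muy)^3 * p),
    DifferenceEntropy     = diff_entropy,
    Homogeneity           = sum(p / (1 + abs(i - j))),
    InverseDiffNorm       = sum(p / (1 + abs(i - j) / ng)),
    SumAverage            = sum_average,
    ClusterTendency       = sum((i + j - mux - muy)^2 * p),
    Dissimilarity         = sum(abs(i - j) * p),
    Homogeneity2          = sum(p / (1 + (i - j)^2)),
    InverseDiffMomentNorm = sum(p / (1 + (i - j)^2 / ng^2)),
    SumEntropy            = sum_entropy
  )
}

#' 2.5D aggregation of slice features
#'
#' Texture features are first computed on each 2-D slice and then combined
#' into 2.5D features by unweighted averaging across the slices of the 3-D
#' lesion.
#'
#' @param per_slice list (or matrix rows) of per-slice 22-feature vectors.
#' @return Named numeric vector, the per-feature mean.
#' @export
aggregate_2_5d <- function(per_slice) {
  if (is.list(per_slice)) per_slice <- do.call(rbind, per_slice)
  if (is.null(per_slice) || nrow(per_slice) == 0)
    stop("lesion too thin for texture analysis: no slice contributed a co-occurrence matrix")
  colMeans(per_slice)
}

#' First-order intensity features
#'
#' Entropy and uniformity are computed on the discretized histogram (same
#' gray-level binning as the GLCM); maximum, mean, standard deviation,
#' interquartile range, skewness and kurtosis on the raw SUVs. The maximum
#' is the region SUVmax. Conventions: standard deviation uses the n-1
#' denominator; the IQR uses linear-interpolation quantiles (type 7);
#' skewness is the population moment ratio m3 / m2^(3/2) and kurtosis the
#' excess kurtosis m4 / m2^2 - 3; when the region is constant (or a single
#' voxel) all dispersion-dependent features are 0 by convention, entropy is
#' 0 and uniformity 1.
#'
#' @param suvs SUV values of the segmented region (non-empty).
#' @param n_bins gray levels for the histogram features.
#' @return Named numeric vector of the 8 intensity features.
#' @export
intensity_features <- function(suvs, n_bins = 64L) {
  if (length(suvs) == 0) stop("empty region")
  lv <- discretize(suvs, n_bins)
  h <- tabulate(lv, nbins = attr(lv, "n_levels")) / length(lv)
  entropy <- -sum(h * .plog2(h))
  uniformity <- sum(h^2)

  n <- length(suvs)
  m <- mean(suvs)
  m2 <- mean((suvs - m)^2)
  if (n < 2 || m2 == 0) {
    sdv <- 0; skew <- 0; kurt <- 0
  } else {
    sdv <- stats::sd(suvs)
    skew <- mean((suvs - m)^3) / m2^1.5
    kurt <- mean((suvs - m)^4) / m2^2 - 3
  }
  c(GlobalEntropy = entropy,
    GlobalUniformity = uniformity,
    GlobalMax = max(suvs),
    InterQuartileRange = unname(stats::quantile(suvs, 0.75, type = 7) -
                                  stats::quantile(suvs, 0.25, type = 7)),
    GlobalMean = m,
    Kurtosis = kurt,
    GlobalStdDev = sdv,
    Skewness = skew)
}

# Linear indices -> (slice,row,col) voxel-center coordinates in mm.
.voxel_coords_mm <- function(idx, dim3, spacing) {
  s <- ((idx - 1L) %% dim3[1]) + 1L
  r <- (((idx - 1L) %/% dim3[1]) %% dim3[2]) + 1L
  cc <- ((idx - 1L) %/% (dim3[1] * dim3[2])) + 1L
  # spacing = (dx, dy, dz): col spacing, row spacing, slice spacing
  cbind(x = (cc - 0.5) * spacing[1],
        y = (r - 0.5) * spacing[2],
        z = (s - 0.5) * spacing[3])
}

# Boundary voxels (some 6-neighbor outside the set); the maximum pairwise
# distance is attained between extreme points, which are boundary voxels.
.boundary_idx <- function(idx, dim3) {
  inset <- array(FALSE, dim3)
  inset[idx] <- TRUE
  pad <- array(FALSE, dim3 + 2L)
  pad[2:(dim3[1] + 1), 2:(dim3[2] + 1), 2:(dim3[3] + 1)] <- inset
  core <- pad[2:(dim3[1] + 1), 2:(dim3[2] + 1), 2:(dim3[3] + 1)]
  interior <- core &
    pad[1:dim3[1], 2:(dim3[2] + 1), 2:(dim3[3] + 1)] &
    pad[3:(dim3[1] + 2), 2:(dim3[2] + 1), 2:(dim3[3] + 1)] &
    pad[2:(dim3[1] + 1), 1:dim3[2], 2:(dim3[3] + 1)] &
    pad[2:(dim3[1] + 1), 3:(dim3[2] + 2), 2:(dim3[3] + 1)] &
    pad[2:(dim3[1] + 1), 2:(dim3[2] + 1), 1:dim3[3]] &
    pad[2:(dim3[1] + 1), 2:(dim3[2] + 1), 3:(dim3[3] + 2)]
  which(core & !interior)
}

#' Shape features of a segmented site
#'
#' `Volume` is the metabolic tumor volume in cc. `Max3DDiameter` is the
#' largest Euclidean distance (mm) between the centers of two segmented
#' voxels. `Roundness` relates the volume to the sphere whose diameter is
#' `Max3DDiameter`: `Volume / (pi/6 * (Max3DDiameter/10)^3)`; this is a
#' sphere-referenced compactness (1 for a perfect ball, smaller for
#' elongated shapes; voxelization can push tiny lesions above 1). A
#' single-voxel region has diameter 0 and roundness 1 by convention.
#'
#' @param seg a [threshold_segment()] result with at least one voxel.
#' @return Named numeric vector `Max3DDiameter` (mm), `Volume` (cc),
#'   `Roundness`.
#' @export
shape_features <- function(seg) {
  if (seg$n_voxels == 0) stop("empty segmentation has no shape")
  if (seg$n_voxels == 1)
    return(c(Max3DDiameter = 0, Volume = seg$mtv_cc, Roundness = 1))
  bidx <- .boundary_idx(seg$voxels, seg$dim)
  xyz <- .voxel_coords_mm(bidx, seg$dim, seg$spacing)
  dmax <- max(stats::dist(xyz))
  sphere_cc <- pi / 6 * (dmax / 10)^3
  c(Max3DDiameter = dmax,
    Volume = seg$mtv_cc,
    Roundness = if (sphere_cc > 0) seg$mtv_cc / sphere_cc else 1)
}

#' Extract the 33-feature vector for one site
#'
#' Runs the full per-site pipeline: threshold segmentation, small-volume
#' check, one lesion-wide gray-level discretization, per-slice co-occurrence
#' matrices pooled over the four in-plane directions (or, optionally,
#' features averaged per direction), 2.5D averaging, intensity and shape
#' features. Disconnected components of the mask are pooled into one
#' feature set.
#'
#' @param vol an [suv_volume].
#' @param mask a [site_mask].
#' @param threshold SUV segmentation threshold.
#' @param min_cc minimum metabolic volume; smaller sites are an error here
#'   (filter them upstream with [filter_small_sites()]).
#' @param n_bins gray levels for discretization.
#' @param direction_pooling `"pool"` (default) accumulates the four
#'   directions into a single matrix per slice; `"average"` computes the 22
#'   features per direction and averages them.
#' @param seg optional pre-computed segmentation (skips re-thresholding).
#' @return Named numeric vector of the 33 features in [feature_names()]
#'   order.
#' @export
extract_feature_vector <- function(vol, mask, threshold = 2.5, min_cc = 5.0,
                                   n_bins = 64L,
                                   direction_pooling = c("pool", "average"),
                                   seg = NULL) {
  direction_pooling <- match.arg(direction_pooling)
  if (is.null(seg)) seg <- threshold_segment(vol, mask, threshold)
  if (seg$mtv_cc < min_cc)
    stop(sprintf("site '%s' MTV %.3f cc is below the %.1f cc minimum",
                 seg$site_label, seg$mtv_cc, min_cc))

  suvs <- vol$voxels[seg$voxels]
  inten <- intensity_features(suvs, n_bins)

  lv <- discretize(suvs, n_bins)
  ng <- attr(lv, "n_levels")
  d <- seg$dim
  lv_arr <- array(NA_integer_, d)
  lv_arr[seg$voxels] <- lv

  slices <- sort(unique(((seg$voxels - 1L) %% d[1]) + 1L))
  per_slice <- list()
  for (s in slices) {
    sl <- matrix(lv_arr[s, , ], d[2], d[3])
    if (direction_pooling == "pool") {
      g <- glcm_slice(sl, ng)
      if (!is.null(g)) per_slice[[length(per_slice) + 1L]] <- glcm_features(g)
    } else {
      per_dir <- list()
      for (dd in names(.glcm_offsets)) {
        g <- glcm_slice(sl, ng, directions = dd)
        if (!is.null(g)) per_dir[[length(per_dir) + 1L]] <- glcm_features(g)
      }
      if (length(per_dir) > 0)
        per_slice[[length(per_slice) + 1L]] <- colMeans(do.call(rbind, per_dir))
    }
  }
  texture <- aggregate_2_5d(per_slice)
  shape <- shape_features(seg)

  out <- c(inten, texture, shape)[feature_names()]
  stopifnot(!anyNA(out), all(is.finite(out)))
  out
}
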