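# Feature formulas for the five texture classes. Every feature returns a
# finite value: formulas that divide by zero on degenerate (single-level,
# single-voxel) ROIs return their documented limits instead of NaN.

glcm_features_one <- function(counts) {
  ng <- nrow(counts)
  N <- sum(counts)
  out <- setNames(numeric(23), catalog_class_members()$glcm)
  if (N == 0) {
    out["Correlation"] <- 1
    out[c("Id", "Idm", "Idmn", "Idn")] <- 0
    return(out)
  }
  p <- counts / N
  i <- matrix(1:ng, ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(i * p)                      # == mean of both margins (symmetric p)
  sigx2 <- sum((1:ng - mu)^2 * px)
  # diagonal and cross-diagonal distributions
  k_diff <- 0:(ng - 1)
  pxmy <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  pxpy <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  DA <- sum(k_diff * pxmy)
  HX <- -sum(xlog2(px))
  HXY <- -sum(xlog2(p))
  pxpyT <- outer(px, px)
  HXY1 <- -sum(p * ifelse(pxpyT > 0, log2(pxpyT), 0))
  HXY2 <- -sum(xlog2(pxpyT))
  out["Autocorrelation"] <- sum(i * j * p)
  out["JointAverage"] <- mu
  out["ClusterProminence"] <- sum((i + j - 2 * mu)^4 * p)
  out["ClusterShade"] <- sum((i + j - 2 * mu)^3 * p)
  out["ClusterTendency"] <- sum((i + j - 2 * mu)^2 * p)
  out["Contrast"] <- sum((i - j)^2 * p)
  out["Correlation"] <- if (sigx2 > 0) {
    (out[["Autocorrelation"]] - mu^2) / sigx2
  } else 1
  out["DifferenceAverage"] <- DA
  out["DifferenceEntropy"] <- -sum(xlog2(pxmy))
  out["DifferenceVariance"] <- sum((k_diff - DA)^2 * pxmy)
  out["Id"] <- sum(p / (1 + abs(i - j)))
  out["Idm"] <- sum(p / (1 + (i - j)^2))
  out["Idmn"] <- sum(p / (1 + ((i - j) / ng)^2))
  out["Idn"] <- sum(p / (1 + abs(i - j) / ng))
  # p is symmetric so HX == HY and max(HX, HY) == HX
  out["Imc1"] <- if (HX > 0) (HXY - HXY1) / HX else 0
  out["Imc2"] <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  off <- abs(i - j) > 0
  out["InverseVariance"] <- sum(p[off] / (i - j)[off]^2)
  out["JointEnergy"] <- sum(p^2)
  out["JointEntropy"] <- HXY
  out["MaximumProbability"] <- max(p)
  out["SumAverage"] <- sum(k_sum * pxpy)
  out["SumEntropy"] <- -sum(xlog2(pxpy))
  out["SumSquares"] <- sigx2
  out
}

#' Compute the 23 GLCM features from a co-occurrence matrix
#'
#' Features are computed per direction on the normalized matrix and averaged
#' with equal weights over the 13 directions.
#'
#' @param tm a [glcm_matrix()] result.
#' @return Named numeric vector of 23 features.
#' @export
glcm_features <- function(tm) {
  stopifnot(tm$kind == "GLCM")
  per_dir <- vapply(tm$directions, glcm_features_one,
                    numeric(length(catalog_class_members()$glcm)))
  rowMeans(per_dir)
}

glrlm_features_one <- function(counts, n_voxels) {
  nm <- catalog_class_members()$glrlm
  out <- setNames(numeric(length(nm)), nm)
  Nr <- sum(counts)
  if (Nr == 0) return(out)
  ng <- nrow(counts); nl <- ncol(counts)
  p <- counts / Nr
  i <- matrix(1:ng, ng, nl)
  jl <- matrix(1:nl, ng, nl, byrow = TRUE)
  pg <- rowSums(counts)   # runs per gray level
  pr <- colSums(counts)   # runs per length
  mu_i <- sum(i * p)
  mu_j <- sum(jl * p)
  out["GrayLevelNonUniformity"] <- sum(pg^2) / Nr
  out["GrayLevelNonUniformityNormalized"] <- sum(pg^2) / Nr^2
  out["GrayLevelVariance"] <- sum((i - mu_i)^2 * p)
  out["HighGrayLevelRunEmphasis"] <- sum(i^2 * p)
  out["LongRunEmphasis"] <- sum(jl^2 * p)
  out["LongRunHighGrayLevelEmphasis"] <- sum(i^2 * jl^2 * p)
  out["LongRunLowGrayLevelEmphasis"] <- sum(jl^2 * p / i^2)
  out["LowGrayLevelRunEmphasis"] <- sum(p / i^2)
  out["RunEntropy"] <- -sum(xlog2(p))
  out["RunLengthNonUniformity"] <- sum(pr^2) / Nr
  out["RunLengthNonUniformityNormalized"] <- sum(pr^2) / Nr^2
  out["RunPercentage"] <- Nr / n_voxels
  out["RunVariance"] <- sum((jl - mu_j)^2 * p)
  out["ShortRunEmphasis"] <- sum(p / jl^2)
  out["ShortRunHighGrayLevelEmphasis"] <- sum(i^2 * p / jl^2)
  out["ShortRunLowGrayLevelEmphasis"] <- sum(p / (i^2 * jl^2))
  out
}

#' Compute the 16 GLRLM features from a run-length matrix
#'
#' @param tm a [glrlm_matrix()] result.
#' @return Named numeric vector of 16 features (direction-averaged).
#' @export
glrlm_features <- function(tm) {
  stopifnot(tm$kind == "GLRLM")
  per_dir <- vapply(tm$directions, glrlm_features_one, n_voxels = tm$n_voxels,
                    numeric(length(catalog_class_members()$glrlm)))
  rowMeans(per_dir)
}

#' Compute the 16 GLSZM features from a size-zone matrix
#'
#' @param tm a [glszm_matrix()] result.
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(tm) {
  stopifnot(tm$kind == "GLSZM")
  nm <- catalog_class_members()$glszm
  out <- setNames(numeric(length(nm)), nm)
  counts <- tm$matrix
  Nz <- sum(counts)
  if (Nz == 0) return(out)
  ng <- nrow(counts); ns <- ncol(counts)
  p <- counts / Nz
  i <- matrix(1:ng, ng, ns)
  js <- matrix(1:ns, ng, ns, byrow = TRUE)
  pg <- rowSums(counts)
  pz <- colSums(counts)
  mu_i <- sum(i * p)
  mu_j <- sum(js * p)
  out["GrayLevelNonUniformity"] <- sum(pg^2) / Nz
  out["GrayLevelNonUniformityNormalized"] <- sum(pg^2) / Nz^2
  out["GrayLevelVariance"] <- sum((i - mu_i)^2 * p)
  out["HighGrayLevelZoneEmphasis"] <- sum(i^2 * p)
  out["LargeAreaEmphasis"] <- sum(js^2 * p)
  out["LargeAreaHighGrayLevelEmphasis"] <- sum(i^2 * js^2 * p)
  out["LargeAreaLowGrayLevelEmphasis"] <- sum(js^2 * p / i^2)
  out["LowGrayLevelZoneEmphasis"] <- sum(p / i^2)
  out["SizeZoneNonUniformity"] <- sum(pz^2) / Nz
  out["SizeZoneNonUniformityNormalized"] <- sum(pz^2) / Nz^2
  out["SmallAreaEmphasis"] <- sum(p / js^2)
  out["SmallAreaHighGrayLevelEmphasis"] <- sum(i^2 * p / js^2)
  out["SmallAreaLowGrayLevelEmphasis"] <- sum(p / (i^2 * js^2))
  out["ZoneEntropy"] <- -sum(xlog2(p))
  out["ZonePercentage"] <- Nz / tm$n_voxels
  out["ZoneVariance"] <- sum((js - mu_j)^2 * p)
  out
}

#' Compute the 14 GLDM features from a dependence matrix
#'
#' @param tm a [gldm_matrix()] result.
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(tm) {
  stopifnot(tm$kind == "GLDM")
  nm <- catalog_class_members()$gldm
  out <- setNames(numeric(length(nm)), nm)
  counts <- tm$matrix
  Nz <- sum(counts)
  if (Nz == 0) return(out)
  ng <- nrow(counts); nd <- ncol(counts)
  p <- counts / Nz
  i <- matrix(1:ng, ng, nd)
  # dependence d runs 0..nd-1; formulas use the shifted index j = d + 1
  jd <- matrix(1:nd, ng, nd, byrow = TRUE)
  pg <- rowSums(counts)
  pd <- colSums(counts)
  mu_i <- sum(i * p)
  mu_j <- sum(jd * p)
  out["DependenceEntropy"] <- -sum(xlog2(p))
  out["DependenceNonUniformity"] <- sum(pd^2) / Nz
  out["DependenceNonUniformityNormalized"] <- sum(pd^2) / Nz^2
  out["DependenceVariance"] <- sum((jd - mu_j)^2 * p)
  out["GrayLevelNonUniformity"] <- sum(pg^2) / Nz
  out["GrayLevelVariance"] <- sum((i - mu_i)^2 * p)
  out["HighGrayLevelEmphasis"] <- sum(i^2 * p)
  out["LargeDependenceEmphasis"] <- sum(jd^2 * p)
  out["LargeDependenceHighGrayLevelEmphasis"] <- sum(i^2 * jd^2 * p)
  out["LargeDependenceLowGrayLevelEmphasis"] <- sum(jd^2 * p / i^2)
  out["LowGrayLevelEmphasis"] <- sum(p / i^2)
  out["SmallDependenceEmphasis"] <- sum(p / jd^2)
  out["SmallDependenceHighGrayLevelEmphasis"] <- sum(i^2 * p / jd^2)
  out["SmallDependenceLowGrayLevelEmphasis"] <- sum(p / (i^2 * jd^2))
  out
}

#' Compute the 5 NGTDM features from the neighborhood difference vectors
#'
#' @param tm an [ngtdm_vector()] result.
#' @return Named numeric vector: Busyness, Coarseness, Complexity, Contrast,
#'   Strength.
#' @export
ngtdm_features <- function(tm) {
  stopifnot(tm$kind == "NGTDM")
  nm <- catalog_class_members()$ngtdm
  out <- setNames(numeric(length(nm)), nm)
  n_i <- tm$n_i
  s_i <- tm$s_i
  Nvp <- sum(n_i)
  if (Nvp == 0) {
    out["Coarseness"] <- 1e6
    return(out)
  }
  p_i <- n_i / Nvp
  present <- which(p_i > 0)
  ngp <- length(present)
  lev <- tm$levels
  denom_coarse <- sum(p_i * s_i)
  out["Coarseness"] <- if (denom_coarse > 0) min(1 / denom_coarse, 1e6) else 1e6
  if (ngp > 1) {
    pi_p <- p_i[present]; lv_p <- lev[present]; si_p <- s_i[present]
    ii <- matrix(lv_p, ngp, ngp)
    jj <- t(ii)
    pii <- matrix(pi_p, ngp, ngp)
    pjj <- t(pii)
    out["Contrast"] <- sum(pii * pjj * (ii - jj)^2) / (ngp * (ngp - 1)) *
      sum(s_i) / Nvp
    # ordered double sum over present levels, per the standard definition
    denom_busy <- sum(abs(outer(lv_p * pi_p, lv_p * pi_p, "-")))
    out["Busyness"] <- if (denom_busy > 0) sum(p_i * s_i) / denom_busy else 0
    sii <- matrix(si_p, ngp, ngp)
    sjj <- t(sii)
    out["Complexity"] <- sum(abs(ii - jj) * (pii * sii + pjj * sjj) /
                               (pii + pjj)) / Nvp
    denom_str <- sum(s_i)
    out["Strength"] <- if (denom_str > 0) {
      sum((pii + pjj) * (ii - jj)^2) / denom_str
    } else 0
  }
  out
}

#' First-order intensity statistics
#'
#' The 18-feature first-order class: energy, entropy and uniformity (on the
#' fixed-bin-width discretized levels), location, dispersion and shape-of-
#' distribution statistics of the raw ROI intensities. Variance, skewness and
#' kurtosis use the population (biased) moments; kurtosis is not
#' excess-corrected; skewness and kurtosis of a constant ROI are 0.
#'
#' @param droi a [discretize_roi()] result (supplies both raw intensities and
#'   discretized levels).
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  x <- droi$values
  n <- length(x)
  vvox <- prod(droi$spacing_mm)
  lv <- droi$levels[!is.na(droi$levels)]
  ph <- tabulate(lv, nbins = droi$ng) / n
  m <- mean(x)
  cen <- x - m
  m2 <- mean(cen^2)
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  robust <- x[x >= q[1] & x <= q[5]]
  nm <- catalog_class_members()$firstorder
  out <- setNames(numeric(length(nm)), nm)
  out["Energy"] <- sum(x^2)
  out["TotalEnergy"] <- vvox * sum(x^2)
  out["Entropy"] <- -sum(xlog2(ph))
  out["Minimum"] <- min(x)
  out["10Percentile"] <- q[1]
  out["90Percentile"] <- q[5]
  out["Maximum"] <- max(x)
  out["Mean"] <- m
  out["Median"] <- q[3]
  out["InterquartileRange"] <- q[4] - q[2]
  out["Range"] <- max(x) - min(x)
  out["MeanAbsoluteDeviation"] <- mean(abs(cen))
  out["RobustMeanAbsoluteDeviation"] <- mean(abs(robust - mean(robust)))
  out["RootMeanSquared"] <- sqrt(mean(x^2))
  out["Skewness"] <- if (m2 > 0) mean(cen^3) / m2^1.5 else 0
  out["Kurtosis"] <- if (m2 > 0) mean(cen^4) / m2^2 else 0
  out["Variance"] <- m2
  out["Uniformity"] <- sum(ph^2)
  out
}
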