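# The pinned feature catalog: 13 shape + 18 first-order + 23 GLCM + 14 GLDM +
# 16 GLRLM + 16 GLSZM + 5 NGTDM = 105 features on the original image, and the
# 92 non-shape features on each of the 8 wavelet sub-bands = 736, for a total
# of 841. Class membership is the enforced contract: GLCM is the 24-feature
# standard set minus MCC; first-order is the 19-feature standard set minus
# StandardDeviation; shape is the 13 classic 3D descriptors (no voxel-count
# volume).

catalog_class_members <- function() {
  list(
    shape = c(
      "MeshVolume", "SurfaceArea", "SurfaceVolumeRatio", "Sphericity",
      "Maximum3DDiameter", "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
      "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
      "LeastAxisLength", "Elongation", "Flatness"
    ),
    firstorder = c(
      "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
      "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
      "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
      "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"
    ),
    glcm = c(
      "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
      "Imc1", "Imc2", "InverseVariance", "JointEnergy", "JointEntropy",
      "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"
    ),
    gldm = c(
      "DependenceEntropy", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "DependenceVariance",
      "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
      "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
      "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
      "SmallDependenceLowGrayLevelEmphasis"
    ),
    glrlm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
      "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
      "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
      "ShortRunLowGrayLevelEmphasis"
    ),
    glszm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
      "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
      "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
      "ZoneEntropy", "ZonePercentage", "ZoneVariance"
    ),
    ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
  )
}

wavelet_band_labels <- function() {
  c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")
}

#' The pinned radiomic feature catalog
#'
#' Enumerates all 841 feature names in their fixed extraction order, serialized
#' as `{imagetype}_{class}_{name}` (e.g.
#' `wavelet_LHL_glszm_SizeZoneNonUniformityNormalized`). The original image
#' contributes 105 features (13 shape, 18 first-order, 23 GLCM, 14 GLDM,
#' 16 GLRLM, 16 GLSZM, 5 NGTDM); each of the 8 wavelet sub-bands contributes
#' the 92 non-shape features.
#'
#' @return A data frame with columns `name`, `image_type` (`original` or
#'   `wavelet_<band>`), `class` and `base_name`, with 841 rows.
#' @export
feature_catalog <- function() {
  cls <- catalog_class_members()
  order_nonshape <- c("firstorder", "glcm", "gldm", "glrlm", "glszm", "ngtdm")
  build <- function(image_type, classes) {
    do.call(rbind, lapply(classes, function(cl) {
      data.frame(
        name = paste(image_type, cl, cls[[cl]], sep = "_"),
        image_type = image_type, class = cl, base_name = cls[[cl]],
        stringsAsFactors = FALSE
      )
    }))
  }
  orig <- build("original", c("shape", order_nonshape))
  wav <- do.call(rbind, lapply(wavelet_band_labels(), function(b) {
    build(paste0("wavelet_", b), order_nonshape)
  }))
  out <- rbind(orig, wav)
  rownames(out) <- NULL
  out
}
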