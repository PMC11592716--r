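# Fixed registry of the 93 map features: 18 first-order + 24 GLCM + 14 GLDM +
# 16 GLRLM + 16 GLSZM + 5 NGTDM. Order is frozen; every FeatureVector and every
# map stack follows it.

.FIRSTORDER_NAMES <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile", "90Percentile",
  "Maximum", "Mean", "Median", "InterquartileRange", "Range",
  "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
  "Skewness", "Kurtosis", "Variance", "Uniformity"
)

.GLCM_NAMES <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"
)

.GLDM_NAMES <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis", "GrayLevelNonUniformity",
  "DependenceNonUniformity", "DependenceNonUniformityNormalized",
  "GrayLevelVariance", "DependenceVariance", "DependenceEntropy",
  "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LargeDependenceHighGrayLevelEmphasis"
)

.GLRLM_NAMES <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis"
)

.GLSZM_NAMES <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis"
)

.NGTDM_NAMES <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

#' Feature registry
#'
#' The fixed table of the 93 features computed per grid cell: 18 first-order,
#' 24 gray-level co-occurrence (GLCM), 14 gray-level dependence (GLDM), 16
#' run-length (GLRLM), 16 size-zone (GLSZM) and 5 neighbouring gray tone
#' difference (NGTDM) features. Shape features are deliberately absent: a grid
#' cell has no shape of interest.
#'
#' @return A data.frame with columns \code{name} (\code{family.Feature}),
#'   \code{family} and \code{index} (position in every feature vector and map
#'   stack).
#' @examples
#' nrow(feature_registry())  # 93
#' table(feature_registry()$family)
#' @export
feature_registry <- function() {
  fam <- c(
    rep("firstorder", length(.FIRSTORDER_NAMES)),
    rep("glcm", length(.GLCM_NAMES)),
    rep("gldm", length(.GLDM_NAMES)),
    rep("glrlm", length(.GLRLM_NAMES)),
    rep("glszm", length(.GLSZM_NAMES)),
    rep("ngtdm", length(.NGTDM_NAMES))
  )
  feat <- c(.FIRSTORDER_NAMES, .GLCM_NAMES, .GLDM_NAMES, .GLRLM_NAMES,
            .GLSZM_NAMES, .NGTDM_NAMES)
  data.frame(
    name = paste(fam, feat, sep = "."),
    family = fam,
    index = seq_along(feat),
    stringsAsFactors = FALSE
  )
}

#' Names of all 93 registry features, in registry order
#' @return Character vector of length 93.
#' @export
feature_names <- function() feature_registry()$name

#' Write the feature registry as CSV
#'
#' Convenience export used to join report tables on feature name.
#'
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_feature_registry <- function(path) {
  utils::write.csv(feature_registry(), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
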