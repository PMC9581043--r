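# Feature-bank name constants, defined here (early in collation order) so
# every module and registry builds from one authoritative list.

FIRSTORDER_NAMES <- c("Energy", "TotalEnergy", "Entropy", "Minimum",
                      "TenthPercentile", "NinetiethPercentile", "Maximum",
                      "Mean", "Median", "InterquartileRange", "Range",
                      "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
                      "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
                      "Uniformity")

SHAPE_NAMES <- c("VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
                 "Sphericity", "Compactness", "Maximum3DDiameter",
                 "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
                 "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
                 "LeastAxisLength", "Elongation", "Flatness")

GLCM_NAMES <- c("Autocorrelation", "JointAverage", "ClusterProminence",
                "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
                "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
                "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
                "Id", "Idn", "InverseVariance", "MaximumProbability",
                "SumEntropy", "SumSquares")

GLRLM_NAMES <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
                 "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
                 "RunLengthNonUniformityNormalized", "RunPercentage",
                 "GrayLevelVariance", "RunVariance", "RunEntropy",
                 "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
                 "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
                 "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")

GLSZM_NAMES <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
                 "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
                 "SizeZoneNonUniformityNormalized", "ZonePercentage",
                 "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
                 "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
                 "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
                 "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")

GLDM_NAMES <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                "GrayLevelNonUniformity", "DependenceNonUniformity",
                "DependenceNonUniformityNormalized", "GrayLevelVariance",
                "DependenceVariance", "DependenceEntropy",
                "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                "SmallDependenceLowGrayLevelEmphasis",
                "SmallDependenceHighGrayLevelEmphasis",
                "LargeDependenceLowGrayLevelEmphasis",
                "LargeDependenceHighGrayLevelEmphasis")

NGTDM_NAMES <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

VISUAL_MEASURES <- c("area_px", "perimeter", "major_axis", "minor_axis",
                     "eccentricity", "solidity", "extent", "circularity",
                     "equivalent_diameter", "mean_h_od")

# 19 co-occurrence features used per (direction, distance) of the histology
# bank: the 3D GLCM set minus JointAverage (redundant with the first-order
# mean) and the two Ng-normalized inverse-difference variants.
HISTO_GLCM_NAMES <- setdiff(GLCM_NAMES, c("JointAverage", "Idmn", "Idn"))

HISTO_GLCM_DIRS <- list(a0 = c(0L, 1L, 0L), a45 = c(-1L, 1L, 0L),
                        a90 = c(1L, 0L, 0L), a135 = c(1L, 1L, 0L))
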