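#' Radiomic feature name registry
#'
#' Enumerates every feature name the extractor emits for one MRI sequence.
#' Names render as `H-<seq>-<filter>-<family>-<stat>`, e.g.
#' `H-T2-waveletHHL-glcm-Idn`. Per sequence the registry holds 86 features
#' (18 first-order + 22 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM) on the original
#' image, the same 86 on each of 4 Laplacian-of-Gaussian scales (344) and on
#' each of 8 wavelet subbands (688), i.e. 1118 names in total. Integer ids are
#' assigned by deterministic enumeration order (filter, then family, then
#' statistic).
#'
#' @param sequence sequence tag, `"T2"` or `"MPR"`.
#' @param log_sigmas numeric vector of Laplacian-of-Gaussian scales in mm;
#'   filters are labelled `log<sigma>`.
#' @return data.frame with columns `name`, `sequence`, `filter`, `family`,
#'   `stat`, `id`.
#' @export
feature_registry <- function(sequence = "T2", log_sigmas = c(2, 3, 4, 5)) {
  stopifnot(sequence %in% c("T2", "MPR"))
  filters <- c("original",
               paste0("log", log_sigmas),
               paste0("wavelet", wavelet_subband_labels()))
  fam <- feature_panels()
  families <- rep(names(fam), lengths(fam))
  stats <- unlist(fam, use.names = FALSE)
  grid <- expand.grid(stat_i = seq_along(stats), filter = filters,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  # enumeration order: filter major, family/stat minor
  grid <- grid[order(match(grid$filter, filters), grid$stat_i), ]
  reg <- data.frame(
    sequence = sequence,
    filter = grid$filter,
    family = families[grid$stat_i],
    stat = stats[grid$stat_i],
    stringsAsFactors = FALSE
  )
  reg$name <- paste("H", sequence, reg$filter, reg$family, reg$stat, sep = "-")
  reg$id <- seq_len(nrow(reg))
  stopifnot(!anyDuplicated(reg$name))
  reg[, c("name", "sequence", "filter", "family", "stat", "id")]
}

# statistic names per feature family; sizes 18/22/16/16/14 sum to 86
feature_panels <- function() {
  list(
    firstorder = c("Energy", "Entropy", "Minimum", "Percentile10",
                   "Percentile90", "Maximum", "Mean", "Median",
                   "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                   "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                   "StandardDeviation", "Variance", "Skewness", "Kurtosis",
                   "Uniformity"),
    glcm = c("Autocorrelation", "JointAverage", "ClusterProminence",
             "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "JointEnergy", "JE", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
             "InverseVariance", "MaximumProbability", "SumEntropy",
             "SumSquares"),
    glrlm = c("SRE", "LRE", "GLN", "GLNN", "RLN", "RLNN", "RP", "GLV", "RV",
              "RE", "LGLRE", "HGLRE", "SRLGLE", "SRHGLE", "LRLGLE", "LRHGLE"),
    glszm = c("SAE", "LAE", "GLNU", "GLNUN", "SZN", "SZNN", "ZP", "GLV", "ZV",
              "ZE", "LGLZE", "HGLZE", "SALGLE", "SAHGLE", "LALGLE", "LAHGLE"),
    gldm = c("SDE", "LDE", "GLN", "DN", "DNN", "GLV", "DV", "DE", "LGLE",
             "HGLE", "SDLGLE", "SDHGLE", "LDLGLE", "LDHGLE")
  )
}

# subband letter order follows array axis order: first letter = axis 1
wavelet_subband_labels <- function() {
  g <- expand.grid(a3 = c("L", "H"), a2 = c("L", "H"), a1 = c("L", "H"),
                   stringsAsFactors = FALSE)
  paste0(g$a1, g$a2, g$a3)
}

#' Write the feature registry as JSON
#'
#' @param path output path.
#' @param sequences sequence tags to include.
#' @inheritParams feature_registry
#' @return invisibly, the combined registry data.frame.
#' @export
write_feature_registry <- function(path, sequences = c("T2", "MPR"),
                                   log_sigmas = c(2, 3, 4, 5)) {
  reg <- do.call(rbind, lapply(sequences, feature_registry, log_sigmas = log_sigmas))
  jsonlite::write_json(reg, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(reg)
}
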