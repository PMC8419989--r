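#' Extraction configuration
#'
#' @param bin_width fixed bin width for gray-level discretization.
#' @param log_sigmas Laplacian-of-Gaussian scales in mm.
#' @param gldm_alpha gray-level tolerance for the dependence matrix.
#' @return list of class `extract_config`.
#' @export
extract_config <- function(bin_width = 25, log_sigmas = c(2, 3, 4, 5),
                           gldm_alpha = 0) {
  stopifnot(bin_width > 0, all(log_sigmas > 0))
  structure(list(bin_width = bin_width, log_sigmas = log_sigmas,
                 gldm_alpha = gldm_alpha), class = "extract_config")
}

# the 86-feature panel (18 first-order + 68 texture) on one image + mask
extract_panel <- function(volume, mask, config) {
  mask <- array(as.logical(mask), dim(mask))
  vals <- volume[mask]
  parts <- list(
    firstorder = first_order_features(vals, config$bin_width),
    glcm = glcm_features(volume, mask, config$bin_width),
    glrlm = glrlm_features(volume, mask, config$bin_width),
    glszm = glszm_features(volume, mask, config$bin_width),
    gldm = gldm_features(volume, mask, config$bin_width, alpha = config$gldm_alpha)
  )
  unlist(lapply(names(parts), function(fam)
    stats::setNames(as.numeric(parts[[fam]]),
                    paste(fam, names(parts[[fam]]), sep = "-"))))
}

# crop volume+mask to the mask bounding box with margin (speeds texture passes)
crop_to_mask <- function(volume, mask, margin = 1L) {
  mask <- array(as.logical(mask), dim(mask))
  w <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  rng <- lapply(1:3, function(a)
    max(1L, min(w[, a]) - margin):min(d[a], max(w[, a]) + margin))
  list(volume = volume[rng[[1]], rng[[2]], rng[[3]], drop = FALSE],
       mask = mask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE])
}

#' Extract the full radiomic signature from a volume pair
#'
#' Computes, for each sequence (T2 and T1-MPRAGE), the 86-feature panel on
#' the original image, on each Laplacian-of-Gaussian scale and on each of the
#' 8 wavelet subbands — 1118 features per sequence, 2236 in total — restricted
#' to the lesion mask, plus the 4 clinical covariates when the pair carries a
#' subject record. Feature names follow [feature_registry()].
#'
#' @param pair a `volume_pair` (see [generate_volume_cohort()]).
#' @param config an [extract_config()].
#' @return named numeric vector (2236 radiomic values, plus `age`, `sex`,
#'   `edss`, `duration` when available).
#' @export
extract_all <- function(pair, config = extract_config()) {
  stopifnot(inherits(pair, "volume_pair"))
  seqs <- list(T2 = pair$t2, MPR = pair$mpr)
  out <- list()
  for (sq in names(seqs)) {
    vol <- seqs[[sq]]
    cr <- crop_to_mask(vol, pair$mask, margin = 2L)
    vals <- list()
    vals[["original"]] <- extract_panel(cr$volume, cr$mask, config)
    for (s in config$log_sigmas) {
      lg <- log_filter(vol, s, pair$spacing)
      crl <- crop_to_mask(lg, pair$mask, margin = 0L)
      vals[[paste0("log", s)]] <- extract_panel(crl$volume, crl$mask, config)
    }
    wb <- wavelet_subbands(cr$volume)
    wmask <- downsample_mask(cr$mask)
    for (lab in names(wb))
      vals[[paste0("wavelet", lab)]] <- extract_panel(wb[[lab]], wmask, config)
    for (f in names(vals)) {
      v <- vals[[f]]
      names(v) <- paste("H", sq, f, names(v), sep = "-")
      out[[paste(sq, f)]] <- v
    }
  }
  rec <- unlist(out, use.names = TRUE)
  names(rec) <- sub("^[^.]*\\.", "", names(rec))
  reg <- c(feature_registry("T2", config$log_sigmas)$name,
           feature_registry("MPR", config$log_sigmas)$name)
  rec <- rec[reg]                            # registry order, asserts coverage
  stopifnot(!anyNA(names(rec)))
  if (!is.null(pair$subject)) {
    subj <- pair$subject
    rec <- c(rec, age = subj$age, sex = sex_numeric(subj$sex),
             edss = subj$edss, duration = subj$duration)
  }
  rec
}

#' Extract a feature table from a cohort of volume pairs
#'
#' @param pairs list of `volume_pair` objects.
#' @param config an [extract_config()].
#' @return a feature table data.frame (one row per subject) with metadata
#'   columns `subject_id`, `diagnosis`, `scanner` followed by clinical
#'   covariates and radiomic features.
#' @export
extract_cohort <- function(pairs, config = extract_config()) {
  recs <- lapply(pairs, extract_all, config = config)
  mat <- do.call(rbind, recs)
  meta <- data.frame(
    subject_id = vapply(pairs, function(p) p$subject$id, ""),
    diagnosis = vapply(pairs, function(p) p$subject$diagnosis, ""),
    scanner = vapply(pairs, function(p) p$subject$scanner, ""),
    stringsAsFactors = FALSE
  )
  clin <- c("age", "sex", "edss", "duration")
  tab <- cbind(meta, as.data.frame(mat[, c(clin, setdiff(colnames(mat), clin)),
                                       drop = FALSE]))
  rownames(tab) <- NULL
  tab
}

#' Standardize feature columns against reference statistics
#'
#' Z-scores every radiomic and clinical feature column using the reference
#' table's column means and standard deviations (sample SD). Columns with
#' zero reference SD are mapped to 0 and flagged in the `constant_columns`
#' attribute. When `reference` is omitted the table is its own reference.
#'
#' @param table feature table to transform.
#' @param reference feature table providing the statistics (e.g. the training
#'   split); must contain the same feature columns.
#' @return standardized table; attributes `standardized`, `reference_stats`
#'   (data.frame of mean/SD per column) and `constant_columns`.
#' @export
standardize <- function(table, reference = table) {
  cols <- feature_cols(table)
  clin <- intersect(CLINICAL_COLS, names(table))
  cols <- c(clin, cols)
  if (!all(cols %in% names(reference)))
    stop("reference is missing columns: ",
         paste(head(setdiff(cols, names(reference))), collapse = ", "))
  mu <- vapply(reference[cols], function(x) mean(sex_numeric(x)), 0)
  sdv <- vapply(reference[cols], function(x) sd(sex_numeric(x)), 0)
  const <- cols[sdv == 0]
  out <- table
  for (i in seq_along(cols)) {
    x <- sex_numeric(table[[cols[i]]])
    out[[cols[i]]] <- if (sdv[i] == 0) rep(0, length(x)) else (x - mu[i]) / sdv[i]
  }
  attr(out, "standardized") <- TRUE
  attr(out, "reference_stats") <- data.frame(column = cols, mean = mu, sd = sdv,
                                             row.names = NULL)
  attr(out, "constant_columns") <- const
  out
}

#' Invert a standardization using its reference statistics
#'
#' @param table a table produced by [standardize()].
#' @param stats the `reference_stats` attribute of the standardized table.
#' @return table on the original scale (constant columns restored to the
#'   reference mean).
#' @export
unstandardize <- function(table, stats = attr(table, "reference_stats")) {
  if (is.null(stats)) stop("no reference statistics available")
  out <- table
  for (i in seq_len(nrow(stats))) {
    cl <- stats$column[i]
    out[[cl]] <- table[[cl]] * stats$sd[i] + stats$mean[i]
  }
  attr(out, "standardized") <- NULL
  out
}
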