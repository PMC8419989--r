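#' Synthetic cohort configuration
#'
#' Defines a reproducible two-class (MS/NMO), two-scanner (1.5T/3T) synthetic
#' cohort. Defaults mirror the study design this package targets: cell sizes
#' 38/30 (3T) and 40/8 (1.5T) for MS/NMO, 1118 radiomic features per MRI
#' sequence, and clinical covariates drawn from the published group moments
#' (age, sex, EDSS, disease duration).
#'
#' @param n_ms_3t,n_nmo_3t,n_ms_15t,n_nmo_15t subjects per class and scanner.
#' @param n_features radiomic features generated per modality (T2 and MPR) in
#'   table mode.
#' @param n_discriminative number of planted class-informative features,
#'   split as evenly as possible between the two modalities.
#' @param effect_size standardized mean difference (Cohen's d) of planted
#'   features between classes.
#' @param n_scanner_shifted number of features carrying an additive scanner
#'   batch shift (disjoint from the planted set).
#' @param shift_size batch shift between scanner strata in SD units.
#' @param scale_shift multiplicative SD ratio applied to shifted features in
#'   the 1.5T stratum (1 = location shift only).
#' @param block_correlation equicorrelation within consecutive blocks of
#'   `block_size` features, in `[0, 1)`.
#' @param block_size features per correlated block.
#' @param volume_dim edge lengths (voxels) of image-mode volumes.
#' @param spacing voxel spacing in mm.
#' @param lesion_count_range integer range of lesions per subject.
#' @param lesion_radius_range_mm lesion semi-axis range in mm.
#' @param lesion_texture_amplitude amplitude of the within-lesion texture
#'   field (0 = constant lesion intensity).
#' @param noise_sd image-mode acquisition noise SD.
#' @param clinical_null draw the clinical covariates of both classes from the
#'   MS moments, removing every clinical class signal (for null-calibration
#'   experiments).
#' @param clinical_effect_size optional standardized EDSS class separation
#'   (Cohen's d). `NULL` (default) keeps the published group moments, whose
#'   implied separation is about 0.58; a numeric value re-centres the NMO
#'   EDSS distribution at `MS mean + d * SD` for planted-signal experiments
#'   that require a calibrated clinical effect.
#' @param seed integer root seed; identical configs generate identical
#'   cohorts.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_ms_3t = 38, n_nmo_3t = 30, n_ms_15t = 40,
                         n_nmo_15t = 8, n_features = 1118,
                         n_discriminative = 10, effect_size = 1.2,
                         n_scanner_shifted = 100, shift_size = 1,
                         scale_shift = 1, block_correlation = 0.3,
                         block_size = 10, volume_dim = c(24, 24, 24),
                         spacing = c(1, 1, 1), lesion_count_range = c(1, 3),
                         lesion_radius_range_mm = c(2.5, 5),
                         lesion_texture_amplitude = 40, noise_sd = 5,
                         clinical_null = FALSE, clinical_effect_size = NULL,
                         seed = 1L) {
  if (!is.null(clinical_effect_size)) {
    clinical_effect_size <- if (!length(clinical_effect_size)) NULL
    else as.numeric(clinical_effect_size)
  }
  cfg <- list(n_ms_3t = n_ms_3t, n_nmo_3t = n_nmo_3t, n_ms_15t = n_ms_15t,
              n_nmo_15t = n_nmo_15t, n_features = n_features,
              n_discriminative = n_discriminative, effect_size = effect_size,
              n_scanner_shifted = n_scanner_shifted, shift_size = shift_size,
              scale_shift = scale_shift, block_correlation = block_correlation,
              block_size = block_size, volume_dim = volume_dim,
              spacing = spacing, lesion_count_range = lesion_count_range,
              lesion_radius_range_mm = lesion_radius_range_mm,
              lesion_texture_amplitude = lesion_texture_amplitude,
              noise_sd = noise_sd, clinical_null = isTRUE(clinical_null),
              clinical_effect_size = clinical_effect_size,
              seed = as.integer(seed))
  counts <- c(n_ms_3t, n_nmo_3t, n_ms_15t, n_nmo_15t)
  if (any(counts < 0) || sum(counts) == 0)
    stop("subject counts must be non-negative with at least one subject")
  if (n_discriminative > 2 * n_features)
    stop("n_discriminative exceeds the number of features")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (block_correlation < 0 || block_correlation >= 1)
    stop("block_correlation must be in [0, 1)")
  structure(cfg, class = "synth_config")
}

# clinical covariate moments (per-class) used by the generator:
# age ~ Normal, EDSS ~ Normal truncated to [0,10] rounded to 0.5 steps,
# sex ~ Bernoulli(male), duration (months) ~ log-normal matched to mean/SD
clinical_moments <- function() {
  list(MS = list(age = c(36.5, 10.0), edss = c(2.9, 1.5), male = 27 / 78,
                 duration = c(56.8, 54.1)),
       NMO = list(age = c(40.9, 11.7), edss = c(3.8, 1.6), male = 7 / 38,
                  duration = c(66.4, 58.4)))
}

# subject roster with clinical covariates for one config (RNG must be seeded
# by the caller)
draw_subjects <- function(config) {
  cells <- data.frame(
    diagnosis = c("MS", "NMO", "MS", "NMO"),
    scanner = c("3T", "3T", "1.5T", "1.5T"),
    n = c(config$n_ms_3t, config$n_nmo_3t, config$n_ms_15t, config$n_nmo_15t),
    stringsAsFactors = FALSE
  )
  mom <- clinical_moments()
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    n <- cells$n[i]
    if (n == 0) return(NULL)
    m <- mom[[if (isTRUE(config$clinical_null)) "MS" else cells$diagnosis[i]]]
    if (!is.null(config$clinical_effect_size) && !isTRUE(config$clinical_null)) {
      base <- mom$MS$edss
      m$edss <- if (cells$diagnosis[i] == "NMO")
        c(base[1] + config$clinical_effect_size * base[2], base[2]) else base
    }
    edss <- rnorm(n, m$edss[1], m$edss[2])
    edss <- round(pmin(pmax(edss, 0), 10) * 2) / 2
    mlog <- log(1 + (m$duration[2] / m$duration[1])^2)
    dur <- rlnorm(n, log(m$duration[1]) - mlog / 2, sqrt(mlog))
    data.frame(
      diagnosis = cells$diagnosis[i], scanner = cells$scanner[i],
      age = pmax(rnorm(n, m$age[1], m$age[2]), 18),
      sex = ifelse(rbinom(n, 1, m$male) == 1, "male", "female"),
      edss = edss, duration = dur, stringsAsFactors = FALSE
    )
  })
  subj <- do.call(rbind, rows)
  subj$subject_id <- sprintf("S%03d", seq_len(nrow(subj)))
  subj[, c("subject_id", "diagnosis", "scanner", "age", "sex", "edss",
           "duration")]
}

#' Generate a table-level synthetic cohort
#'
#' Draws a subjects-by-features matrix with the naming convention of
#' [feature_registry()]: `n_features` per modality (T2 and MPR) plus the four
#' clinical covariates. Base features are standard normal with optional
#' block equicorrelation; planted discriminative features are shifted by
#' +/- `effect_size`/2 between classes; scanner-shifted features are shifted
#' by +/- `shift_size`/2 between scanner strata (and rescaled by
#' `scale_shift` in the 1.5T stratum). Planted and shifted feature names are
#' attached as attributes `planted` and `scanner_shifted`.
#'
#' @param config a [synth_config()].
#' @return feature table data.frame with columns `subject_id`, `diagnosis`,
#'   `scanner`, `age`, `sex`, `edss`, `duration`, then radiomic features.
#' @export
generate_feature_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_ms_3t + config$n_ms_15t == 0 ||
      config$n_nmo_3t + config$n_nmo_15t == 0)
    stop("each diagnosis class needs at least one subject")
  if (config$n_features > 1118)
    stop("table mode supports at most 1118 features per modality (the size ",
         "of the per-sequence feature registry)")
  withr::with_seed(config$seed, {
    subj <- draw_subjects(config)
    n <- nrow(subj)
    fnames <- c(head(feature_registry("T2")$name, config$n_features),
                head(feature_registry("MPR")$name, config$n_features))
    p <- length(fnames)
    rho <- config$block_correlation
    x <- matrix(rnorm(n * p), n, p)
    if (rho > 0) {
      nblock <- ceiling(p / config$block_size)
      z <- matrix(rnorm(n * nblock), n, nblock)
      bid <- rep(seq_len(nblock), each = config$block_size)[seq_len(p)]
      x <- sqrt(rho) * z[, bid, drop = FALSE] + sqrt(1 - rho) * x
    }
    colnames(x) <- fnames
    # planted class effects, split across modalities
    n_t2 <- ceiling(config$n_discriminative / 2)
    n_mpr <- config$n_discriminative - n_t2
    planted <- c(sample(fnames[seq_len(config$n_features)],
                        min(n_t2, config$n_features)),
                 sample(fnames[config$n_features + seq_len(config$n_features)],
                        min(n_mpr, config$n_features)))
    sgn <- ifelse(subj$diagnosis == "NMO", 0.5, -0.5)
    for (f in planted) x[, f] <- x[, f] + config$effect_size * sgn
    # scanner batch effects on a disjoint feature set
    pool <- setdiff(fnames, planted)
    shifted <- sample(pool, min(config$n_scanner_shifted, length(pool)))
    ssgn <- ifelse(subj$scanner == "1.5T", 0.5, -0.5)
    for (f in shifted) {
      x[, f] <- x[, f] * ifelse(subj$scanner == "1.5T", config$scale_shift, 1)
      x[, f] <- x[, f] + config$shift_size * ssgn
    }
    tab <- cbind(subj, as.data.frame(x, optional = TRUE))
    rownames(tab) <- NULL
    attr(tab, "planted") <- planted
    attr(tab, "scanner_shifted") <- shifted
    tab
  })
}

#' Generate an image-level synthetic cohort
#'
#' Builds, per subject, co-registered T2 and T1-MPRAGE volumes on a shared
#' grid with ellipsoidal lesions inside an ellipsoidal brain envelope and an
#' exact binary lesion mask. Diagnosis class is encoded as a within-lesion
#' texture difference (different spatial autocorrelation length of the lesion
#' intensity field: MS lesions have fine-grained, NMO coarse-grained
#' texture); scanner is encoded as a global intensity gain and a noise-SD
#' change.
#'
#' @param config a [synth_config()].
#' @return list of `volume_pair` objects; each has elements `t2`, `mpr`,
#'   `mask`, `spacing`, `subject`.
#' @export
generate_volume_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  dimv <- config$volume_dim
  if (max(config$lesion_radius_range_mm) + 1 >=
      min(dimv * config$spacing) / 2)
    stop("lesion radius exceeds volume extent")
  withr::with_seed(config$seed, {
    subj <- draw_subjects(config)
    lapply(seq_len(nrow(subj)), function(i)
      simulate_volume_pair(subj[i, ], config))
  })
}

simulate_volume_pair <- function(subject, config) {
  dimv <- config$volume_dim
  sp <- config$spacing
  ctr <- (dimv + 1) / 2
  coords <- list(x = (seq_len(dimv[1]) - ctr[1]) * sp[1],
                 y = (seq_len(dimv[2]) - ctr[2]) * sp[2],
                 z = (seq_len(dimv[3]) - ctr[3]) * sp[3])
  semi <- dimv * sp * 0.45
  dist2 <- outer(outer((coords$x / semi[1])^2, (coords$y / semi[2])^2, `+`),
                 (coords$z / semi[3])^2, `+`)
  brain <- dist2 <= 1
  gain <- if (subject$scanner == "1.5T") 1.2 else 1
  noise_sd <- config$noise_sd * if (subject$scanner == "1.5T") 1.5 else 1
  t2 <- array(ifelse(brain, 100, 0), dimv)
  mpr <- array(ifelse(brain, 140, 0), dimv)
  mask <- array(FALSE, dimv)
  n_les <- sample(seq(config$lesion_count_range[1],
                      config$lesion_count_range[2]), 1)
  # class texture: spatial smoothing scale of the lesion intensity field
  smooth_sigma <- if (subject$diagnosis == "NMO") 1.6 else 0.6
  texture <- if (config$lesion_texture_amplitude > 0) {
    fld <- array(rnorm(prod(dimv)), dimv)
    fld <- gauss_smooth(fld, smooth_sigma, sp)
    fld <- fld / max(sd(fld), 1e-12) * config$lesion_texture_amplitude
    fld
  } else array(0, dimv)
  for (l in seq_len(n_les)) {
    r <- runif(3, config$lesion_radius_range_mm[1],
               config$lesion_radius_range_mm[2])
    half <- dimv * sp / 2
    lim <- half - r - 1                     # keep the lesion inside the grid
    cen <- c(runif(1, -lim[1], lim[1]), runif(1, -lim[2], lim[2]),
             runif(1, -lim[3], lim[3]))
    d2 <- outer(outer(((coords$x - cen[1]) / r[1])^2,
                      ((coords$y - cen[2]) / r[2])^2, `+`),
                ((coords$z - cen[3]) / r[3])^2, `+`)
    mask <- mask | (d2 <= 1)
  }
  if (!any(mask)) {
    ci <- as.integer(round(ctr))
    mask[ci[1], ci[2], ci[3]] <- TRUE
  }
  t2[mask] <- 160 + texture[mask]
  mpr[mask] <- 90 - 0.5 * texture[mask]
  if (noise_sd > 0) {
    t2 <- t2 + array(rnorm(prod(dimv), 0, noise_sd), dimv)
    mpr <- mpr + array(rnorm(prod(dimv), 0, noise_sd), dimv)
  }
  subj <- as.list(subject)
  subj$id <- subject$subject_id
  structure(list(t2 = t2 * gain, mpr = mpr * gain,
                 mask = array(as.integer(mask), dimv), spacing = sp,
                 subject = subj),
            class = "volume_pair")
}

# separable Gaussian smoothing (unit-sum taps, replicate padding)
gauss_smooth <- function(a, sigma, spacing) {
  for (ax in 1:3) {
    r <- max(1L, ceiling(3 * sigma / spacing[ax]))
    x <- (-r:r) * spacing[ax]
    g <- exp(-x^2 / (2 * sigma^2))
    a <- conv_axis(a, g / sum(g), ax)
  }
  a
}

#' Random train/test split of a feature table
#'
#' @param table feature table.
#' @param n_train number of training subjects, `0 < n_train < nrow(table)`.
#' @param seed integer seed; identical seeds give identical membership.
#' @return list with `train` and `test` tables; each carries a
#'   `class_balance` attribute (diagnosis counts).
#' @export
split_train_test <- function(table, n_train, seed = 1L) {
  n <- nrow(table)
  if (!(n_train > 0 && n_train < n))
    stop("n_train must be strictly between 0 and ", n)
  withr::with_seed(as.integer(seed), {
    idx <- sample(n, n_train)
  })
  train <- table[sort(idx), , drop = FALSE]
  test <- table[setdiff(seq_len(n), idx), , drop = FALSE]
  attr(train, "class_balance") <- table(train$diagnosis)
  attr(test, "class_balance") <- table(test$diagnosis)
  list(train = train, test = test)
}
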