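#' Read and write feature tables as CSV
#'
#' RFC 4180 CSV with header
#' `subject_id,diagnosis,scanner,age,sex,edss,duration,<feature...>`.
#' Feature names containing `-` are preserved verbatim.
#'
#' @param table feature table.
#' @param path file path.
#' @return `write_feature_table`: invisibly, the path;
#'   `read_feature_table`: the table.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(META_COLS, CLINICAL_COLS)
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("malformed feature table '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  tab
}

#' Write and read volumes as NIfTI-1
#'
#' Volumes are written as `.nii.gz` with the voxel spacing recorded in the
#' header; masks as unsigned 8-bit.
#'
#' @param volume 3-D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm.
#' @param mask write as uint8 (for binary masks).
#' @return `write_volume`: invisibly, the path; `read_volume`: 3-D array
#'   with attribute `spacing`.
#' @export
write_volume <- function(volume, path, spacing = c(1, 1, 1), mask = FALSE) {
  img <- RNifti::asNifti(volume, pixdim = spacing,
                         datatype = if (mask) "uint8" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "spacing") <- RNifti::pixdim(img)
  out
}

#' Write a volume pair (T2, MPRAGE, mask) as NIfTI files
#'
#' @param pair a `volume_pair`.
#' @param dir output directory (created if needed); files are
#'   `<id>_t2.nii.gz`, `<id>_mpr.nii.gz`, `<id>_mask.nii.gz`.
#' @return invisibly, the three paths.
#' @export
write_volume_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "volume_pair"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- pair$subject$id
  paths <- file.path(dir, paste0(id, c("_t2", "_mpr", "_mask"), ".nii.gz"))
  write_volume(pair$t2, paths[1], pair$spacing)
  write_volume(pair$mpr, paths[2], pair$spacing)
  write_volume(pair$mask, paths[3], pair$spacing, mask = TRUE)
  invisible(paths)
}

#' Run configuration for the full pipeline
#'
#' Bundles every tunable of the pipeline stages with a single root seed.
#' A persisted configuration re-runs to identical outputs.
#'
#' @param seed root seed; all stage seeds are derived from it.
#' @param synth a [synth_config()] (its seed is overridden by `seed`).
#' @param n_train training-set size for the split.
#' @param alpha univariate filter significance level.
#' @param modality_cap,fusion_cap selection caps.
#' @param sfs_trees,sfs_folds,sfs_repeats internal forward-selection scoring
#'   parameters (forest size, CV folds, repeated-CV count).
#' @param n_trees final model forest size.
#' @param k cross-validation folds.
#' @param B bootstrap resamples for test evaluation.
#' @param positive positive class label.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, synth = synth_config(), n_train = 86,
                       alpha = 0.05, modality_cap = 10, fusion_cap = 8,
                       sfs_trees = 200, sfs_folds = 5, sfs_repeats = 3,
                       n_trees = 500, k = 10, B = 1000, positive = "NMO") {
  synth$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), synth = synth, n_train = n_train,
                 alpha = alpha, modality_cap = modality_cap,
                 fusion_cap = fusion_cap, sfs_trees = sfs_trees,
                 sfs_folds = sfs_folds, sfs_repeats = sfs_repeats,
                 n_trees = n_trees, k = k, B = B, positive = positive),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `write_run_config`: invisibly, the path; `read_run_config`: the
#'   configuration.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x[!vapply(x, is.null, TRUE)], unclass_deep)
  } else x
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  synth <- do.call(synth_config, raw$synth)
  raw$synth <- NULL
  do.call(run_config, c(raw, list(synth = synth)))
}

#' Run the full table-level pipeline
#'
#' Simulate a cohort, split train/test, standardize against the training
#' statistics, select the multi-parametric phenotype, train the balanced
#' random forest, evaluate by stratified cross-validation and test-set
#' bootstrap, and explain every test subject with exact Shapley values.
#' All stage seeds derive from the configuration's root seed.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, the cohort CSV, phenotype
#'   JSON, evaluation reports and explanations are written there.
#' @param verbose print stage progress.
#' @return list with `cohort`, `train`, `test`, `selection`
#'   (`pyramid_phenotype`), `model`, `cv_report`, `test_report`,
#'   `explanations`, `importance`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  stage_seeds <- withr::with_seed(config$seed,
                                  sample.int(.Machine$integer.max, 6))
  say("simulating cohort")
  cohort <- generate_feature_cohort(config$synth)
  split <- split_train_test(cohort, config$n_train, seed = stage_seeds[1])
  train <- standardize(split$train, split$train)
  stats <- attr(train, "reference_stats")
  test <- standardize(split$test, split$train)
  say("selecting phenotype")
  selection <- pyramid_select(train, alpha = config$alpha,
                              modality_cap = config$modality_cap,
                              fusion_cap = config$fusion_cap,
                              seed = stage_seeds[2], n_trees = config$sfs_trees,
                              k = config$sfs_folds,
                              cv_repeats = config$sfs_repeats,
                              positive = config$positive)
  say("training model")
  model <- train_balanced_rf(train, selection$phenotype, seed = stage_seeds[3],
                             n_trees = config$n_trees,
                             positive = config$positive)
  say("evaluating")
  cv_report <- cross_validate(train, selection$phenotype, k = config$k,
                              seed = stage_seeds[4], n_trees = config$n_trees,
                              positive = config$positive)
  test_report <- bootstrap_evaluate(model, test, B = config$B,
                                    seed = stage_seeds[5])
  say("explaining")
  explanations <- explain_cohort(model, test, train)
  importance <- global_importance(explanations)
  result <- list(cohort = cohort, train = train, test = test,
                 selection = selection, model = model, cv_report = cv_report,
                 test_report = test_report, explanations = explanations,
                 importance = importance, reference_stats = stats,
                 config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_feature_table(cohort, file.path(out_dir, "cohort.csv"))
    write_phenotype(selection, file.path(out_dir, "phenotype.json"))
    write_eval_report(cv_report, file.path(out_dir, "cv_report.json"))
    write_eval_report(test_report, file.path(out_dir, "test_report.json"))
    write_explanations(explanations, file.path(out_dir, "explanations.json"))
    write_run_config(config, file.path(out_dir, "run_config.json"))
  }
  result
}
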