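#' Train a balanced random forest on a phenotype
#'
#' Probability random forest with per-tree balanced class resampling: each
#' tree is grown on an equal-count draw of `floor(0.632 * m)` subjects per
#' class without replacement, where `m` is the minority-class size and 0.632
#' is the expected unique fraction of a same-size bootstrap. Drawing without
#' replacement keeps the number of distinct points per class symmetric, which
#' makes predicted probabilities on class-uninformative data centre on 0.5
#' regardless of the training imbalance. Optional class weights act on the
#' split criterion; since the in-bag sample is already balanced they default
#' to 1.
#'
#' @param table feature table (training split).
#' @param features phenotype feature names (model inputs).
#' @param labels class labels (default `table$diagnosis`).
#' @param seed integer seed; identical seeds give identical forests.
#' @param n_trees number of trees.
#' @param positive positive class label (scores are its probability).
#' @param class_weights optional named per-class split weights.
#' @return object of class `mmrf_model`.
#' @export
train_balanced_rf <- function(table, features, labels = table$diagnosis,
                              seed = 1L, n_trees = 500, positive = "NMO",
                              class_weights = NULL) {
  if (!length(features)) stop("empty phenotype")
  if (inherits(features, "phenotype")) features <- features$features
  missing <- setdiff(features, names(table))
  if (length(missing)) stop("features not in table: ",
                            paste(head(missing), collapse = ", "))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  y <- factor(labels, levels = c(setdiff(unique(labels), positive), positive))
  x <- model_frame(table, features)
  n <- nrow(x)
  m <- min(table(y))
  s <- max(1L, floor(0.632 * m))
  cw <- if (is.null(class_weights)) rep(1, nlevels(y)) else
    as.numeric(class_weights[levels(y)])
  fit <- ranger::ranger(
    x = x, y = y, probability = TRUE, num.trees = n_trees,
    replace = FALSE, sample.fraction = rep(s / n, nlevels(y)),
    class.weights = cw, seed = as.integer(seed), num.threads = 1
  )
  structure(list(forest = fit, features = features, positive = positive,
                 levels = levels(y), prior = as.numeric(prop.table(table(y))),
                 seed = as.integer(seed)),
            class = "mmrf_model")
}

model_frame <- function(table, features) {
  x <- table[, features, drop = FALSE]
  if ("sex" %in% features) x$sex <- sex_numeric(x$sex)
  x
}

#' Predict positive-class probabilities
#'
#' @param object an `mmrf_model`.
#' @param newdata feature table or data.frame containing the phenotype
#'   columns.
#' @param ... unused.
#' @return numeric vector of positive-class scores in `[0, 1]`.
#' @export
predict.mmrf_model <- function(object, newdata, ...) {
  x <- model_frame(newdata, object$features)
  pr <- predict(object$forest, data = x, num.threads = 1)$predictions
  as.numeric(pr[, object$positive])
}

#' Classification metrics from scores
#'
#' AUC via the Mann-Whitney identity (ties counted 1/2); accuracy,
#' sensitivity and specificity at the given score threshold with respect to
#' the declared positive class.
#'
#' @param scores positive-class scores.
#' @param labels true class labels.
#' @param positive positive class label.
#' @param threshold score threshold for the hard prediction.
#' @return named vector `auc`, `accuracy`, `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(scores, labels, positive = "NMO", threshold = 0.5) {
  labels <- as.character(labels)
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  pred <- scores >= threshold
  c(auc = rank_auc(scores, labels, positive),
    accuracy = mean(pred == pos),
    sensitivity = sum(pred & pos) / sum(pos),
    specificity = sum(!pred & !pos) / sum(!pos))
}

#' Relative standard deviation of AUC
#'
#' The stability statistic `AUC_RSD = AUC_STD / AUC_MEAN`, with `AUC_STD`
#' the sample standard deviation (denominator n - 1) of the per-fold or
#' per-resample AUCs.
#'
#' @param aucs numeric vector of AUC values with positive mean.
#' @return scalar RSD (0 for a single value, by convention).
#' @export
auc_rsd <- function(aucs) {
  m <- mean(aucs)
  if (!is.finite(m) || m <= 0) stop("AUC mean must be positive")
  if (length(aucs) < 2) return(0)
  sd(aucs) / m
}

# assemble an eval_report from a metric matrix (resamples/folds x metrics)
eval_report <- function(metric_mat, positive, kind, n_resamples) {
  mm <- colMeans(metric_mat)
  ss <- apply(metric_mat, 2, sd)
  if (nrow(metric_mat) < 2) ss[] <- 0
  ci <- apply(metric_mat, 2, quantile, probs = c(0.025, 0.975), type = 7)
  structure(list(
    auc_mean = mm[["auc"]], auc_std = ss[["auc"]],
    auc_rsd = if (mm[["auc"]] > 0) ss[["auc"]] / mm[["auc"]] else NA_real_,
    metrics = data.frame(metric = colnames(metric_mat), mean = unname(mm),
                         sd = unname(ss), ci_low = unname(ci[1, ]),
                         ci_high = unname(ci[2, ]), row.names = NULL),
    per_resample = metric_mat,
    n_resamples = n_resamples, positive_class = positive, kind = kind,
    flagged = nrow(metric_mat) < 2
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s evaluation (%d resamples, positive class %s)\n",
              x$kind, x$n_resamples, x$positive_class))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-12s %.3f +/- %.3f  [%.3f, %.3f]\n", m$metric[i],
                m$mean[i], m$sd[i], m$ci_low[i], m$ci_high[i]))
  cat(sprintf("  AUC_RSD      %.4f\n", x$auc_rsd))
  invisible(x)
}

#' Stratified k-fold cross-validation of a balanced random forest
#'
#' Trains on k-1 folds, scores the held-out fold, computes per-fold metrics
#' at threshold 0.5 and reports the fold mean, sample SD and AUC_RSD.
#'
#' @param table feature table.
#' @param features phenotype feature names (or a `phenotype`).
#' @param k number of folds (at most the minority-class count).
#' @param seed integer seed for folds and forests.
#' @param n_trees trees per forest.
#' @param positive positive class label.
#' @return an `eval_report` (`kind = "cross-validation"`).
#' @export
cross_validate <- function(table, features, k = 10, seed = 1L, n_trees = 500,
                           positive = "NMO") {
  if (inherits(features, "phenotype")) features <- features$features
  labels <- as.character(table$diagnosis)
  withr::with_seed(as.integer(seed), {
    folds <- stratified_folds(labels, k)
    fit_seeds <- sample.int(.Machine$integer.max, k)
  })
  rows <- t(vapply(seq_len(k), function(f) {
    tr <- folds != f
    model <- train_balanced_rf(table[tr, , drop = FALSE], features,
                               labels = labels[tr], seed = fit_seeds[f],
                               n_trees = n_trees, positive = positive)
    sc <- predict(model, table[!tr, , drop = FALSE])
    compute_metrics(sc, labels[!tr], positive)
  }, c(auc = 0, accuracy = 0, sensitivity = 0, specificity = 0)))
  eval_report(rows, positive, "cross-validation", k)
}

#' Bootstrap evaluation on an independent test set
#'
#' Scores the test set once with the trained model, then draws `B`
#' class-stratified bootstrap resamples of the test subjects (resampling
#' within each class preserves both classes in every resample) and computes
#' the metric suite on each. Reports mean, sample SD, percentile 95% CI and
#' AUC_RSD across resamples.
#'
#' @param model an `mmrf_model`.
#' @param test_table independent test feature table.
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @param positive positive class label (defaults to the model's).
#' @return an `eval_report` (`kind = "bootstrap"`); attribute
#'   `point_estimate` holds the un-resampled metrics.
#' @export
bootstrap_evaluate <- function(model, test_table, B = 1000, seed = 1L,
                               positive = model$positive) {
  labels <- as.character(test_table$diagnosis)
  if (length(unique(labels)) < 2) stop("test set must contain both classes")
  scores <- predict(model, test_table)
  point <- compute_metrics(scores, labels, positive)
  idx_by_class <- split(seq_along(labels), labels)
  rows <- withr::with_seed(as.integer(seed), {
    t(vapply(seq_len(B), function(b) {
      idx <- unlist(lapply(idx_by_class, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      compute_metrics(scores[idx], labels[idx], positive)
    }, c(auc = 0, accuracy = 0, sensitivity = 0, specificity = 0)))
  })
  rep <- eval_report(rows, positive, "bootstrap", B)
  attr(rep, "point_estimate") <- point
  rep
}

#' Save / load a trained model
#'
#' The fitted forest is persisted with `saveRDS`; a JSON sidecar records the
#' phenotype, class levels, positive class, prior and seed so a run is
#' self-describing.
#'
#' @param model an `mmrf_model`.
#' @param path output path for the binary container; the sidecar is
#'   `<path>.json`.
#' @return `save_model`: invisibly, the path. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(list(features = model$features, levels = model$levels,
                            positive = model$positive, prior = model$prior,
                            seed = model$seed, format_version = 1L),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mmrf_model"))
  model
}

#' Serialize an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(
    kind = report$kind, positive_class = report$positive_class,
    n_resamples = report$n_resamples, auc_mean = report$auc_mean,
    auc_std = report$auc_std, auc_rsd = report$auc_rsd,
    metrics = report$metrics
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read an evaluation report from JSON
#'
#' @param path path written by [write_eval_report()].
#' @return list with the report fields (metrics as a data.frame).
#' @export
read_eval_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
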