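#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. The exact null distribution
#' is used when the combined sample size is at most 12 and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#' Two identical samples give p = 1 under this convention.
#'
#' @param x,y numeric samples, each non-empty.
#' @return list with `W` (rank-sum statistic of `x`) and `p`.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Scanner-robustness filter
#'
#' Keeps the features that show no significant intensity difference between
#' the 1.5T and 3T scanner strata (Wilcoxon rank-sum, two-sided). By default
#' the comparison is run within each diagnosis class separately and a feature
#' is removed if the scanner difference is significant in either class; this
#' avoids confounding by a class imbalance across scanners. Set
#' `by_class = FALSE` to compare pooled strata.
#'
#' @param table feature table.
#' @param alpha significance level; a feature is kept iff every comparison
#'   has p >= alpha.
#' @param features columns to screen (default: all radiomic and clinical
#'   feature columns).
#' @param by_class run the scanner comparison within each diagnosis class.
#' @return character vector of kept feature names; attribute `records` holds
#'   the per-feature univariate statistics data.frame.
#' @export
robustness_filter <- function(table, alpha = 0.05,
                              features = selectable_cols(table),
                              by_class = TRUE) {
  if (length(unique(table$scanner)) < 2)
    stop("robustness filtering needs both scanner strata")
  strata <- if (by_class) unique(table$diagnosis) else NA
  pmin_robust <- vapply(features, function(f) {
    vals <- sex_numeric(table[[f]])
    ps <- vapply(strata, function(cl) {
      sel <- if (is.na(cl)) rep(TRUE, nrow(table)) else table$diagnosis == cl
      a <- vals[sel & table$scanner == "1.5T"]
      b <- vals[sel & table$scanner == "3T"]
      if (!length(a) || !length(b)) return(1)
      rank_sum_test(a, b)$p
    }, 0)
    min(ps)
  }, 0)
  kept <- features[pmin_robust >= alpha]
  attr(kept, "records") <- data.frame(feature = features, p_robust = pmin_robust,
                                      row.names = NULL)
  kept
}

#' Class-relevance filter
#'
#' Keeps the features whose distribution differs significantly between the
#' MS and NMO classes (Wilcoxon rank-sum, two-sided, p < alpha).
#'
#' @inheritParams robustness_filter
#' @return character vector of kept feature names; attribute `records` holds
#'   per-feature p-values and univariate AUCs.
#' @export
relevance_filter <- function(table, alpha = 0.05,
                             features = selectable_cols(table)) {
  if (length(unique(table$diagnosis)) < 2)
    stop("relevance filtering needs both diagnosis classes")
  recs <- lapply(features, function(f) {
    vals <- sex_numeric(table[[f]])
    ht <- rank_sum_test(vals[table$diagnosis == "NMO"],
                        vals[table$diagnosis == "MS"])
    auc <- univariate_auc(vals, table$diagnosis)
    data.frame(feature = f, W = ht$W, p_class = ht$p, auc_uni = auc)
  })
  recs <- do.call(rbind, recs)
  kept <- features[recs$p_class < alpha]
  attr(kept, "records") <- recs
  kept
}

selectable_cols <- function(table) {
  c(intersect(CLINICAL_COLS, names(table)), radiomic_cols(table))
}

#' Univariate AUC of a single feature
#'
#' Mann-Whitney AUC (ties counted 1/2) of the feature for separating the two
#' classes, reported orientation-free as `max(AUC, 1 - AUC)`; the signed
#' value is in attribute `directed`.
#'
#' @param values feature values.
#' @param labels class labels.
#' @param positive positive class label.
#' @return AUC in `[0.5, 1]` with attribute `directed`.
#' @export
univariate_auc <- function(values, labels, positive = "NMO") {
  auc <- rank_auc(values, labels, positive)
  out <- max(auc, 1 - auc)
  attr(out, "directed") <- auc
  out
}

#' Random-forest sequential forward selection
#'
#' Greedy forward selection scored by stratified k-fold cross-validated AUC
#' of a balanced random forest: at each step the candidate that maximizes the
#' mean CV AUC of the currently selected set plus that candidate is added
#' (ties broken toward the earlier candidate in `candidates` order). The full
#' AUC trace up to `cap` features is recorded and the returned phenotype is
#' the prefix achieving the global trace maximum — the stopping point.
#'
#' @param table feature table (training split).
#' @param candidates candidate feature names.
#' @param cap maximum panel size, >= 1.
#' @param seed integer seed controlling fold assignment and forest growth.
#' @param n_trees trees per internal forest.
#' @param k internal cross-validation folds.
#' @param cv_repeats independent fold assignments averaged per score;
#'   repeated cross-validation lowers the variance of candidate comparisons,
#'   which greedy selection is sensitive to.
#' @param patience exploration stops once this many consecutive steps have
#'   failed to improve the trace maximum (the returned prefix is the argmax
#'   either way); `Inf` explores to `cap`.
#' @param positive positive class label.
#' @return object of class `phenotype`: list with `features` (selected
#'   prefix), `trace` (CV AUC after each step), `full_order` (all `cap`
#'   candidates in selection order), `cap`.
#' @export
rf_sfs <- function(table, candidates, cap = 8, seed = 1L, n_trees = 200,
                   k = 5, cv_repeats = 3, patience = 3, positive = "NMO") {
  if (!length(candidates)) stop("no candidate features")
  if (cap < 1) stop("cap must be >= 1")
  labels <- table$diagnosis
  cap <- min(cap, length(candidates))
  withr::with_seed(as.integer(seed), {
    folds <- lapply(seq_len(cv_repeats), function(i)
      stratified_folds(labels, k))
    fit_seeds <- sample.int(.Machine$integer.max, cap * length(candidates))
  })
  selected <- character(0)
  trace <- numeric(0)
  si <- 0L
  remaining <- candidates
  for (step in seq_len(cap)) {
    scores <- rep(NA_real_, length(remaining))
    for (ci in seq_along(remaining)) {
      si <- si + 1L
      feats <- c(selected, remaining[ci])
      scores[ci] <- cv_auc(table, feats, labels, folds, n_trees,
                           fit_seeds[si], positive)
    }
    best <- which.max(scores)            # first maximum: earlier candidate wins
    selected <- c(selected, remaining[best])
    trace <- c(trace, scores[best])
    remaining <- remaining[-best]
    if (step - which.max(trace) >= patience) break
  }
  stop_at <- which.max(trace)
  structure(list(features = selected[seq_len(stop_at)], trace = trace,
                 full_order = selected, cap = cap, positive = positive),
            class = "phenotype")
}

# mean fold AUC of a balanced RF over pre-assigned (repeated) folds
cv_auc <- function(table, feats, labels, folds_list, n_trees, seed, positive) {
  if (!is.list(folds_list)) folds_list <- list(folds_list)
  aucs <- unlist(lapply(folds_list, function(folds)
    vapply(sort(unique(folds)), function(f) {
      tr <- folds != f
      model <- train_balanced_rf(table[tr, , drop = FALSE], feats,
                                 labels = labels[tr], seed = seed,
                                 n_trees = n_trees, positive = positive)
      sc <- predict(model, table[!tr, , drop = FALSE])
      rank_auc(sc, labels[!tr], positive)
    }, 0)))
  mean(aucs)
}

#' Multi-level (pyramid) phenotype selection
#'
#' The full selection pipeline: (1) scanner-robustness filter, (2) class-
#' relevance filter, (3) random-forest sequential forward selection within
#' each modality (T2, MPR, clinical) yielding three preliminary phenotypes,
#' (4) a fusion-level forward selection over the union of the three,
#' yielding the multi-parametric phenotype.
#'
#' @param table feature table (training split).
#' @param alpha significance level for both univariate filters.
#' @param modality_cap per-modality panel cap for step (3).
#' @param fusion_cap panel cap for the fusion step (4).
#' @param seed integer root seed.
#' @param n_trees,k internal forest size and CV folds for scoring.
#' @param positive positive class label.
#' @return object of class `pyramid_phenotype`: the final `phenotype` plus
#'   all intermediate artifacts (`robust`, `relevant`, `preliminary`,
#'   `records`).
#' @export
pyramid_select <- function(table, alpha = 0.05, modality_cap = 10,
                           fusion_cap = 8, seed = 1L, n_trees = 200, k = 5,
                           cv_repeats = 3, patience = 3, positive = "NMO") {
  robust <- robustness_filter(table, alpha)
  relevant <- relevance_filter(table, alpha, features = robust)
  modality <- function(f) {
    ifelse(f %in% CLINICAL_COLS, "clinical",
           ifelse(startsWith(f, "H-T2-"), "T2", "MPR"))
  }
  withr::with_seed(as.integer(seed),
                   seeds <- sample.int(.Machine$integer.max, 4))
  prelim <- list()
  mods <- c("T2", "MPR", "clinical")
  for (i in seq_along(mods)) {
    cand <- relevant[modality(relevant) == mods[i]]
    prelim[[mods[i]]] <- if (length(cand))
      rf_sfs(table, cand, cap = modality_cap, seed = seeds[i],
             n_trees = n_trees, k = k, cv_repeats = cv_repeats,
             patience = patience, positive = positive)
    else NULL
  }
  fused_cand <- unlist(lapply(prelim, function(p) p$features),
                       use.names = FALSE)
  if (!length(fused_cand))
    stop("no features survived filtering and per-modality selection")
  final <- rf_sfs(table, fused_cand, cap = fusion_cap, seed = seeds[4],
                  n_trees = n_trees, k = k, cv_repeats = cv_repeats,
                  patience = patience, positive = positive)
  structure(list(
    phenotype = final,
    preliminary = prelim,
    robust = as.character(robust),
    relevant = as.character(relevant),
    records = list(robustness = attr(robust, "records"),
                   relevance = attr(relevant, "records"))
  ), class = "pyramid_phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  cat("Phenotype (", length(x$features), " features, trace max CV AUC ",
      sprintf("%.3f", max(x$trace)), "):\n", sep = "")
  cat(paste0("  ", x$features, collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize a phenotype (with selection trace) as JSON
#'
#' @param phenotype a `phenotype` or `pyramid_phenotype`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_phenotype <- function(phenotype, path) {
  if (inherits(phenotype, "pyramid_phenotype")) {
    obj <- list(features = phenotype$phenotype$features,
                trace = phenotype$phenotype$trace,
                preliminary = lapply(phenotype$preliminary,
                                     function(p) if (is.null(p)) list() else
                                       list(features = p$features, trace = p$trace)),
                n_robust = length(phenotype$robust),
                n_relevant = length(phenotype$relevant))
  } else {
    obj <- list(features = phenotype$features, trace = phenotype$trace)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
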