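#' Exact interventional Shapley explanation of one prediction
#'
#' Enumerates all 2^M coalitions of the model's M input features. The value
#' of a coalition S is the model's mean prediction over the background table
#' with the columns in S replaced by the explained record's values
#' (interventional/marginal value function). Shapley contributions are exact
#' up to this background average; local accuracy
#' `base_value + sum(phi) = prediction` holds identically because the empty
#' and full coalitions are evaluated directly.
#'
#' @param model an `mmrf_model`, or a function mapping a data.frame of
#'   feature columns to a numeric score vector.
#' @param record single-row data.frame with the feature columns (extra
#'   columns ignored).
#' @param background non-empty data.frame of reference records (typically
#'   the training table).
#' @param features feature names; defaults to the model's phenotype (required
#'   when `model` is a plain function).
#' @return object of class `explanation`: list with `subject_id`,
#'   `base_value`, `phi` (named, probability units), `percent`
#'   (`100*|phi|/sum|phi|`), `prediction`.
#' @export
exact_shapley <- function(model, record, background,
                          features = model$features) {
  f <- score_fun(model)
  M <- length(features)
  if (M < 1) stop("no features to attribute")
  if (M > 16) stop("exact enumeration supports at most 16 features, got ", M)
  if (!nrow(background)) stop("background table is empty")
  stopifnot(nrow(record) == 1)
  v <- coalition_values(f, record, background, features)
  phi <- phi_from_values(v, M)
  names(phi) <- features
  prediction <- v[[2^M]]                 # full coalition: background-free
  base <- v[[1]]
  new_explanation(record, base, phi, prediction)
}

score_fun <- function(model) {
  if (is.function(model)) model
  else function(d) predict(model, d)
}

# value of every coalition (bitmask order 0 .. 2^M - 1), one batched predict
coalition_values <- function(f, record, background, features) {
  M <- length(features)
  nb <- nrow(background)
  bg <- background[, features, drop = FALSE]
  if ("sex" %in% features) bg$sex <- sex_numeric(bg$sex)
  rec <- model_frame(record, features)
  blocks <- vector("list", 2^M)
  for (c_i in 0:(2^M - 1)) {
    blk <- bg
    in_s <- bitwAnd(c_i, bitwShiftL(1L, 0:(M - 1))) != 0L
    for (j in which(in_s)) blk[[j]] <- rep(rec[[j]], nb)
    blocks[[c_i + 1]] <- blk
  }
  big <- do.call(rbind, blocks)
  sc <- f(big)
  rowsum_means <- rowsum(sc, rep(seq_len(2^M), each = nb)) / nb
  as.numeric(rowsum_means)
}

# Shapley combination of cached coalition values
phi_from_values <- function(v, M) {
  w <- vapply(0:(M - 1), function(s)
    exp(lfactorial(s) + lfactorial(M - 1 - s) - lfactorial(M)), 0)
  phi <- numeric(M)
  sizes <- vapply(0:(2^M - 1), function(c_i) sum(bitwAnd(c_i, bitwShiftL(1L, 0:(M - 1))) != 0L), 0L)
  for (j in seq_len(M)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(2^M - 1), bit) == 0L) - 1L
    phi[j] <- sum(w[sizes[without + 1L] + 1L] *
                    (v[without + bit + 1L] - v[without + 1L]))
  }
  phi
}

new_explanation <- function(record, base, phi, prediction) {
  pct <- if (sum(abs(phi)) > 0) 100 * abs(phi) / sum(abs(phi)) else
    rep(NA_real_, length(phi))
  structure(list(
    subject_id = if ("subject_id" %in% names(record)) record$subject_id else NA_character_,
    base_value = base, phi = phi,
    percent = stats::setNames(pct, names(phi)),
    prediction = prediction
  ), class = "explanation")
}

#' Permutation-sampling Shapley estimator
#'
#' Monte-Carlo estimate of the same interventional Shapley values: for each
#' sampled feature ordering, features are added one at a time and the
#' marginal change in coalition value is credited to the added feature.
#' Coalition values are cached (there are at most 2^M), so the estimator
#' converges to the exhaustive computation as `n_perm` grows — used as an
#' independent cross-check of [exact_shapley()].
#'
#' @inheritParams exact_shapley
#' @param n_perm number of sampled permutations.
#' @param seed integer seed.
#' @return an `explanation`.
#' @export
permutation_shapley <- function(model, record, background, n_perm = 10000,
                                seed = 1L, features = model$features) {
  f <- score_fun(model)
  M <- length(features)
  if (M > 25) stop("coalition cache requires a small feature count")
  v <- coalition_values(f, record, background, features)
  phi <- numeric(M)
  withr::with_seed(as.integer(seed), {
    for (p in seq_len(n_perm)) {
      ord <- sample.int(M)
      mask <- 0L
      for (j in ord) {
        nxt <- bitwOr(mask, bitwShiftL(1L, j - 1L))
        phi[j] <- phi[j] + v[nxt + 1L] - v[mask + 1L]
        mask <- nxt
      }
    }
  })
  phi <- phi / n_perm
  names(phi) <- features
  new_explanation(record, v[[1]], phi, v[[2^M]])
}

#' Contribution percentages from Shapley values
#'
#' `percent_i = 100 * |phi_i| / sum(|phi|)` — the absolute-value convention,
#' so mixed-sign contributions still yield positive percentages summing to
#' 100.
#'
#' @param phi numeric vector of Shapley contributions, not all zero.
#' @return percentages summing to 100.
#' @export
contribution_percent <- function(phi) {
  tot <- sum(abs(phi))
  if (tot == 0) stop("all contributions are zero")
  100 * abs(phi) / tot
}

#' Model-level feature importance from a set of explanations
#'
#' Mean absolute Shapley contribution per feature across subjects, ranked
#' descending; the per-subject contribution matrix is attached for
#' beeswarm-style reporting.
#'
#' @param explanations list of `explanation` objects (same feature set).
#' @return data.frame with `feature`, `importance` (mean |phi|), `rank`;
#'   attribute `phi_matrix` (subjects x features).
#' @export
global_importance <- function(explanations) {
  if (!length(explanations)) stop("no explanations supplied")
  phimat <- do.call(rbind, lapply(explanations, function(e) e$phi))
  rownames(phimat) <- vapply(explanations, function(e)
    as.character(e$subject_id), "")
  imp <- colMeans(abs(phimat))
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    row.names = NULL)
  out <- out[order(-out$importance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "phi_matrix") <- phimat
  out
}

#' Linear trend between feature values and their Shapley contributions
#'
#' Ordinary least-squares fit of contributions against feature values; the
#' slope sign classifies the relationship as positive or negative.
#'
#' @param values feature values (>= 3, non-constant).
#' @param phi matching Shapley contributions.
#' @return list with `slope`, `intercept`, `sign` (`"positive"`,
#'   `"negative"` or `"flat"` for a zero slope).
#' @export
value_contribution_trend <- function(values, phi) {
  if (length(values) < 3) stop("need at least 3 points")
  if (sd(values) == 0) stop("feature values are constant")
  fit <- lm(phi ~ values)
  slope <- unname(coef(fit)[2])
  list(slope = slope, intercept = unname(coef(fit)[1]),
       sign = if (slope > 0) "positive" else if (slope < 0) "negative" else "flat")
}

#' Explain every subject of a table
#'
#' @param model an `mmrf_model`.
#' @param table feature table whose rows are explained.
#' @param background background table (training data).
#' @return list of `explanation` objects.
#' @export
explain_cohort <- function(model, table, background) {
  lapply(seq_len(nrow(table)), function(i)
    exact_shapley(model, table[i, , drop = FALSE], background))
}

#' Serialize explanations as JSON
#'
#' @param explanations list of `explanation` objects.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_explanations <- function(explanations, path) {
  obj <- lapply(explanations, function(e)
    list(subject_id = e$subject_id, base_value = e$base_value,
         prediction = e$prediction, phi = as.list(e$phi),
         percent = as.list(e$percent)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
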