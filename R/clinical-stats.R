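#' Two-sample t-test from summary statistics
#'
#' Welch (unequal-variance) t-test computed from group means, SDs and sizes;
#' `var_equal = TRUE` gives the pooled Student variant. Welch is the default
#' because it reproduces the published group-comparison p-values from
#' printed summaries.
#'
#' @param mean_a,sd_a,n_a summary statistics of group A (n >= 2, sd >= 0).
#' @param mean_b,sd_b,n_b summary statistics of group B.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                 var_equal = FALSE) {
  if (n_a < 2 || n_b < 2) stop("each group needs n >= 2")
  if (sd_a < 0 || sd_b < 0) stop("standard deviations must be >= 0")
  if (var_equal) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Chi-squared test with Yates continuity correction
#'
#' Continuity-corrected chi-squared statistic for a 2x2 count table,
#' `sum(max(0, |O - E| - 0.5)^2 / E)` with 1 degree of freedom; the
#' correction term is clipped at zero so a perfectly proportional table
#' gives chi2 = 0, p = 1.
#'
#' @param counts 2x2 matrix of non-negative counts with positive margins.
#' @param correct apply the continuity correction (default TRUE).
#' @return list with `chi2`, `df`, `p`.
#' @export
yates_chi2 <- function(counts, correct = TRUE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all margins must be positive")
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  dev <- abs(counts - E)
  if (correct) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / E)
  list(chi2 = chi2, df = 1, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Metrics of a confusion matrix
#'
#' Accuracy, sensitivity, specificity and the hard-prediction AUC
#' (`(sensitivity + specificity) / 2`, i.e. balanced accuracy — exactly the
#' rank AUC of a binary 0/1 predictor).
#'
#' @param tp,fn,tn,fp non-negative integer cell counts (positive-class
#'   convention: `tp + fn` positives, `tn + fp` negatives).
#' @return named vector `accuracy`, `sensitivity`, `specificity`,
#'   `hard_auc`; empty class margins yield `NaN` for the affected metrics.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn + tn + fp > 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  c(accuracy = (tp + tn) / (tp + fn + tn + fp),
    sensitivity = sens, specificity = spec,
    hard_auc = (sens + spec) / 2)
}

#' Reconstruct class totals from reported misdiagnosis counts
#'
#' Given a cohort total, the number diagnosed correctly, the two
#' misdiagnosis counts and the printed (rounded) sensitivity and
#' specificity, enumerates every integer positive/negative split and returns
#' the unique confusion matrix whose metrics round to the printed values.
#' Both orientations (either class as positive) are examined.
#'
#' @param total cohort size.
#' @param correct number of correct diagnoses (`correct + fn + fp = total`).
#' @param mis_pos_as_neg positives misclassified as negative (fn).
#' @param mis_neg_as_pos negatives misclassified as positive (fp).
#' @param printed_sens,printed_spec printed sensitivity/specificity.
#' @param digits rounding precision of the printed metrics.
#' @return list with `tp`, `fn`, `tn`, `fp`, `n_pos`, `n_neg`,
#'   `orientation` (`"as_given"` or `"swapped"`); an attribute `candidates`
#'   lists all consistent splits. Errors if none or several distinct splits
#'   are consistent.
#' @export
infer_class_totals <- function(total, correct, mis_pos_as_neg, mis_neg_as_pos,
                               printed_sens, printed_spec, digits = 3) {
  if (correct + mis_pos_as_neg + mis_neg_as_pos != total)
    stop("correct + misdiagnosed must equal total")
  cand <- list()
  for (orient in c("as_given", "swapped")) {
    fn <- if (orient == "as_given") mis_pos_as_neg else mis_neg_as_pos
    fp <- if (orient == "as_given") mis_neg_as_pos else mis_pos_as_neg
    for (n_pos in seq_len(total - 1)) {
      n_neg <- total - n_pos
      tp <- n_pos - fn
      tn <- n_neg - fp
      if (tp < 0 || tn < 0 || tp + tn != correct) next
      if (round(tp / n_pos, digits) == round(printed_sens, digits) &&
          round(tn / n_neg, digits) == round(printed_spec, digits))
        cand[[length(cand) + 1]] <- list(tp = tp, fn = fn, tn = tn, fp = fp,
                                         n_pos = n_pos, n_neg = n_neg,
                                         orientation = orient)
    }
  }
  splits <- unique(vapply(cand, function(x) paste(x$n_pos, x$orientation), ""))
  if (!length(cand)) stop("no integer class split is consistent with the printed metrics")
  if (length(splits) > 1) {
    out <- cand[[1]]
    out$ambiguous <- TRUE
    attr(out, "candidates") <- cand
    warning("multiple consistent splits; result flagged ambiguous")
    return(out)
  }
  out <- cand[[1]]
  out$ambiguous <- FALSE
  attr(out, "candidates") <- cand
  out
}

#' Feature-clinical correlation matrix
#'
#' Pairwise correlations (Pearson by default, Spearman optionally) between
#' the phenotype's radiomic features and the clinical covariates, with
#' two-sided p-values and significance flags at `alpha`.
#'
#' @param table feature table (sex is encoded 0/1 automatically).
#' @param features radiomic feature names.
#' @param covariates clinical covariate names.
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha significance level for the `significant` flag matrix.
#' @return list with symmetric matrices `r` (unit diagonal), `p` and
#'   `significant`.
#' @export
feature_clinical_correlation <- function(table, features,
                                         covariates = CLINICAL_COLS,
                                         method = "pearson", alpha = 0.05) {
  cols <- c(features, covariates)
  if (nrow(table) < 3) stop("need at least 3 subjects")
  x <- as.data.frame(lapply(table[cols], sex_numeric))
  names(x) <- cols
  if (any(vapply(x, sd, 0) == 0)) stop("constant column among inputs")
  k <- length(cols)
  r <- diag(1, k); p <- matrix(0, k, k)
  dimnames(r) <- dimnames(p) <- list(cols, cols)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ct <- suppressWarnings(cor.test(x[[i]], x[[j]], method = method))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, significant = p < alpha & row(p) != col(p))
}
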