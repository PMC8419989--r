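#' @importFrom stats pt pchisq quantile sd var median rnorm runif rbinom rlnorm
#'   wilcox.test lm coef cor cor.test predict qt complete.cases
#' @importFrom utils head read.csv write.csv combn
NULL

# xlogx convention: 0 * log2(0) = 0, used by every entropy-type feature
xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

# stratified fold assignment: within each class, cycle fold labels over a
# random permutation so fold sizes differ by at most one per class
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stop("class '", cl, "' has fewer members (", length(idx),
                              ") than folds (", k, ")")
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# Mann-Whitney AUC with midrank tie handling
rank_auc <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# columns of a feature table that hold radiomic features (naming convention
# H-<seq>-...) or clinical covariates
CLINICAL_COLS <- c("age", "sex", "edss", "duration")
META_COLS <- c("subject_id", "diagnosis", "scanner")

feature_cols <- function(table) {
  setdiff(names(table), c(META_COLS, CLINICAL_COLS))
}

radiomic_cols <- function(table) {
  grep("^H-", names(table), value = TRUE)
}

# sex as numeric 0/1 (male = 1) for correlation / modelling
sex_numeric <- function(sex) {
  if (is.numeric(sex)) return(sex)
  as.numeric(sex == "male")
}
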