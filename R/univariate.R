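#' Univariate relevance scores: absolute Pearson correlation
#'
#' Scores each feature independently by `|Pearson r(x_j, y)|`. For a binary
#' classification outcome the classes are encoded 0/1 in `class_levels`
#' order; the filter refuses multi-class outcomes (use
#' [information_gain_scores()] there). Constant features have undefined
#' correlation and are scored 0 with a `zero_variance` flag rather than
#' raising an error, so degenerate omics columns do not abort runs.
#'
#' @param X complete [feature_matrix()].
#' @param y [outcome()]; regression or binary classification.
#' @return object of class `fs_scores`: list with `feature_ids`, `score`
#'   (named, in \[0, 1\]), `method = "pearson"`, `zero_variance` (named logical).
#' @export
correlation_scores <- function(X, y) {
  validate_pair(X, y)
  if (anyNA(X)) fs_validation_stop("fs_missing_error",
    "X contains missing values; run drop_incomplete_features() first")
  yv <- encode_outcome_numeric(y)
  sds <- apply(X, 2L, stats::sd)
  zero_var <- sds == 0
  score <- rep(0, ncol(X))
  if (any(!zero_var)) {
    score[!zero_var] <- abs(as.vector(stats::cor(unclass(X)[, !zero_var, drop = FALSE], yv)))
  }
  names(score) <- colnames(X)
  names(zero_var) <- colnames(X)
  structure(list(feature_ids = colnames(X), score = score,
                 method = "pearson", zero_variance = zero_var),
            class = "fs_scores")
}

# 0/1 (or numeric) encoding of the outcome for correlation-based scoring.
encode_outcome_numeric <- function(y) {
  if (y$task == "regression") return(y$values)
  if (length(y$class_levels) != 2L) {
    fs_validation_stop("fs_multiclass_error", paste0(
      "correlation filter requires a binary outcome (got ",
      length(y$class_levels), " classes); use the information-gain filter ",
      "(information_gain_scores) for multi-class problems"))
  }
  as.numeric(y$values == y$class_levels[2L])
}

#' Filter features by absolute correlation with the outcome
#'
#' Keeps features scoring strictly above `cutoff`; features with
#' `|r| <= cutoff` are removed (the boundary is dropped). Survivor order is
#' the input column order.
#'
#' @inheritParams correlation_scores
#' @param cutoff relevance cutoff on `|r|`; default 0.30.
#' @return `list(X = filtered fs_matrix, step = fs_filter_step)`.
#' @export
filter_by_correlation <- function(X, y, cutoff = 0.30) {
  sc <- correlation_scores(X, y)
  keep <- sc$score > cutoff
  if (!any(keep)) {
    fs_stop("fs_no_features_error",
            sprintf("no features pass univariate filter (max score %.4f <= cutoff %.2f)",
                    max(sc$score), cutoff),
            max_score = max(sc$score))
  }
  kept <- colnames(X)[keep]
  dropped <- colnames(X)[!keep]
  reason <- ifelse(sc$zero_variance[dropped], "zero_variance", "below_cutoff")
  step <- fs_filter_step("univariate_corr", kept, dropped, sc$score,
                         stats::setNames(reason, dropped), cutoff)
  list(X = subset_features(X, kept), step = step)
}

#' Univariate relevance scores: information gain
#'
#' Scores each feature by the mutual information (in bits) between the class
#' and the equal-frequency-discretized feature:
#' `IG_j = H(class) - H(class | bin(x_j))`. Default discretization uses
#' `ceiling(sqrt(n))` bins capped at 10; constant features fall into a single
#' bin and score 0.
#'
#' @param X complete [feature_matrix()].
#' @param y classification [outcome()] (any number of classes >= 2).
#' @param n_bins number of equal-frequency bins; default
#'   `min(ceiling(sqrt(n)), 10)`.
#' @return object of class `fs_scores` with `method = "information_gain"`,
#'   scores in bits (>= 0).
#' @export
information_gain_scores <- function(X, y, n_bins = NULL) {
  validate_pair(X, y)
  if (y$task != "classification") {
    fs_validation_stop("fs_task_error", "information gain requires a classification outcome")
  }
  if (anyNA(X)) fs_validation_stop("fs_missing_error",
    "X contains missing values; run drop_incomplete_features() first")
  n <- n_samples(X)
  if (is.null(n_bins)) n_bins <- min(ceiling(sqrt(n)), 10L)
  cls <- y$values
  h_class <- entropy_bits(table(cls))
  score <- vapply(seq_len(ncol(X)), function(j) {
    b <- equal_freq_bins(unclass(X)[, j], n_bins)
    h_cond <- conditional_entropy_bits(b, cls)
    max(h_class - h_cond, 0)
  }, numeric(1))
  names(score) <- colnames(X)
  zero_var <- apply(X, 2L, stats::sd) == 0
  names(zero_var) <- colnames(X)
  structure(list(feature_ids = colnames(X), score = score,
                 method = "information_gain", zero_variance = zero_var),
            class = "fs_scores")
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

conditional_entropy_bits <- function(bins, cls) {
  tab <- table(bins, cls)
  w <- rowSums(tab) / sum(tab)
  sum(w * apply(tab, 1L, entropy_bits))
}

# Equal-frequency discretization via quantile breaks (duplicates collapsed).
equal_freq_bins <- function(x, n_bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Filter features by information gain
#'
#' Keeps features with gain strictly above `cutoff` (default 0: keep any
#' feature carrying class information after discretization).
#'
#' @inheritParams information_gain_scores
#' @param cutoff gain cutoff in bits.
#' @return `list(X = filtered fs_matrix, step = fs_filter_step)`.
#' @export
filter_by_information_gain <- function(X, y, cutoff = 0, n_bins = NULL) {
  sc <- information_gain_scores(X, y, n_bins = n_bins)
  keep <- sc$score > cutoff
  if (!any(keep)) {
    fs_stop("fs_no_features_error",
            sprintf("no features pass univariate filter (max gain %.4f <= cutoff %.2f)",
                    max(sc$score), cutoff),
            max_score = max(sc$score))
  }
  kept <- colnames(X)[keep]
  dropped <- colnames(X)[!keep]
  reason <- ifelse(sc$zero_variance[dropped], "zero_variance", "below_cutoff")
  step <- fs_filter_step("univariate_gain", kept, dropped, sc$score,
                         stats::setNames(reason, dropped), cutoff)
  list(X = subset_features(X, kept), step = step)
}
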