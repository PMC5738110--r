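#' Construct a feature matrix (samples x features)
#'
#' The canonical container every workflow stage consumes and returns: a
#' numeric matrix with samples as rows and features as columns, carrying
#' unique sample and feature identifiers. Missing cells are `NA` and must be
#' removed with [drop_incomplete_features()] before any filter runs.
#'
#' @param values numeric matrix or data frame, `n_samples x n_features`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to existing rownames or `"s1".."sn"`.
#' @param feature_ids character vector of unique feature identifiers; defaults
#'   to existing colnames or `"f1".."fp"`.
#' @return An object of class `fs_matrix`: the numeric matrix with dimnames
#'   set to the identifiers.
#' @examples
#' X <- feature_matrix(matrix(rnorm(12), 4, 3))
#' n_samples(X); n_features(X)
#' @export
feature_matrix <- function(values, sample_ids = NULL, feature_ids = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    fs_validation_stop("fs_type_error", "`values` must be a numeric matrix")
  }
  n <- nrow(values); p <- ncol(values)
  if (n < 2L) fs_validation_stop("fs_dim_error", sprintf("need >= 2 samples, got %d", n))
  if (p < 1L) fs_validation_stop("fs_dim_error", "need >= 1 feature")
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (is.null(feature_ids)) feature_ids <- colnames(values)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(p))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != n) {
    fs_validation_stop("fs_dim_error",
      sprintf("length(sample_ids) %d != %d samples", length(sample_ids), n))
  }
  if (length(feature_ids) != p) {
    fs_validation_stop("fs_dim_error",
      sprintf("length(feature_ids) %d != %d features", length(feature_ids), p))
  }
  if (anyDuplicated(sample_ids)) {
    fs_validation_stop("fs_duplicate_id_error", "duplicate sample_ids")
  }
  if (anyDuplicated(feature_ids)) {
    fs_validation_stop("fs_duplicate_id_error", "duplicate feature_ids")
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(values, class = c("fs_matrix", "matrix", "array"))
}

#' @rdname feature_matrix
#' @param X an `fs_matrix`.
#' @export
n_samples <- function(X) nrow(X)

#' @rdname feature_matrix
#' @export
n_features <- function(X) ncol(X)

#' @rdname feature_matrix
#' @export
sample_ids <- function(X) rownames(X)

#' @rdname feature_matrix
#' @export
feature_ids <- function(X) colnames(X)

#' Subset a feature matrix by feature ids or sample index
#'
#' @param X an `fs_matrix`.
#' @param ids feature ids to keep, in the requested order.
#' @return an `fs_matrix` restricted to the requested features/samples.
#' @export
subset_features <- function(X, ids) {
  feature_matrix(unclass(X)[, ids, drop = FALSE],
                 sample_ids = rownames(X), feature_ids = ids)
}

#' @rdname subset_features
#' @param idx sample indices to keep.
#' @export
subset_samples <- function(X, idx) {
  feature_matrix(unclass(X)[idx, , drop = FALSE],
                 sample_ids = rownames(X)[idx], feature_ids = colnames(X))
}

#' @export
print.fs_matrix <- function(x, ...) {
  cat(sprintf("<fs_matrix: %d samples x %d features, %d missing cells>\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Construct a per-sample outcome
#'
#' @param values per-sample labels (coerced to character/factor when
#'   `task = "classification"`) or numeric values (regression). Numeric 0/1
#'   labels in a classification task are treated as categories.
#' @param task `"classification"` or `"regression"`.
#' @param class_levels optional ordered class levels (classification only);
#'   defaults to sorted unique labels.
#' @return An object of class `fs_outcome` with fields `task`, `values`
#'   (factor or numeric) and `class_levels`.
#' @examples
#' outcome(c("A", "A", "B", "B"), task = "classification")
#' @export
outcome <- function(values, task = c("classification", "regression"),
                    class_levels = NULL) {
  task <- match.arg(task)
  if (task == "classification") {
    values <- as.character(values)
    if (anyNA(values)) fs_validation_stop("fs_outcome_error", "missing class labels")
    if (is.null(class_levels)) class_levels <- sort(unique(values))
    if (!all(values %in% class_levels)) {
      fs_validation_stop("fs_outcome_error", "labels outside class_levels")
    }
    values <- factor(values, levels = class_levels)
  } else {
    values <- as.numeric(values)
    if (!all(is.finite(values))) {
      fs_validation_stop("fs_outcome_error", "regression outcome must be finite")
    }
    class_levels <- NULL
  }
  structure(list(task = task, values = values, class_levels = class_levels),
            class = "fs_outcome")
}

#' @export
print.fs_outcome <- function(x, ...) {
  if (x$task == "classification") {
    cat(sprintf("<fs_outcome: classification, %d samples, classes: %s>\n",
                length(x$values), paste(x$class_levels, collapse = ", ")))
  } else {
    cat(sprintf("<fs_outcome: regression, %d samples>\n", length(x$values)))
  }
  invisible(x)
}

#' Validate a feature-matrix / outcome pair
#'
#' Checks all cross-invariants: matching lengths, unique identifiers, at
#' least two classes with at least two samples each (classification), finite
#' non-constant outcome (regression). Idempotent and side-effect free.
#'
#' @param X an [feature_matrix()].
#' @param y an [outcome()].
#' @return The pair, invisibly, as `list(X = X, y = y)`, unchanged.
#' @export
validate_pair <- function(X, y) {
  if (!inherits(X, "fs_matrix")) fs_validation_stop("fs_type_error", "X is not an fs_matrix")
  if (!inherits(y, "fs_outcome")) fs_validation_stop("fs_type_error", "y is not an fs_outcome")
  if (length(y$values) != n_samples(X)) {
    fs_validation_stop("fs_dim_error",
      sprintf("outcome length %d != %d samples", length(y$values), n_samples(X)))
  }
  if (y$task == "classification") {
    tab <- table(y$values)
    if (length(tab) < 2L) {
      fs_validation_stop("fs_outcome_error", "classification needs >= 2 class levels")
    }
    small <- names(tab)[tab < 2L]
    if (length(small)) {
      fs_validation_stop("fs_class_size_error",
        sprintf("class %s has < 2 samples", paste(small, collapse = ", ")))
    }
  } else {
    if (stats::var(y$values) == 0) {
      fs_validation_stop("fs_outcome_error", "constant regression outcome")
    }
  }
  invisible(list(X = X, y = y))
}

#' Remove features containing missing values
#'
#' Feature-wise complete-case deletion: any feature with at least one missing
#' cell is dropped (no imputation). The returned step result scores each
#' feature by its fraction of missing cells.
#'
#' @param X an [feature_matrix()].
#' @return `list(X = complete fs_matrix, step = fs_filter_step)`.
#' @export
drop_incomplete_features <- function(X) {
  miss_frac <- colMeans(is.na(X))
  keep <- miss_frac == 0
  if (!any(keep)) fs_stop("fs_no_features_error", "no complete features")
  kept <- colnames(X)[keep]
  dropped <- colnames(X)[!keep]
  step <- fs_filter_step(
    step_name = "drop_incomplete",
    kept_feature_ids = kept,
    dropped_feature_ids = dropped,
    scores = stats::setNames(miss_frac, colnames(X)),
    drop_reason = stats::setNames(rep("missing_values", length(dropped)), dropped),
    cutoff = 0
  )
  list(X = subset_features(X, kept), step = step)
}

#' Filter step result
#'
#' Records which features a filter kept and dropped, per-feature scores
#' (absolute Pearson r, information gain in bits, mean absolute correlation,
#' or missing fraction depending on the step) and a single drop reason per
#' dropped feature.
#'
#' @param step_name step label.
#' @param kept_feature_ids,dropped_feature_ids ordered id vectors partitioning
#'   the input feature set.
#' @param scores named numeric, one score per input feature.
#' @param drop_reason named character over dropped features; values in
#'   `below_cutoff`, `redundant_pair`, `zero_variance`, `missing_values`.
#' @param cutoff the cutoff the step applied.
#' @return object of class `fs_filter_step`.
#' @export
fs_filter_step <- function(step_name, kept_feature_ids, dropped_feature_ids,
                           scores, drop_reason, cutoff) {
  all_ids <- c(kept_feature_ids, dropped_feature_ids)
  if (anyDuplicated(all_ids)) {
    fs_stop("fs_internal_error", "kept and dropped feature sets overlap")
  }
  if (!setequal(names(scores), all_ids)) {
    fs_stop("fs_internal_error", "scores do not cover the input feature set")
  }
  valid_reasons <- c("below_cutoff", "redundant_pair", "zero_variance", "missing_values")
  if (length(dropped_feature_ids)) {
    if (!setequal(names(drop_reason), dropped_feature_ids) ||
        !all(drop_reason %in% valid_reasons)) {
      fs_stop("fs_internal_error", "every dropped feature needs exactly one valid drop_reason")
    }
  }
  structure(list(step_name = step_name,
                 kept_feature_ids = kept_feature_ids,
                 dropped_feature_ids = dropped_feature_ids,
                 scores = scores,
                 drop_reason = drop_reason,
                 cutoff = cutoff),
            class = "fs_filter_step")
}

#' @export
print.fs_filter_step <- function(x, ...) {
  cat(sprintf("<fs_filter_step %s: kept %d, dropped %d (cutoff %s)>\n",
              x$step_name, length(x$kept_feature_ids),
              length(x$dropped_feature_ids), format(x$cutoff)))
  invisible(x)
}
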