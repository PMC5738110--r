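#' Recursive feature elimination with internal cross-validation
#'
#' Backward elimination wrapped around a learning model. For every
#' cross-validation fold, features are ranked on the fold's training part
#' only; for each candidate subset size the model is refit on the top-k
#' features and scored on the held-out part (accuracy for classification,
#' RMSE for regression). The chosen size is the one with the best mean CV
#' performance, ties broken toward the smaller size (parsimony). The final
#' ranking and selected set are then computed on the full data.
#'
#' Classification folds are stratified by class; regression folds are plain
#' random partitions. All randomness derives from `seed`, so identical input
#' and seed give an identical profile.
#'
#' @param X complete [feature_matrix()].
#' @param y [outcome()].
#' @param model an [model_spec()].
#' @param cv_folds number of internal CV folds (>= 2, and at most the
#'   smallest class size for stratified classification folds). Default 10.
#' @param subset_sizes strictly increasing candidate sizes; default powers of
#'   2 from 1 up to the feature count, always including the full count.
#'   Sizes exceeding the feature count are pruned with a warning.
#' @param seed integer seed.
#' @return object of class `fs_rfe_profile`: `subset_sizes`, `cv_mean`,
#'   `cv_sd`, `chosen_size`, `final_ranking`, `selected_feature_ids`, `metric`
#'   (`"accuracy"` or `"rmse"`), and `fold_rankings` (per-fold training
#'   rankings, kept for leakage audits).
#' @export
rfe <- function(X, y, model = model_spec(), cv_folds = 10L,
                subset_sizes = NULL, seed = 1L) {
  validate_pair(X, y)
  if (anyNA(X)) fs_validation_stop("fs_missing_error", "X contains missing values")
  p <- ncol(X)
  if (is.null(subset_sizes)) subset_sizes <- default_subset_sizes(p)
  subset_sizes <- as.integer(subset_sizes)
  if (any(diff(subset_sizes) <= 0)) {
    fs_validation_stop("fs_config_error", "subset_sizes must be strictly increasing")
  }
  if (any(subset_sizes > p)) {
    warning(sprintf("pruning subset sizes exceeding the %d available features: %s",
                    p, paste(subset_sizes[subset_sizes > p], collapse = ", ")))
    subset_sizes <- subset_sizes[subset_sizes <= p]
  }
  if (!length(subset_sizes)) subset_sizes <- p
  folds <- make_cv_folds(y, cv_folds, derive_seed(seed, 101L))
  metric <- if (y$task == "classification") "accuracy" else "rmse"

  fold_scores <- matrix(NA_real_, nrow = length(folds), ncol = length(subset_sizes),
                        dimnames = list(NULL, as.character(subset_sizes)))
  fold_rankings <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    holdout <- folds[[f]]
    train <- setdiff(seq_len(nrow(X)), holdout)
    Xtr <- subset_samples(X, train)
    ytr <- subset_outcome(y, train)
    ranking <- rank_features(model, Xtr, ytr, seed = derive_seed(seed, 1000L + f))
    fold_rankings[[f]] <- ranking
    Xho <- subset_samples(X, holdout)
    yho <- y$values[holdout]
    for (s in seq_along(subset_sizes)) {
      k <- subset_sizes[s]
      ids <- ranking[seq_len(k)]
      fit <- fit_model_raw(subset_features(Xtr, ids), ytr, model,
                           seed = derive_seed(seed, 2000L + f * 100L + s))
      pred <- predict(fit, subset_features(Xho, ids))
      fold_scores[f, s] <- if (metric == "accuracy") {
        mean(as.character(pred) == as.character(yho))
      } else {
        sqrt(mean((pred - yho)^2))
      }
    }
  }
  cv_mean <- colMeans(fold_scores)
  cv_sd <- apply(fold_scores, 2L, stats::sd)
  best <- if (metric == "accuracy") which.max(cv_mean) else which.min(cv_mean)
  chosen_size <- subset_sizes[best]  # sizes increasing: first optimum = smallest

  final_ranking <- rank_features(model, X, y, seed = derive_seed(seed, 9001L))
  selected <- final_ranking[seq_len(chosen_size)]
  structure(list(subset_sizes = subset_sizes,
                 cv_mean = unname(cv_mean), cv_sd = unname(cv_sd),
                 chosen_size = chosen_size,
                 final_ranking = final_ranking,
                 selected_feature_ids = selected,
                 metric = metric,
                 fold_rankings = fold_rankings,
                 model = model$kind, cv_folds = length(folds), seed = seed),
            class = "fs_rfe_profile")
}

#' @export
print.fs_rfe_profile <- function(x, ...) {
  cat(sprintf("<fs_rfe_profile: %s/%s, sizes {%s}, chosen %d (CV %s %.3f)>\n",
              x$model, x$metric, paste(x$subset_sizes, collapse = ","),
              x$chosen_size,
              x$metric, x$cv_mean[match(x$chosen_size, x$subset_sizes)]))
  invisible(x)
}

default_subset_sizes <- function(p) {
  s <- 2^(0:floor(log2(p)))
  sort(unique(c(s, p)))
}

# Model fit without training-metric bookkeeping (hot loop inside RFE).
fit_model_raw <- function(X, y, model, seed) {
  M <- unclass(X)
  fit <- withr::with_seed(seed, {
    if (model$kind == "random_forest") {
      randomForest::randomForest(x = M, y = y$values, ntree = model$n_trees)
    } else {
      g <- if (is.null(model$gamma)) median_heuristic_gamma(M) else model$gamma
      e1071::svm(x = M, y = y$values, kernel = "radial",
                 cost = model$cost, gamma = g, scale = FALSE)
    }
  })
  structure(list(fit = fit, feature_ids = colnames(X), task = y$task,
                 spec = model, seed = seed), class = "fs_model")
}

subset_outcome <- function(y, idx) {
  if (y$task == "classification") {
    structure(list(task = y$task, values = droplevels(y$values[idx]),
                   class_levels = levels(droplevels(y$values[idx]))),
              class = "fs_outcome")
  } else {
    structure(list(task = y$task, values = y$values[idx], class_levels = NULL),
              class = "fs_outcome")
  }
}

# Seeded fold assignment: stratified by class for classification, plain
# random partition for regression. Returns list of holdout index vectors.
make_cv_folds <- function(y, cv_folds, seed) {
  cv_folds <- as.integer(cv_folds)
  n <- length(y$values)
  if (cv_folds < 2L) fs_validation_stop("fs_config_error", "cv_folds must be >= 2")
  if (cv_folds > n) fs_validation_stop("fs_fold_error",
    sprintf("cv_folds %d exceeds %d samples; use fewer folds", cv_folds, n))
  assign <- integer(n)
  withr::with_seed(seed, {
    if (y$task == "classification") {
      tab <- table(y$values)
      if (cv_folds > min(tab)) {
        fs_stop("fs_fold_error",
                sprintf("smallest class has %d samples < %d folds; use fewer folds",
                        min(tab), cv_folds))
      }
      for (cl in levels(y$values)) {
        idx <- sample(which(y$values == cl))
        assign[idx] <- rep_len(seq_len(cv_folds), length(idx))
      }
    } else {
      idx <- sample(n)
      assign[idx] <- rep_len(seq_len(cv_folds), n)
    }
  })
  split(seq_len(n), assign)
}
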