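#' Wrapper model specification
#'
#' The learning models the RFE wrapper and the final fit support: a random
#' forest (500 trees by default, impurity importance) or a radial-kernel SVM
#' (cost 1, kernel width from the median heuristic on the training data).
#'
#' @param kind `"random_forest"` or `"svm_radial"`.
#' @param n_trees forest size (random forest only).
#' @param cost soft-margin / regularization constant (SVM only). Default 10:
#'   with the median-heuristic kernel width, cost 1 visibly underfits even
#'   noiseless linear signals, while cost 10 fits them and remains
#'   regularized on noisy omics data.
#' @param gamma radial kernel width; `NULL` (default) uses the median
#'   heuristic `1 / (2 * median(pairwise squared distances))` computed on the
#'   training matrix at fit time.
#' @return object of class `fs_model_spec`.
#' @export
model_spec <- function(kind = c("random_forest", "svm_radial"),
                       n_trees = 500L, cost = 10, gamma = NULL) {
  kind <- match.arg(kind)
  if (n_trees < 1L) fs_validation_stop("fs_config_error", "n_trees must be >= 1")
  if (cost <= 0) fs_validation_stop("fs_config_error", "cost must be > 0")
  structure(list(kind = kind, n_trees = as.integer(n_trees),
                 cost = cost, gamma = gamma),
            class = "fs_model_spec")
}

median_heuristic_gamma <- function(M) {
  d2 <- as.vector(stats::dist(M))^2
  d2 <- d2[d2 > 0]
  if (!length(d2)) return(1 / max(ncol(M), 1L))
  1 / (2 * stats::median(d2))
}

#' Fit a wrapper model on selected features
#'
#' Deterministic given `seed`. The returned handle predicts on new samples by
#' matching feature ids, so column order in prediction input is irrelevant.
#'
#' @param X complete [feature_matrix()] restricted to the selected features.
#' @param y [outcome()].
#' @param model an [model_spec()].
#' @param seed integer seed.
#' @return object of class `fs_model`: fitted model plus `feature_ids`,
#'   `task`, `spec` and training metrics (`$training_metrics`).
#' @export
fit_final_model <- function(X, y, model = model_spec(), seed = 1L) {
  validate_pair(X, y)
  if (ncol(X) < 1L) fs_validation_stop("fs_dim_error", "no selected features to fit on")
  if (anyNA(X)) fs_validation_stop("fs_missing_error", "X contains missing values")
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
  handle <- structure(list(fit = fit, feature_ids = colnames(X),
                           task = y$task, spec = model, seed = seed),
                      class = "fs_model")
  handle$training_metrics <- compute_metrics(predict(handle, X), y$values, y$task)
  handle
}

#' Predict from a fitted wrapper model
#'
#' @param object an `fs_model` handle from [fit_final_model()].
#' @param newdata an [feature_matrix()] containing (at least) the model's
#'   feature ids, in any column order.
#' @param ... unused.
#' @return factor of predicted labels (classification) or numeric predictions
#'   (regression).
#' @export
predict.fs_model <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_ids, colnames(newdata))
  if (length(missing)) {
    fs_stop("fs_predict_error",
            sprintf("prediction input is missing selected feature id(s): %s",
                    paste(missing, collapse = ", ")),
            missing_ids = missing)
  }
  M <- unclass(newdata)[, object$feature_ids, drop = FALSE]
  # random-forest majority votes break ties at random; seeding from the
  # model handle keeps predictions reproducible and independent of ambient
  # RNG state
  p <- withr::with_seed(derive_seed(object$seed, 777L),
                        stats::predict(object$fit, M))
  if (object$task == "classification") factor(as.character(p)) else as.numeric(p)
}

#' Rank features by model importance
#'
#' Produces the total importance order RFE eliminates against. Random forest
#' uses impurity-decrease importance (mean decrease in Gini impurity for
#' classification, node-purity increase for regression) from a forest grown
#' with the given seed. The radial SVM has no native importance, so it uses
#' the model-free absolute Pearson correlation ranking. Ties are broken by
#' column order.
#'
#' @param model an [model_spec()].
#' @param X complete [feature_matrix()], >= 1 feature.
#' @param y [outcome()].
#' @param seed integer seed (random forest only).
#' @return character vector of feature ids, most important first.
#' @export
rank_features <- function(model, X, y, seed = 1L) {
  validate_pair(X, y)
  if (anyNA(X)) fs_validation_stop("fs_missing_error", "X contains missing values")
  if (ncol(X) == 1L) return(colnames(X))
  imp <- if (model$kind == "random_forest") {
    fit <- withr::with_seed(seed, randomForest::randomForest(
      x = unclass(X), y = y$values, ntree = model$n_trees))
    randomForest::importance(fit)[, 1L]
  } else {
    correlation_scores(X, y)$score
  }
  colnames(X)[order(-imp, seq_along(imp))]
}
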