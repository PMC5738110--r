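#' Run a configured feature-selection workflow
#'
#' Executes the configured chain on the running matrix: features with missing
#' cells are removed first (feature-wise complete-case rule), then each
#' configured filter in order, then RFE (if enabled), and finally the model
#' is fit on the selected features (or components). Feature counts are
#' non-increasing across steps and each step's input ids equal the previous
#' step's kept ids; both are asserted on the result.
#'
#' @param X an [feature_matrix()].
#' @param y an [outcome()] with `y$task == config$task`.
#' @param config an [workflow_config()].
#' @return object of class `fs_workflow_result`: `steps` (list of
#'   `fs_filter_step` in execution order), `pca` (projection or NULL),
#'   `rfe_profile` (or NULL), `final_feature_ids`, `model` (fitted
#'   `fs_model`), `n_features_per_step`, `transforms` (the prediction chain)
#'   and `timing_sec` per step.
#' @export
run_workflow <- function(X, y, config) {
  if (!inherits(config, "fs_config")) {
    fs_validation_stop("fs_type_error", "config is not an fs_config")
  }
  validate_pair(X, y)
  if (y$task != config$task) {
    fs_validation_stop("fs_task_error",
      sprintf("outcome task '%s' != config task '%s'", y$task, config$task))
  }
  steps <- list()
  transforms <- list()
  timing <- numeric(0)
  n_per_step <- c(input = ncol(X))
  pca_proj <- NULL
  cur <- X

  run_step <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), fsflow_error = function(e) {
      e$message <- sprintf("[step %s] %s", name, conditionMessage(e))
      stop(e)
    })
    timing[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  res <- run_step("drop_incomplete", function() drop_incomplete_features(cur))
  cur <- res$X
  steps <- c(steps, list(res$step))
  transforms <- c(transforms, list(list(type = "subset", ids = colnames(cur))))
  n_per_step[["drop_incomplete"]] <- ncol(cur)

  for (st in config$steps) {
    res <- switch(st,
      univariate_corr = run_step(st, function()
        filter_by_correlation(cur, y, cutoff = config$corr_cutoff)),
      univariate_gain = run_step(st, function()
        filter_by_information_gain(cur, y, cutoff = config$gain_cutoff)),
      matrix_corr = run_step(st, function()
        correlation_matrix_filter(cur, cutoff = config$matrix_cutoff)),
      pca = run_step(st, function()
        pca_filter(cur, var_retained = config$pca_var))
    )
    if (st == "pca") {
      pca_proj <- res$projection
      transforms <- c(transforms, list(list(type = "pca", projection = pca_proj)))
    } else {
      steps <- c(steps, list(res$step))
      transforms <- c(transforms, list(list(type = "subset", ids = res$step$kept_feature_ids)))
    }
    if (ncol(res$X) > ncol(cur)) fs_stop("fs_internal_error", "feature count increased")
    cur <- res$X
    n_per_step[[st]] <- ncol(cur)
    if (ncol(cur) == 0L) {
      fs_stop("fs_no_features_error", sprintf("empty feature set after step %s", st))
    }
  }

  rfe_profile <- NULL
  if (config$rfe) {
    rfe_profile <- run_step("rfe", function()
      rfe(cur, y, model = model_spec(config$model),
          cv_folds = config$cv_folds, subset_sizes = config$subset_sizes,
          seed = derive_seed(config$seed, 11L)))
    cur <- subset_features(cur, rfe_profile$selected_feature_ids)
    transforms <- c(transforms, list(list(type = "subset", ids = colnames(cur))))
    n_per_step[["rfe"]] <- ncol(cur)
  }

  final_model <- run_step("final_fit", function()
    fit_final_model(cur, y, model = model_spec(config$model),
                    seed = derive_seed(config$seed, 12L)))

  structure(list(steps = steps, pca = pca_proj, rfe_profile = rfe_profile,
                 final_feature_ids = colnames(cur), model = final_model,
                 n_features_per_step = n_per_step,
                 transforms = transforms, timing_sec = timing,
                 config = config),
            class = "fs_workflow_result")
}

#' @export
print.fs_workflow_result <- function(x, ...) {
  cat("<fs_workflow_result>\n  features per step: ",
      paste(sprintf("%s=%d", names(x$n_features_per_step), x$n_features_per_step),
            collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted workflow
#'
#' Applies the whole training-time chain to new raw samples: subsets to each
#' step's kept features (matching by id), projects through the training PCA
#' if one was fit, and predicts with the final model.
#'
#' @param object an `fs_workflow_result`.
#' @param newdata an [feature_matrix()] with original feature ids.
#' @param ... unused.
#' @return predicted labels or values.
#' @export
predict.fs_workflow_result <- function(object, newdata, ...) {
  cur <- newdata
  for (tr in object$transforms) {
    if (tr$type == "subset") {
      missing <- setdiff(tr$ids, colnames(cur))
      if (length(missing)) {
        fs_stop("fs_predict_error",
                sprintf("prediction input is missing feature id(s): %s",
                        paste(utils::head(missing, 5L), collapse = ", ")),
                missing_ids = missing)
      }
      cur <- subset_features(cur, tr$ids)
    } else {
      cur <- project_pca(tr$projection, cur, tr$projection$n_retained)
    }
  }
  predict(object$model, cur)
}

#' Classification / regression metrics
#'
#' Classification: accuracy, the fraction of correct predictions.
#' Regression: RMSE in outcome units and R-squared as the squared Pearson
#' correlation of predicted vs observed (`r2_convention = "cor"`, the
#' resampling-framework convention) or `1 - SSE/SST`
#' (`r2_convention = "ss"`). Constant predictions make the correlation
#' undefined; R-squared is then reported as 0 with `r2_defined = FALSE` and a
#' warning.
#'
#' @param predicted,observed equal-length vectors (>= 2 observations).
#' @param task `"classification"` or `"regression"`.
#' @param r2_convention `"cor"` (default) or `"ss"`.
#' @return named list: `accuracy`, or `rmse`, `r2`, `r2_defined`.
#' @export
compute_metrics <- function(predicted, observed,
                            task = c("classification", "regression"),
                            r2_convention = c("cor", "ss")) {
  task <- match.arg(task)
  r2_convention <- match.arg(r2_convention)
  if (length(predicted) != length(observed)) {
    fs_validation_stop("fs_dim_error",
      sprintf("predicted length %d != observed length %d",
              length(predicted), length(observed)))
  }
  if (length(observed) < 2L) {
    fs_validation_stop("fs_dim_error", "need >= 2 observations")
  }
  if (task == "classification") {
    return(list(accuracy = mean(as.character(predicted) == as.character(observed))))
  }
  predicted <- as.numeric(predicted); observed <- as.numeric(observed)
  rmse <- sqrt(mean((predicted - observed)^2))
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("constant predictions or observations: R^2 undefined, reported as 0")
    return(list(rmse = rmse, r2 = 0, r2_defined = FALSE))
  }
  r2 <- if (r2_convention == "cor") {
    stats::cor(predicted, observed)^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
  list(rmse = rmse, r2 = r2, r2_defined = TRUE)
}
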