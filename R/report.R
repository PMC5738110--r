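#' Write a metrics JSON report
#'
#' Serializes an [evaluate_workflow()] result (or a single
#' [run_workflow()] result) to the package's metrics JSON layout: executed
#' steps, feature counts per step, per-split metrics, mean, sd, seed and a
#' full echo of the effective configuration. Timing is deliberately excluded
#' (hardware-dependent), so identical seeds produce byte-identical files.
#'
#' @param result an `fs_evaluation` or `fs_workflow_result`.
#' @param path output file path.
#' @return the report list, invisibly.
#' @export
write_metrics_json <- function(result, path) {
  report <- metrics_report(result)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(report)
}

metrics_report <- function(result) {
  if (inherits(result, "fs_evaluation")) {
    list(
      report_type = "evaluation",
      steps = as.list(c(result$config$steps, if (result$config$rfe) "rfe")),
      n_splits = result$n_splits,
      per_split_metrics = result$per_split,
      mean = result$mean,
      sd = result$sd,
      median_n_features = result$median_n_features,
      train_fraction = result$train_fraction,
      balance = result$balance,
      seed = result$seed,
      config = config_echo(result$config)
    )
  } else if (inherits(result, "fs_workflow_result")) {
    list(
      report_type = "workflow",
      steps = as.list(vapply(result$steps, function(s) s$step_name, character(1))),
      n_features_per_step = as.list(result$n_features_per_step),
      final_feature_ids = as.list(result$final_feature_ids),
      training_metrics = result$model$training_metrics,
      seed = result$config$seed,
      config = config_echo(result$config)
    )
  } else {
    fs_validation_stop("fs_type_error",
      "result must be an fs_evaluation or fs_workflow_result")
  }
}

#' Validate a metrics report against the shipped schema
#'
#' Checks the structural contract documented in
#' `system.file("schema", "metrics-schema.json", package = "fsflow")`:
#' required keys by report type, numeric mean/sd, and that the stored mean
#' and sd match the per-split vector to 1e-12.
#'
#' @param report a list as produced by [write_metrics_json()], or a path to a
#'   metrics JSON file.
#' @return TRUE invisibly; errors with a named condition on violation.
#' @export
validate_metrics_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report, simplifyVector = TRUE)
  need <- function(keys) {
    miss <- setdiff(keys, names(report))
    if (length(miss)) {
      fs_validation_stop("fs_schema_error",
        sprintf("metrics report missing key(s): %s", paste(miss, collapse = ", ")))
    }
  }
  need(c("report_type", "steps", "seed", "config"))
  if (identical(report$report_type, "evaluation")) {
    need(c("n_splits", "per_split_metrics", "mean", "sd", "median_n_features"))
    ps <- as.data.frame(report$per_split_metrics)
    if (nrow(ps) != report$n_splits) {
      fs_validation_stop("fs_schema_error", "per_split_metrics rows != n_splits")
    }
    for (cn in names(report$mean)) {
      if (!cn %in% names(ps)) {
        fs_validation_stop("fs_schema_error", sprintf("missing per-split column %s", cn))
      }
      if (abs(mean(ps[[cn]]) - as.numeric(report$mean[[cn]])) > 1e-12 ||
          abs(stats::sd(ps[[cn]]) - as.numeric(report$sd[[cn]])) > 1e-12) {
        fs_validation_stop("fs_schema_error",
          sprintf("stored mean/sd of %s do not match the per-split vector", cn))
      }
    }
  } else if (identical(report$report_type, "workflow")) {
    need(c("n_features_per_step", "final_feature_ids"))
    counts <- unlist(report$n_features_per_step)
    if (any(diff(counts) > 0)) {
      fs_validation_stop("fs_schema_error",
        "feature counts must be non-increasing across steps")
    }
  } else {
    fs_validation_stop("fs_schema_error", "unknown report_type")
  }
  invisible(TRUE)
}

#' Write per-split selected features as TSV
#'
#' Long-format table with columns `split` and `feature_id`, one row per
#' selected feature per split.
#'
#' @param evaluation an `fs_evaluation`.
#' @param path output file path.
#' @export
write_selected_features <- function(evaluation, path) {
  if (!inherits(evaluation, "fs_evaluation")) {
    fs_validation_stop("fs_type_error", "evaluation must be an fs_evaluation")
  }
  df <- do.call(rbind, lapply(seq_along(evaluation$selected_features), function(i) {
    data.frame(split = i, feature_id = evaluation$selected_features[[i]])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
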