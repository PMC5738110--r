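#' Workflow configuration
#'
#' Defines an ordered chain of filter steps followed (optionally) by RFE, and
#' the model used for RFE and the final fit. Validated up front so invalid
#' chains fail before any computation:
#' * `univariate_gain` is only valid for classification;
#' * `matrix_corr` may not follow `pca` — PCA scores are uncorrelated by
#'   construction, so the step would be a guaranteed no-op;
#' * `subset_sizes` must be strictly increasing.
#'
#' @param steps character vector, an ordered subset of
#'   `c("univariate_corr", "univariate_gain", "matrix_corr", "pca")`.
#'   Defaults encode the published workflow shape: relevance filter at 0.30,
#'   redundancy filter at 0.75, PCA at 95% variance, 10-fold internal CV,
#'   but `steps` itself defaults to empty (identity chain).
#' @param task `"classification"` or `"regression"`.
#' @param corr_cutoff univariate absolute-correlation cutoff (default 0.30).
#' @param gain_cutoff information-gain cutoff in bits (default 0).
#' @param matrix_cutoff pairwise redundancy cutoff (default 0.75).
#' @param pca_var PCA variance-retention fraction (default 0.95).
#' @param rfe enable the RFE wrapper (default TRUE).
#' @param model `"random_forest"` or `"svm_radial"`.
#' @param cv_folds internal CV folds for RFE (default 10).
#' @param subset_sizes candidate subset sizes for RFE; `NULL` = powers of 2.
#' @param seed integer seed governing all randomness in the run.
#' @return object of class `fs_config`.
#' @export
workflow_config <- function(steps = character(0),
                            task = c("classification", "regression"),
                            corr_cutoff = 0.30, gain_cutoff = 0,
                            matrix_cutoff = 0.75, pca_var = 0.95,
                            rfe = TRUE,
                            model = c("random_forest", "svm_radial"),
                            cv_folds = 10L, subset_sizes = NULL,
                            seed = 1L) {
  task <- match.arg(task)
  model <- match.arg(model)
  allowed <- c("univariate_corr", "univariate_gain", "matrix_corr", "pca")
  bad <- setdiff(steps, allowed)
  if (length(bad)) {
    fs_validation_stop("fs_config_error",
      sprintf("unknown step(s): %s (allowed: %s)",
              paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  }
  if ("univariate_gain" %in% steps && task != "classification") {
    fs_validation_stop("fs_config_error",
      "univariate_gain is only valid for classification tasks")
  }
  ipca <- match("pca", steps, nomatch = 0L)
  icm <- match("matrix_corr", steps, nomatch = 0L)
  if (ipca > 0L && icm > ipca) {
    fs_validation_stop("fs_config_error", paste0(
      "matrix_corr may not follow pca: principal component scores are ",
      "pairwise uncorrelated, so a correlation-matrix filter after PCA is a ",
      "guaranteed no-op"))
  }
  if (!is.null(subset_sizes)) {
    subset_sizes <- as.integer(subset_sizes)
    if (any(diff(subset_sizes) <= 0)) {
      fs_validation_stop("fs_config_error", "subset_sizes must be strictly increasing")
    }
  }
  if (cv_folds < 2L) fs_validation_stop("fs_config_error", "cv_folds must be >= 2")
  structure(list(steps = steps, task = task,
                 corr_cutoff = corr_cutoff, gain_cutoff = gain_cutoff,
                 matrix_cutoff = matrix_cutoff, pca_var = pca_var,
                 rfe = isTRUE(rfe), model = model,
                 cv_folds = as.integer(cv_folds), subset_sizes = subset_sizes,
                 seed = as.integer(seed)),
            class = "fs_config")
}

#' @export
print.fs_config <- function(x, ...) {
  chain <- c(x$steps, if (x$rfe) sprintf("rfe[%s,cv%d]", x$model, x$cv_folds))
  if (!length(chain)) chain <- "(identity)"
  cat(sprintf("<fs_config %s: %s, seed %d>\n", x$task,
              paste(chain, collapse = " -> "), x$seed))
  invisible(x)
}

# Plain-list echo of a config for the metrics JSON.
config_echo <- function(config) {
  list(steps = as.list(config$steps), task = config$task,
       corr_cutoff = config$corr_cutoff, gain_cutoff = config$gain_cutoff,
       matrix_cutoff = config$matrix_cutoff, pca_var = config$pca_var,
       rfe = config$rfe, model = config$model, cv_folds = config$cv_folds,
       subset_sizes = if (is.null(config$subset_sizes)) "auto"
                      else as.list(config$subset_sizes),
       seed = config$seed)
}
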