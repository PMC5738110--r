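#' Estimate workflow performance over randomized class-balanced splits
#'
#' The resampled accuracy-estimation protocol: for each of `n_splits` seeded
#' repetitions the data are split into a training and a test part —
#' stratified by class so class proportions are preserved ("class-balanced"),
#' or down-sampled to equal class sizes with `balance = "downsample"` — the
#' complete workflow (every filter plus RFE plus the final fit) is re-run on
#' the training part only, and performance is measured on the untouched test
#' part. Re-running selection inside every split is what keeps the estimate
#' leakage-free.
#'
#' Per-split seeds are derived from the master seed by a fixed counter
#' scheme, so split i is reproducible in isolation.
#'
#' @param X an [feature_matrix()].
#' @param y an [outcome()].
#' @param config an [workflow_config()].
#' @param n_splits number of randomized repetitions (default 20).
#' @param train_fraction fraction of samples in each training part
#'   (default 2/3).
#' @param balance `"stratified"` (default; preserve class proportions) or
#'   `"downsample"` (equal class counts in training).
#' @param seed master seed; overrides `config$seed`.
#' @return object of class `fs_evaluation`: `n_splits`, `per_split` (data
#'   frame with one row per split: accuracy or rmse/r2, and `n_features`),
#'   `mean`, `sd`, `median_n_features`, `seed`, `config`, and
#'   `selected_features` (list of per-split selected id vectors).
#' @export
evaluate_workflow <- function(X, y, config, n_splits = 20L,
                              train_fraction = 2 / 3,
                              balance = c("stratified", "downsample"),
                              seed = config$seed) {
  balance <- match.arg(balance)
  validate_pair(X, y)
  n_splits <- as.integer(n_splits)
  if (n_splits < 2L) fs_validation_stop("fs_config_error", "n_splits must be >= 2")
  if (train_fraction <= 0 || train_fraction >= 1) {
    fs_validation_stop("fs_config_error", "train_fraction must be in (0, 1)")
  }
  metric_cols <- if (y$task == "classification") "accuracy" else c("rmse", "r2")
  rows <- vector("list", n_splits)
  selected <- vector("list", n_splits)
  for (i in seq_len(n_splits)) {
    split_seed <- derive_seed(seed, i)
    idx <- make_split(y, train_fraction, balance, split_seed)
    cfg_i <- config
    cfg_i$seed <- split_seed
    res <- run_workflow(subset_samples(X, idx$train), subset_outcome(y, idx$train), cfg_i)
    pred <- predict(res, subset_samples(X, idx$test))
    m <- compute_metrics(pred, y$values[idx$test], y$task)
    rows[[i]] <- c(split = i, unlist(m[metric_cols]),
                   n_features = length(res$final_feature_ids))
    selected[[i]] <- res$final_feature_ids
  }
  per_split <- as.data.frame(do.call(rbind, rows))
  mu <- vapply(metric_cols, function(cn) mean(per_split[[cn]]), numeric(1))
  sdv <- vapply(metric_cols, function(cn) stats::sd(per_split[[cn]]), numeric(1))
  structure(list(n_splits = n_splits, per_split = per_split,
                 mean = as.list(mu), sd = as.list(sdv),
                 median_n_features = stats::median(per_split$n_features),
                 train_fraction = train_fraction, balance = balance,
                 seed = as.integer(seed), config = config,
                 selected_features = selected, task = y$task),
            class = "fs_evaluation")
}

#' @export
print.fs_evaluation <- function(x, ...) {
  m <- paste(sprintf("%s %.4f (sd %.4f)", names(x$mean),
                     unlist(x$mean), unlist(x$sd)), collapse = ", ")
  cat(sprintf("<fs_evaluation: %d splits, %s, median %d features>\n",
              x$n_splits, m, x$median_n_features))
  invisible(x)
}

# Stratified (or down-sampled) train/test split. Guards against a
# single-class training set with bounded resampling, though stratification
# makes that unreachable in practice.
make_split <- function(y, train_fraction, balance, seed) {
  n <- length(y$values)
  for (attempt in 1:10) {
    train <- withr::with_seed(derive_seed(seed, attempt - 1L), {
      if (y$task == "classification") {
        per_class <- lapply(levels(y$values), function(cl) {
          idx <- which(y$values == cl)
          k <- max(2L, round(train_fraction * length(idx)))
          if (k >= length(idx)) k <- length(idx) - 1L
          sample(idx, k)
        })
        if (balance == "downsample") {
          k <- min(lengths(per_class))
          per_class <- lapply(per_class, function(ix) ix[seq_len(k)])
        }
        sort(unlist(per_class))
      } else {
        sort(sample(n, max(2L, round(train_fraction * n))))
      }
    })
    test <- setdiff(seq_len(n), train)
    ok <- length(test) >= 2L &&
      (y$task == "regression" || length(unique(y$values[train])) >= 2L)
    if (ok) return(list(train = train, test = test))
  }
  fs_stop("fs_split_error", "could not construct a valid train/test split in 10 attempts")
}
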