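#' Greedy correlation-matrix redundancy filter
#'
#' Removes between-feature redundancy while keeping original features.
#' Repeatedly, among all feature pairs with `|r| >= cutoff`, the pair with the
#' largest `|r|` is located and the member with the larger mean absolute
#' correlation against all currently retained features is dropped, until no
#' violating pair remains (the findCorrelation-style heuristic). Ties in mean
#' absolute correlation (within 1e-12) drop the feature with the larger
#' column index, keeping earlier features.
#'
#' Guarantee: no retained pair has `|r| >= cutoff`. The filter is idempotent
#' and never drops a feature that participates in no violating pair.
#'
#' @param X complete [feature_matrix()] with at least 2 features and no
#'   zero-variance columns (undefined correlation raises an error).
#' @param cutoff redundancy cutoff on pairwise `|r|`; default 0.75. The
#'   boundary is inclusive: pairs at exactly `cutoff` are violations.
#' @return `list(X = filtered fs_matrix, step = fs_filter_step)`; step scores
#'   are each feature's initial mean absolute correlation with all others.
#' @export
correlation_matrix_filter <- function(X, cutoff = 0.75) {
  if (!inherits(X, "fs_matrix")) fs_validation_stop("fs_type_error", "X is not an fs_matrix")
  if (anyNA(X)) fs_validation_stop("fs_missing_error",
    "X contains missing values; run drop_incomplete_features() first")
  if (ncol(X) < 2L) fs_validation_stop("fs_dim_error", "correlation-matrix filter needs >= 2 features")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    fs_validation_stop("fs_zero_variance_error",
      sprintf("zero-variance feature(s) present (undefined correlation): %s",
              paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  R <- abs(stats::cor(unclass(X)))
  diag(R) <- 0
  p <- ncol(R)
  init_mean_abs <- rowSums(R) / (p - 1L)
  retained <- rep(TRUE, p)
  dropped_idx <- integer(0)

  repeat {
    sub <- R[retained, retained, drop = FALSE]
    if (nrow(sub) < 2L || max(sub) < cutoff) break
    hit <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    ret_idx <- which(retained)
    i <- ret_idx[hit[["row"]]]; j <- ret_idx[hit[["col"]]]
    # mean |r| of each pair member against all other retained features
    others_i <- setdiff(ret_idx, i); others_j <- setdiff(ret_idx, j)
    mi <- mean(R[i, others_i]); mj <- mean(R[j, others_j])
    drop <- if (abs(mi - mj) <= 1e-12) max(i, j) else if (mi > mj) i else j
    retained[drop] <- FALSE
    dropped_idx <- c(dropped_idx, drop)
  }

  kept <- colnames(X)[retained]
  dropped <- colnames(X)[sort(dropped_idx)]
  # post-condition check (cheap insurance on the greedy loop)
  if (length(kept) >= 2L) {
    Rk <- R[retained, retained, drop = FALSE]
    if (max(Rk) >= cutoff) fs_stop("fs_internal_error", "CM filter post-condition violated")
  }
  step <- fs_filter_step("matrix_corr", kept, dropped,
                         stats::setNames(init_mean_abs, colnames(X)),
                         stats::setNames(rep("redundant_pair", length(dropped)), dropped),
                         cutoff)
  list(X = subset_features(X, kept), step = step)
}

#' Fit a PCA projection
#'
#' Principal components of the column-centered (and by default unit-variance
#' scaled) matrix, via [stats::prcomp()]. Deterministic across platforms: the
#' loading with the largest absolute value in each component is forced
#' positive. Components with a variance ratio below 1e-12 are treated as zero
#' variance (rank detection).
#'
#' @param X complete [feature_matrix()], `n_samples >= 3`.
#' @param scale. scale features to unit variance before rotation
#'   (default TRUE; omics features often live on wildly different scales).
#' @return object of class `fs_pca`: `loadings` (feature x component),
#'   `explained_variance_ratio` (non-increasing, sums to 1),
#'   `center`, `scale` (per-feature), `n_nonzero` (rank).
#' @export
pca_fit <- function(X, scale. = TRUE) {
  if (!inherits(X, "fs_matrix")) fs_validation_stop("fs_type_error", "X is not an fs_matrix")
  if (anyNA(X)) fs_validation_stop("fs_missing_error",
    "X contains missing values; run drop_incomplete_features() first")
  if (nrow(X) < 3L) fs_validation_stop("fs_dim_error", "PCA needs >= 3 samples")
  sds <- apply(X, 2L, stats::sd)
  if (all(sds == 0)) fs_validation_stop("fs_zero_variance_error", "all features constant")
  if (scale. && any(sds == 0)) {
    fs_validation_stop("fs_zero_variance_error",
      "zero-variance feature(s) cannot be unit-scaled; remove them first")
  }
  pc <- stats::prcomp(unclass(X), center = TRUE, scale. = scale.)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  # sign convention: largest-|loading| entry positive in every component
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    v <- pc$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2L, flip, "*")
  structure(list(
    loadings = loadings,
    explained_variance_ratio = evr,
    center = pc$center,
    scale = if (scale.) pc$scale else stats::setNames(rep(1, ncol(X)), colnames(X)),
    n_nonzero = sum(evr > 1e-12),
    feature_ids = colnames(X)
  ), class = "fs_pca")
}

#' @export
print.fs_pca <- function(x, ...) {
  cat(sprintf("<fs_pca: %d features, %d nonzero components, PC1 ratio %.3f>\n",
              nrow(x$loadings), x$n_nonzero, x$explained_variance_ratio[1]))
  invisible(x)
}

#' Cumulative explained variance
#'
#' @param p a fitted [pca_fit()] projection.
#' @return non-decreasing vector of cumulative variance fractions ending at 1.
#' @export
cumulative_variance <- function(p) {
  if (!inherits(p, "fs_pca")) fs_validation_stop("fs_type_error", "not an fs_pca")
  cumsum(p$explained_variance_ratio)
}

#' PCA variance-retention filter
#'
#' Replaces features with the scores of the smallest leading set of principal
#' components whose cumulative explained variance reaches `var_retained`
#' (default 0.95). Output feature ids are `PC1..PCk`.
#'
#' @inheritParams pca_fit
#' @param var_retained fraction of variance to retain, in (0, 1\].
#' @return `list(X = fs_matrix of component scores, projection = fs_pca
#'   with n_retained set)`.
#' @export
pca_filter <- function(X, var_retained = 0.95, scale. = TRUE) {
  if (!is.numeric(var_retained) || var_retained <= 0 || var_retained > 1) {
    fs_validation_stop("fs_config_error", "var_retained must be in (0, 1]")
  }
  proj <- pca_fit(X, scale. = scale.)
  cum <- cumulative_variance(proj)
  k <- which(cum >= var_retained - 1e-12)[1L]
  if (is.na(k)) k <- proj$n_nonzero
  k <- min(k, proj$n_nonzero)
  k <- max(k, 1L)
  proj$n_retained <- k
  scores <- project_pca(proj, X, k)
  list(X = scores, projection = proj)
}

# Project (new) samples onto the first k fitted components.
project_pca <- function(proj, X, k = proj$n_retained) {
  missing <- setdiff(proj$feature_ids, colnames(X))
  if (length(missing)) {
    fs_stop("fs_predict_error",
            sprintf("input is missing fitted feature id(s): %s",
                    paste(utils::head(missing, 5L), collapse = ", ")),
            missing_ids = missing)
  }
  M <- unclass(X)[, proj$feature_ids, drop = FALSE]
  M <- sweep(M, 2L, proj$center, "-")
  M <- sweep(M, 2L, proj$scale, "/")
  S <- M %*% proj$loadings[, seq_len(k), drop = FALSE]
  feature_matrix(S, sample_ids = rownames(X),
                 feature_ids = paste0("PC", seq_len(k)))
}
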