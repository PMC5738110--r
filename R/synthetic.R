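#' Synthetic dataset specification
#'
#' Describes the informative / redundant / irrelevant block structure the
#' workflow assumes, so every stage is testable without external downloads:
#' a small block of outcome-informative features, a block of redundant
#' copies (each correlated with exactly one informative parent — a star
#' topology, so "which feature proxies which" is checkable), and a large
#' block of pure-noise features. Missing values can be injected uniformly at
#' random.
#'
#' @param n_samples number of samples.
#' @param k_informative,k_redundant,k_noise block sizes.
#' @param effect_size standardized class-mean difference d (classification).
#' @param beta coefficient vector over informative features (regression);
#'   recycled to length `k_informative`.
#' @param redundancy_rho target correlation of a redundant copy with its
#'   parent, in \[0, 1).
#' @param noise_sd residual SD of the regression outcome.
#' @param missing_fraction fraction of cells masked missing, in \[0, 1).
#' @param class_proportions class proportions (must sum to 1); length gives
#'   the number of classes.
#' @param heavy_tails if TRUE draw feature noise from a t(3) distribution
#'   (scaled to unit variance) instead of a Gaussian, for robustness tests.
#' @param seed integer seed; output is fully determined by it.
#' @return object of class `fs_synth_spec`.
#' @export
synthetic_spec <- function(n_samples = 100L, k_informative = 5L,
                           k_redundant = 0L, k_noise = 50L,
                           effect_size = 1, beta = 1,
                           redundancy_rho = 0.8, noise_sd = 1,
                           missing_fraction = 0,
                           class_proportions = c(0.5, 0.5),
                           heavy_tails = FALSE, seed = 1L) {
  if (n_samples < 4L) fs_validation_stop("fs_config_error", "n_samples must be >= 4")
  if (k_informative < 1L && (effect_size > 0 || k_redundant > 0L)) {
    fs_validation_stop("fs_config_error",
      "k_informative must be >= 1 when effect_size > 0 or redundancy is requested")
  }
  if (redundancy_rho < 0 || redundancy_rho >= 1) {
    fs_validation_stop("fs_config_error", "redundancy_rho must be in [0, 1)")
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    fs_validation_stop("fs_config_error", "missing_fraction must be in [0, 1)")
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    fs_validation_stop("fs_config_error", "class_proportions must sum to 1")
  }
  structure(list(n_samples = as.integer(n_samples),
                 k_informative = as.integer(k_informative),
                 k_redundant = as.integer(k_redundant),
                 k_noise = as.integer(k_noise),
                 effect_size = effect_size, beta = beta,
                 redundancy_rho = redundancy_rho, noise_sd = noise_sd,
                 missing_fraction = missing_fraction,
                 class_proportions = class_proportions,
                 heavy_tails = heavy_tails, seed = as.integer(seed)),
            class = "fs_synth_spec")
}

rnoise <- function(n, heavy_tails) {
  if (heavy_tails) stats::rt(n, df = 3) / sqrt(3) else stats::rnorm(n)
}

#' Generate a synthetic classification dataset
#'
#' Informative feature j of a sample in class k is `N(mu_k, 1)` with class
#' means centered and separated by `effect_size` (two classes: -d/2 and
#' +d/2). A redundant copy is `rho * parent + sqrt(1 - rho^2) * sigma_p * e`
#' with `e ~ N(0, 1)` and `sigma_p` the parent's marginal SD, so the
#' population correlation with the parent is exactly `rho`. Noise features
#' are `N(0, 1)`. Class counts follow `class_proportions` exactly (rounded),
#' label order is shuffled, and missing cells are masked uniformly at rate
#' `missing_fraction`. Fully determined by the spec seed.
#'
#' @param spec an [synthetic_spec()].
#' @return list: `X` ([feature_matrix()]), `y` ([outcome()]), `ground_truth`
#'   with `informative` ids, `redundant_parent` (named map copy -> parent)
#'   and `noise` ids.
#' @export
make_classification_data <- function(spec) {
  n <- spec$n_samples
  K <- length(spec$class_proportions)
  counts <- diff(c(0L, round(cumsum(spec$class_proportions) * n)))
  if (any(counts < 2L)) {
    fs_validation_stop("fs_config_error", "every class needs >= 2 samples")
  }
  levels <- paste0("C", seq_len(K))
  mu <- (seq_len(K) - (K + 1) / 2) * spec$effect_size
  withr::with_seed(spec$seed, {
    labels <- sample(rep(levels, counts))
    cls_idx <- match(labels, levels)
    inf <- matrix(rnoise(n * spec$k_informative, spec$heavy_tails),
                  n, spec$k_informative)
    inf <- inf + matrix(mu[cls_idx], n, spec$k_informative)
    # marginal variance of an informative feature under the class mixture
    pk <- counts / n
    v <- 1 + sum(pk * mu^2) - sum(pk * mu)^2
    build_dataset(spec, inf, sigma_parent = sqrt(v),
                  y = outcome(labels, "classification", class_levels = levels))
  })
}

#' Generate a synthetic regression dataset
#'
#' Informative features are `N(0, 1)`; the outcome is
#' `y = X_informative %*% beta + N(0, noise_sd)`. Redundant and noise blocks
#' are built as in [make_classification_data()].
#'
#' @inheritParams make_classification_data
#' @return as [make_classification_data()].
#' @export
make_regression_data <- function(spec) {
  n <- spec$n_samples
  beta <- rep_len(spec$beta, spec$k_informative)
  withr::with_seed(spec$seed, {
    inf <- matrix(rnoise(n * spec$k_informative, spec$heavy_tails),
                  n, spec$k_informative)
    yv <- as.vector(inf %*% beta) + stats::rnorm(n, sd = spec$noise_sd)
    build_dataset(spec, inf, sigma_parent = 1,
                  y = outcome(yv, "regression"))
  })
}

# Shared assembly of redundant + noise blocks, ids, ground truth and the
# missingness mask. Runs inside the caller's with_seed().
build_dataset <- function(spec, inf, sigma_parent, y) {
  n <- spec$n_samples
  inf_ids <- if (spec$k_informative) paste0("inf_", seq_len(spec$k_informative)) else character(0)
  red_ids <- if (spec$k_redundant) paste0("red_", seq_len(spec$k_redundant)) else character(0)
  nse_ids <- if (spec$k_noise) paste0("nse_", seq_len(spec$k_noise)) else character(0)
  parent_map <- character(0)
  red <- NULL
  if (spec$k_redundant > 0L) {
    parents <- rep_len(seq_len(spec$k_informative), spec$k_redundant)
    rho <- spec$redundancy_rho
    red <- vapply(parents, function(pj) {
      rho * inf[, pj] + sqrt(1 - rho^2) * sigma_parent * rnoise(n, spec$heavy_tails)
    }, numeric(n))
    parent_map <- stats::setNames(inf_ids[parents], red_ids)
  }
  nse <- if (spec$k_noise > 0L) {
    matrix(rnoise(n * spec$k_noise, spec$heavy_tails), n, spec$k_noise)
  } else NULL
  M <- cbind(inf, red, nse)
  colnames(M) <- c(inf_ids, red_ids, nse_ids)
  if (spec$missing_fraction > 0) {
    mask <- stats::runif(length(M)) < spec$missing_fraction
    M[mask] <- NA_real_
  }
  X <- feature_matrix(M, sample_ids = paste0("s", seq_len(n)))
  list(X = X, y = y,
       ground_truth = list(informative = inf_ids,
                           redundant_parent = parent_map,
                           noise = nse_ids))
}
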