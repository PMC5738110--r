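# Independent brute-force oracles. These deliberately re-derive every
# quantity from defining formulas through a different code path than the
# package implementation.

# Two-pass Pearson correlation from the defining formula.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_entropy_bits <- function(v) {
  p <- table(v) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Information gain via the identity IG = H(C) + H(B) - H(C, B).
oracle_information_gain <- function(bins, cls) {
  joint <- paste(as.character(bins), as.character(cls), sep = "\r")
  oracle_entropy_bits(cls) + oracle_entropy_bits(bins) - oracle_entropy_bits(joint)
}

# Independent greedy correlation-matrix elimination: same declared rule
# (largest violating pair; drop the member with larger mean |r| against
# retained; ties drop the later column), re-implemented from scratch on
# feature-id sets instead of index masks.
oracle_cm_kept <- function(M, cutoff) {
  ids <- colnames(M)
  repeat {
    R <- abs(stats::cor(M[, ids, drop = FALSE]))
    diag(R) <- -1
    if (length(ids) < 2L || max(R) < cutoff) return(ids)
    pos <- which(R == max(R), arr.ind = TRUE)[1L, ]
    a <- ids[pos[1L]]; b <- ids[pos[2L]]
    ma <- mean(abs(stats::cor(M[, a], M[, setdiff(ids, a), drop = FALSE])))
    mb <- mean(abs(stats::cor(M[, b], M[, setdiff(ids, b), drop = FALSE])))
    drop <- if (abs(ma - mb) <= 1e-12) {
      if (match(a, colnames(M)) > match(b, colnames(M))) a else b
    } else if (ma > mb) a else b
    ids <- setdiff(ids, drop)
  }
}

# Maximum absolute off-diagonal correlation among a retained feature set.
max_pair_cor <- function(M, ids) {
  if (length(ids) < 2L) return(0)
  R <- abs(stats::cor(M[, ids, drop = FALSE]))
  diag(R) <- 0
  max(R)
}

# Explained-variance ratios via eigendecomposition of the covariance of the
# centered/scaled matrix (independent of prcomp's SVD route).
oracle_evr <- function(M, scale. = TRUE) {
  S <- scale(M, center = TRUE, scale = scale.)
  ev <- eigen(stats::cov(S), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev / sum(ev)
}

# Small labelled random dataset used across suites.
tiny_classif <- function(n = 12, p = 4, seed = 1) {
  withr::with_seed(seed, {
    X <- feature_matrix(matrix(rnorm(n * p), n, p))
    y <- outcome(rep(c("A", "B"), length.out = n), "classification")
    list(X = X, y = y)
  })
}

# The synthetic study family used by the recovery and non-inferiority
# checks: 5 informative (d = 1.5), 10 redundant copies (rho = 0.85),
# 300 noise features, n = 150.
study_spec <- function(seed) {
  synthetic_spec(n_samples = 150, k_informative = 5, k_redundant = 10,
                 k_noise = 300, effect_size = 1.5, redundancy_rho = 0.85,
                 class_proportions = c(0.5, 0.5), seed = seed)
}

# Fraction of informative signals represented in a selected set, counting a
# redundant copy as representing its parent.
signal_recovery <- function(selected, ground_truth) {
  represented <- unique(c(
    intersect(selected, ground_truth$informative),
    unname(ground_truth$redundant_parent[intersect(selected, names(ground_truth$redundant_parent))])
  ))
  length(represented) / length(ground_truth$informative)
}
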