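test_that("config validation rejects invalid chains before any computation", {
  expect_error(workflow_config(steps = c("pca", "matrix_corr"), task = "classification"),
               "guaranteed no-op", class = "fs_config_error")
  expect_error(workflow_config(steps = "univariate_gain", task = "regression"),
               class = "fs_config_error")
  expect_error(workflow_config(steps = "shrink_wrap", task = "classification"),
               "unknown step", class = "fs_config_error")
  expect_error(workflow_config(task = "classification", cv_folds = 1),
               class = "fs_config_error")
  # matrix_corr BEFORE pca is a legal chain
  expect_s3_class(workflow_config(steps = c("matrix_corr", "pca"),
                                  task = "classification"), "fs_config")
})

test_that("an empty chain without RFE is the identity on features", {
  dat <- tiny_classif(n = 24, p = 6, seed = 1)
  cfg <- workflow_config(task = "classification", rfe = FALSE, seed = 1)
  res <- run_workflow(dat$X, dat$y, cfg)
  expect_identical(res$final_feature_ids, feature_ids(dat$X))
  expect_null(res$rfe_profile)
  expect_s3_class(res$model, "fs_model")
})

test_that("feature counts are non-increasing and chained ids are consistent", {
  dat <- make_classification_data(synthetic_spec(
    n_samples = 80, k_informative = 4, k_redundant = 6, k_noise = 60,
    effect_size = 2, redundancy_rho = 0.9, seed = 3))
  cfg <- workflow_config(steps = c("univariate_corr", "matrix_corr"),
                         task = "classification", cv_folds = 3, seed = 3)
  res <- run_workflow(dat$X, dat$y, cfg)
  expect_true(all(diff(res$n_features_per_step) <= 0))
  # each step's input ids equal the previous step's kept ids
  steps <- res$steps
  for (i in seq_along(steps)[-1]) {
    expect_setequal(names(steps[[i]]$scores), steps[[i - 1]]$kept_feature_ids)
  }
  expect_setequal(res$final_feature_ids, res$rfe_profile$selected_feature_ids)
})

test_that("step errors propagate with the step name attached", {
  dat <- tiny_classif(n = 20, p = 4, seed = 2)
  cfg <- workflow_config(steps = "univariate_corr", task = "classification",
                         corr_cutoff = 1, seed = 1)
  expect_error(run_workflow(dat$X, dat$y, cfg),
               "\\[step univariate_corr\\].*no features pass",
               class = "fs_no_features_error")
})

test_that("metrics match their defining formulas on a hand-built fixture", {
  pred <- c(1.1, 1.9, 3.2, 3.9, 5.1)
  obs <- c(1, 2, 3, 4, 5)
  m <- compute_metrics(pred, obs, "regression")
  expect_equal(m$rmse, sqrt(mean((pred - obs)^2)), tolerance = 1e-12)
  expect_equal(m$r2, oracle_pearson(pred, obs)^2, tolerance = 1e-12)
  expect_true(m$r2_defined)
  # exact predictions
  m0 <- compute_metrics(obs, obs, "regression")
  expect_equal(m0$rmse, 0)
  expect_equal(m0$r2, 1)
  # sum-of-squares convention on the same fixture
  mss <- compute_metrics(pred, obs, "regression", r2_convention = "ss")
  expect_equal(mss$r2, 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-12)
  # all-wrong binary predictions
  expect_equal(compute_metrics(c("A", "A"), c("B", "B"), "classification")$accuracy, 0)
  # constant predictions: R^2 undefined -> 0 with a warning
  expect_warning(mc <- compute_metrics(rep(2, 5), obs, "regression"), "undefined")
  expect_equal(mc$r2, 0)
  expect_false(mc$r2_defined)
  expect_error(compute_metrics(1:3, 1:4, "regression"), class = "fs_dim_error")
})

test_that("perfectly separable classes evaluate to mean accuracy 1", {
  dat <- make_classification_data(synthetic_spec(
    n_samples = 80, k_informative = 3, k_noise = 10, effect_size = 5, seed = 5))
  cfg <- workflow_config(steps = "univariate_corr", task = "classification",
                         cv_folds = 3, seed = 5)
  ev <- evaluate_workflow(dat$X, dat$y, cfg, n_splits = 5, seed = 5)
  expect_equal(ev$mean$accuracy, 1)
})

test_that("null data with permuted labels stays near the majority-class rate", {
  dat <- make_classification_data(synthetic_spec(
    n_samples = 60, k_informative = 1, k_noise = 20, effect_size = 0, seed = 17))
  cfg <- workflow_config(task = "classification", rfe = FALSE, seed = 17)
  ev <- evaluate_workflow(dat$X, dat$y, cfg, n_splits = 20, seed = 17)
  majority <- max(table(dat$y$values)) / length(dat$y$values)
  n_test <- 60 - round(2 / 3 * 30) * 2
  se_mean <- sqrt(majority * (1 - majority) / n_test) / sqrt(20)
  expect_lt(abs(ev$mean$accuracy - majority), 3 * max(se_mean, ev$sd$accuracy / sqrt(20)))
})

test_that("evaluation summaries are internally consistent and reproducible", {
  dat <- make_classification_data(synthetic_spec(
    n_samples = 50, k_informative = 2, k_noise = 15, effect_size = 2, seed = 7))
  cfg <- workflow_config(steps = "univariate_corr", task = "classification",
                         cv_folds = 3, seed = 7)
  ev <- evaluate_workflow(dat$X, dat$y, cfg, n_splits = 4, seed = 7)
  expect_identical(ev$n_splits, 4L)
  expect_equal(ev$mean$accuracy, mean(ev$per_split$accuracy), tolerance = 1e-12)
  expect_equal(ev$sd$accuracy, sd(ev$per_split$accuracy), tolerance = 1e-12)
  ev2 <- evaluate_workflow(dat$X, dat$y, cfg, n_splits = 4, seed = 7)
  expect_identical(ev$per_split, ev2$per_split)
  expect_identical(ev$selected_features, ev2$selected_features)
})

test_that("training-phase selections ignore test-set values (no leakage)", {
  dat <- make_classification_data(synthetic_spec(
    n_samples = 60, k_informative = 2, k_noise = 20, effect_size = 1.5, seed = 8))
  cfg <- workflow_config(steps = "univariate_corr", task = "classification",
                         cv_folds = 3, seed = 8)
  ev <- evaluate_workflow(dat$X, dat$y, cfg, n_splits = 3, seed = 8)
  # perturb exactly split 1's held-out samples
  idx <- fsflow:::make_split(dat$y, 2 / 3, "stratified", fsflow:::derive_seed(8, 1))
  M <- unclass(dat$X)
  M[idx$test, ] <- M[idx$test, ] * 50 - 3
  ev2 <- evaluate_workflow(feature_matrix(M, sample_ids = sample_ids(dat$X)),
                           dat$y, cfg, n_splits = 3, seed = 8)
  expect_identical(ev2$selected_features[[1]], ev$selected_features[[1]])
})

test_that("downsampled balancing equalizes training class counts", {
  yv <- c(rep("A", 30), rep("B", 12))
  withr::with_seed(9, M <- matrix(rnorm(42 * 5), 42, 5))
  y <- outcome(yv, "classification")
  idx <- fsflow:::make_split(y, 2 / 3, "downsample", 123)
  tab <- table(y$values[idx$train])
  expect_equal(unname(tab["A"]), unname(tab["B"]))
})

test_that("metrics JSON reports validate and reject corrupted summaries", {
  dat <- make_classification_data(synthetic_spec(
    n_samples = 40, k_informative = 2, k_noise = 10, effect_size = 2, seed = 10))
  cfg <- workflow_config(steps = "univariate_corr", task = "classification",
                         cv_folds = 3, seed = 10)
  ev <- evaluate_workflow(dat$X, dat$y, cfg, n_splits = 3, seed = 10)
  path <- withr::local_tempfile(fileext = ".json")
  rep <- write_metrics_json(ev, path)
  expect_true(validate_metrics_report(path))
  bad <- rep; bad$mean$accuracy <- bad$mean$accuracy + 0.5
  expect_error(validate_metrics_report(bad), class = "fs_schema_error")
  bad2 <- rep; bad2$per_split_metrics <- NULL
  expect_error(validate_metrics_report(bad2), class = "fs_schema_error")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- write_selected_features(ev, tsv)
  expect_identical(sort(unique(df$split)), 1:3)
  expect_identical(df$feature_id[df$split == 2], ev$selected_features[[2]])
})
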