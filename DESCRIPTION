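Package: fsflow
Title: Filter and Wrapper Feature-Selection Workflows for High-Dimensional Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composable feature-selection workflows for omics feature tables
    (samples x features): univariate relevance filtering by absolute Pearson
    correlation or information gain, multivariate redundancy reduction by
    greedy correlation-matrix elimination or PCA variance-retention filtering,
    and backward recursive feature elimination (RFE) wrapped around a random
    forest or radial-kernel SVM with internal cross-validation. Includes a
    resampled accuracy-estimation harness over randomized class-balanced
    train/test splits, a synthetic-data generator with informative, redundant
    and irrelevant feature blocks, TSV/CSV readers for both table
    orientations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse,
    yaml
Config/testthat/edition: 3
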