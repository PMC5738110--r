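#' Read a feature table from CSV/TSV
#'
#' Reads a delimited numeric feature table in either orientation and returns
#' the canonical samples-as-rows [feature_matrix()] plus the outcome. The
#' first column always holds row identifiers. `"NA"` tokens and empty cells
#' become missing values.
#'
#' Labels come either from a named column (samples-as-rows) / named row
#' (features-as-rows) via `label_column`, or from a separate two-column
#' (sample_id, label) or one-label-per-line file via `labels_path`.
#'
#' @param path file path; delimiter inferred from the extension (`.csv` =
#'   comma, otherwise tab) unless `sep` is given.
#' @param task `"classification"` or `"regression"`.
#' @param orientation `"samples"` (samples as rows, default) or `"features"`
#'   (features as rows, GEO series-matrix style).
#' @param label_column name of the label column/row inside the table.
#' @param labels_path separate label file.
#' @param sep field delimiter override.
#' @return `list(X = fs_matrix, y = fs_outcome)`; `y` is NULL when no label
#'   source is given.
#' @export
read_feature_table <- function(path, task = c("classification", "regression"),
                               orientation = c("samples", "features"),
                               label_column = NULL, labels_path = NULL,
                               sep = NULL) {
  task <- match.arg(task)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    fs_validation_stop("fs_io_error", sprintf("file not found: %s", path))
  }
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                      na.strings = c("NA", ""), stringsAsFactors = FALSE),
    error = function(e) fs_stop("fs_io_error",
      sprintf("failed to parse %s: %s", path, conditionMessage(e))))
  if (ncol(df) < 2L) fs_stop("fs_io_error", "table needs an id column plus data columns")
  row_ids <- as.character(df[[1L]])
  if (anyDuplicated(row_ids)) {
    fs_validation_stop("fs_duplicate_id_error",
      sprintf("duplicate row id at line %d", which(duplicated(row_ids))[1L] + 1L))
  }
  body <- df[, -1L, drop = FALSE]

  labels <- NULL
  if (!is.null(label_column)) {
    if (orientation == "samples") {
      if (!label_column %in% colnames(body)) {
        fs_validation_stop("fs_io_error",
          sprintf("label column '%s' absent from %s", label_column, path))
      }
      labels <- body[[label_column]]
      body <- body[, setdiff(colnames(body), label_column), drop = FALSE]
    } else {
      hit <- which(row_ids == label_column)
      if (!length(hit)) {
        fs_validation_stop("fs_io_error",
          sprintf("label row '%s' absent from %s", label_column, path))
      }
      labels <- unlist(body[hit, ], use.names = FALSE)
      body <- body[-hit, , drop = FALSE]
      row_ids <- row_ids[-hit]
    }
  }
  M <- as.matrix(as.data.frame(lapply(body, as.numeric), check.names = FALSE))
  if (orientation == "samples") {
    X <- feature_matrix(M, sample_ids = row_ids, feature_ids = colnames(body))
  } else {
    X <- feature_matrix(t(M), sample_ids = colnames(body), feature_ids = row_ids)
  }
  if (!is.null(labels_path)) {
    if (!is.null(labels)) {
      fs_validation_stop("fs_io_error", "give either label_column or labels_path, not both")
    }
    labels <- read_labels_file(labels_path, sample_ids(X))
  }
  y <- if (is.null(labels)) NULL else outcome(labels, task)
  if (!is.null(y)) validate_pair(X, y)
  list(X = X, y = y)
}

read_labels_file <- function(path, ids) {
  if (!file.exists(path)) {
    fs_validation_stop("fs_io_error", sprintf("labels file not found: %s", path))
  }
  first <- readLines(path, n = 1L)
  if (grepl("\t|,", first)) {
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.delim(path, sep = sep, header = FALSE,
                            stringsAsFactors = FALSE)
    lab <- stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
    missing <- setdiff(ids, names(lab))
    if (length(missing)) {
      fs_validation_stop("fs_io_error",
        sprintf("labels file lacks sample(s): %s",
                paste(utils::head(missing, 5L), collapse = ", ")))
    }
    unname(lab[ids])
  } else {
    readLines(path)
  }
}

#' Write a feature table (and labels) to TSV/CSV
#'
#' Inverse of [read_feature_table()]: writes the matrix in the requested
#' orientation with a `label` column/row when an outcome is supplied.
#' Missing cells are written as `NA`.
#'
#' @param X an [feature_matrix()].
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @param y optional [outcome()] stored in a `label` column/row.
#' @param orientation `"samples"` or `"features"`.
#' @export
write_feature_table <- function(X, path, y = NULL,
                                orientation = c("samples", "features")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  M <- unclass(X)
  if (orientation == "samples") {
    df <- data.frame(sample_id = rownames(M), check.names = FALSE)
    if (!is.null(y)) df$label <- as.character(y$values)
    df <- cbind(df, as.data.frame(M, check.names = FALSE))
  } else {
    body <- t(M)
    if (!is.null(y)) body <- rbind(label = as.character(y$values), body)
    df <- data.frame(feature_id = rownames(body), check.names = FALSE)
    df <- cbind(df, as.data.frame(body, check.names = FALSE))
    colnames(df) <- c("feature_id", rownames(M))
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
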