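#' Construct a decision table
#'
#' A decision table holds `n` samples described by numeric condition
#' attributes plus one categorical decision attribute. It is the universe
#' that neighborhood granulation, entropy measures and feature selection
#' operate on.
#'
#' @param values Numeric matrix or data frame, samples in rows, condition
#'   attributes in columns. Column names become the feature names; unnamed
#'   columns are named `f1`, `f2`, ...
#' @param labels Vector of decision values, one per sample. Any categorical
#'   type is accepted; values are mapped to classes in first-appearance order.
#' @param sample_ids Optional character vector of sample identifiers; defaults
#'   to the row names of `values`, or `s1`, `s2`, ...
#'
#' @return An object of class `decision_table`: a list with elements
#'   `values` (numeric matrix), `labels` (factor with levels in
#'   first-appearance order) and `sample_ids`.
#'
#' @details Missing values and non-numeric condition attributes are rejected:
#'   the neighborhood model is defined for complete continuous data only.
#'   Feature names must be unique.
#'
#' @examples
#' dt <- decision_table(matrix(runif(20), 10, 2), rep(c("a", "b"), 5))
#' dt
#' @seealso [normalize_min_max()], [neighborhood_system()], [read_decision_table()]
#' @export
decision_table <- function(values, labels, sample_ids = NULL) {
  if (is.data.frame(values)) {
    non_num <- names(values)[!vapply(values, is.numeric, logical(1))]
    if (length(non_num) > 0L) {
      stop("non-numeric condition attribute(s): ", paste(non_num, collapse = ", "),
           call. = FALSE)
    }
    values <- as.matrix(values)
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix or all-numeric data frame", call. = FALSE)
  }
  if (nrow(values) == 0L) stop("decision table has no samples", call. = FALSE)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at sample %d, feature %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (length(labels) != nrow(values)) {
    stop("'labels' must have one entry per sample", call. = FALSE)
  }
  if (anyNA(labels)) stop("missing decision label(s)", call. = FALSE)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) {
    stop("feature names must be unique", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  }
  rownames(values) <- NULL
  labels <- as.character(labels)
  structure(
    list(values = values,
         labels = factor(labels, levels = unique(labels)),
         sample_ids = as.character(sample_ids)),
    class = "decision_table"
  )
}

#' @export
print.decision_table <- function(x, ...) {
  cat(sprintf("Decision table: %d samples, %d features, %d classes\n",
              nrow(x$values), ncol(x$values), nlevels(x$labels)))
  cat("  features:", paste(utils::head(colnames(x$values), 8L), collapse = ", "),
      if (ncol(x$values) > 8L) "..." else "", "\n")
  cat("  classes: ",
      paste(sprintf("%s (%d)", levels(x$labels), tabulate(x$labels)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.decision_table <- function(x) dim(x$values)

#' Min-max normalize a decision table
#'
#' Rescales every condition attribute to `[0, 1]` by `(x - min) / (max - min)`,
#' with the minimum and maximum taken over that column of the full table.
#' A constant column (max = min) maps to all zeros, keeping it inert rather
#' than failing. Labels are unchanged.
#'
#' Normalization statistics are computed once on the whole table; when the
#' table is later split for cross-validation this reproduces the standard
#' whole-table protocol and is mildly optimistic relative to fitting the
#' scaler on training folds only.
#'
#' @param table A [decision_table].
#' @return A [decision_table] with all values in `[0, 1]`.
#' @examples
#' dt <- decision_table(cbind(x = c(0.12, 0.21, 0.31, 0.61)), c("Y", "Y", "N", "N"))
#' normalize_min_max(dt)$values
#' @export
normalize_min_max <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  v <- table$values
  mins <- apply(v, 2L, min)
  maxs <- apply(v, 2L, max)
  rng <- maxs - mins
  out <- sweep(v, 2L, mins, "-")
  keep <- rng > 0
  out[, keep] <- sweep(out[, keep, drop = FALSE], 2L, rng[keep], "/")
  out[, !keep] <- 0
  table$values <- out
  table
}

#' The four-sample worked-example decision table
#'
#' A tiny decision table with three condition attributes (`a`, `b`, `c`) and a
#' binary decision (`Y`/`N`), used throughout the documentation and tests to
#' replay every quantity of the method by hand: granules, approximate
#' precision, each entropy, and the greedy selection that picks `{c, a}` at
#' radius 0.3.
#'
#' @return A [decision_table] with 4 samples and 3 features.
#' @examples
#' toy_decision_table()
#' @export
toy_decision_table <- function() {
  decision_table(
    values = matrix(
      c(0.12, 0.41, 0.61,
        0.21, 0.15, 0.14,
        0.31, 0.11, 0.26,
        0.61, 0.13, 0.23),
      nrow = 4L, byrow = TRUE,
      dimnames = list(NULL, c("a", "b", "c"))
    ),
    labels = c("Y", "Y", "N", "N"),
    sample_ids = paste0("x", 1:4)
  )
}

#' Read a decision table from CSV or ARFF
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"arff"`; the default guesses from the file
#'   extension (falling back to CSV).
#' @param label_column Name of the decision column. Default: the last column.
#' @param sep Field delimiter for CSV input.
#' @return A [decision_table].
#' @details All condition columns must be numeric and complete; violations are
#'   reported with the offending row/column. ARFF files are read with
#'   \pkg{foreign}; the nominal class attribute (by default the last) is taken
#'   as the decision.
#' @examples
#' path <- file.path(tempdir(), "toy.csv")
#' write_decision_table(toy_decision_table(), path)
#' read_decision_table(path)
#' @export
read_decision_table <- function(path, format = c("auto", "csv", "arff"),
                                label_column = NULL, sep = ",") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  df <- switch(format,
    csv = utils::read.csv(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE),
    arff = foreign::read.arff(path)
  )
  if (nrow(df) == 0L) stop("no samples in ", path, call. = FALSE)
  if (is.null(label_column)) label_column <- names(df)[ncol(df)]
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in ", path, call. = FALSE)
  }
  labels <- df[[label_column]]
  cond <- df[, setdiff(names(df), label_column), drop = FALSE]
  for (j in seq_along(cond)) {
    if (!is.numeric(cond[[j]])) {
      stop(sprintf("condition attribute '%s' is not numeric", names(cond)[j]),
           call. = FALSE)
    }
    if (anyNA(cond[[j]])) {
      stop(sprintf("missing value at row %d, column '%s'",
                   which(is.na(cond[[j]]))[1L], names(cond)[j]), call. = FALSE)
    }
  }
  if (anyNA(labels)) {
    stop(sprintf("missing decision label at row %d", which(is.na(labels))[1L]),
         call. = FALSE)
  }
  decision_table(cond, labels)
}

#' Write a decision table to CSV or ARFF
#'
#' The decision column is written last, named `class` (CSV keeps the label
#' column name `class` so a round trip through [read_decision_table()] with
#' defaults recovers the table).
#'
#' @param table A [decision_table].
#' @param path Output path.
#' @param format `"csv"` or `"arff"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_decision_table <- function(table, path, format = c("auto", "csv", "arff")) {
  stopifnot(inherits(table, "decision_table"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  df <- as.data.frame(table$values)
  df$class <- table$labels
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    foreign::write.arff(df, path)
  }
  invisible(path)
}
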