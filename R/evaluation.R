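# Run an expression with a private RNG stream so harness seeding never
# disturbs the caller's random state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' k-nearest-neighbor prediction (Euclidean, majority vote)
#'
#' Majority vote over the `k` nearest training samples in Euclidean
#' distance; a tied vote is broken in favor of the class of the single
#' nearest neighbor.
#'
#' @param train Numeric training matrix (rows = samples).
#' @param labels Factor of training labels.
#' @param test Numeric matrix of query samples over the same columns.
#' @param k Number of neighbors (capped at the training size).
#' @return Factor of predicted labels with the training levels.
#' @export
knn_predict <- function(train, labels, test, k = 3) {
  train <- as.matrix(train); test <- as.matrix(test)
  labels <- as.factor(labels)
  k <- min(k, nrow(train))
  out <- character(nrow(test))
  for (q in seq_len(nrow(test))) {
    d <- sqrt(colSums((t(train) - test[q, ])^2))
    nn <- order(d)[seq_len(k)]
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    out[q] <- if (length(top) == 1L) top else as.character(labels[nn[1L]])
  }
  factor(out, levels = levels(labels))
}

#' Built-in classifier contracts
#'
#' A classifier contract is a list with a `name` and a `fit(x, y)` function
#' returning a `predict(newx)` function whose output is one training-level
#' label per query row. External classifiers (e.g. SVM or decision trees
#' from another package) can be plugged into [cross_validate()] and
#' [radius_sweep()] through the same shape; the package itself ships only
#' the 3-NN rule so the harness has no external ML dependency.
#'
#' @param k Number of neighbors.
#' @return A classifier contract list.
#' @examples
#' cl <- knn_classifier(3)
#' pr <- cl$fit(matrix(c(0, 0, 1, 1), 2), factor(c("a", "b")))
#' pr(matrix(c(0.1, 0.1), 1))
#' @export
knn_classifier <- function(k = 3) {
  force(k)
  list(
    name = sprintf("%d-NN", k),
    fit = function(x, y) {
      x <- as.matrix(x); y <- as.factor(y)
      function(newx) knn_predict(x, y, newx, k = k)
    }
  )
}

# Fold assignment: stratified within classes when each class has at least k
# samples, otherwise plain folds with a warning. Samples are put in canonical
# order by sample_id first so the assignment is invariant to row permutations.
make_folds <- function(labels, sample_ids, k, seed) {
  n <- length(labels)
  canon <- order(sample_ids)
  folds <- integer(n)
  with_seed(seed, {
    if (min(table(labels)) < k) {
      warning("a class has fewer samples than folds; using non-stratified folds",
              call. = FALSE)
      folds[canon] <- sample(rep_len(seq_len(k), n))
    } else {
      for (lev in levels(labels)) {
        idx <- canon[labels[canon] == lev]
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
  })
  folds
}

#' Cross-validated accuracy of a classifier on a feature subset
#'
#' Stratified k-fold cross-validation: folds are drawn within each class
#' (driven by `seed`), the classifier is fitted on the training folds and
#' scored on the held-out fold, and the overall fraction of correctly
#' predicted samples is returned. When a class has fewer samples than
#' folds, plain (non-stratified) folds are used with a warning. Setting
#' `k = n` gives leave-one-out.
#'
#' @param table A [decision_table] (use normalized values for distance-based
#'   classifiers).
#' @param features Feature subset (indices or names) the classifier sees.
#' @param classifier A classifier contract, e.g. [knn_classifier()].
#' @param k Number of folds (`>= 2`).
#' @param seed Integer seed driving the fold assignment.
#' @return Accuracy in `[0, 1]`.
#' @examples
#' dt <- generate_table(synthetic_spec(n_samples = 40, class_separation = 8))$table
#' cross_validate(dt, c(1, 2), knn_classifier(3), k = 5, seed = 1)
#' @export
cross_validate <- function(table, features, classifier, k = 10, seed = 1) {
  stopifnot(inherits(table, "decision_table"), k >= 2)
  if (length(features) == 0L) stop("'features' must be non-empty", call. = FALSE)
  nm <- colnames(table$values)
  if (is.character(features)) features <- match(features, nm)
  x <- table$values[, features, drop = FALSE]
  y <- droplevels(table$labels)
  n <- nrow(x)
  k <- min(k, n)
  folds <- make_folds(y, table$sample_ids, k, seed)
  correct <- 0L
  for (f in seq_len(k)) {
    te <- folds == f
    if (!any(te)) next
    pred <- classifier$fit(x[!te, , drop = FALSE], y[!te])(x[te, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == as.character(y[te]))
  }
  correct / n
}

#' Radius sweep: selection size and accuracy across neighborhood radii
#'
#' For each radius in `grid`, runs the greedy selection on the full
#' normalized table and cross-validates each classifier on the selected
#' subset. This whole-table protocol (select once, then cross-validate) is
#' the standard way these selectors are profiled; it is optimistic relative
#' to re-selecting inside each training fold. When a radius selects nothing,
#' the row records the majority-class baseline accuracy and 0 features.
#'
#' @param table A [decision_table].
#' @param grid Strictly positive radii; default `seq(0.05, 1, by = 0.05)`.
#' @param classifiers List of classifier contracts.
#' @param k Folds for [cross_validate()].
#' @param seed Integer seed for fold assignment.
#' @param p,log_base Passed to the selector.
#' @return An object of class `radius_sweep`: data frame with one row per
#'   radius -- `delta`, `n_selected`, one accuracy column per classifier,
#'   and `mean_accuracy` -- plus the per-radius selections in
#'   `attr(, "selections")`.
#' @examples
#' dt <- generate_table(synthetic_spec(n_samples = 40))$table
#' radius_sweep(dt, grid = c(0.1, 0.2), k = 5, seed = 1)
#' @export
radius_sweep <- function(table, grid = seq(0.05, 1, by = 0.05),
                         classifiers = list(knn_classifier(3)),
                         k = 10, seed = 1, p = 2, log_base = 10) {
  stopifnot(inherits(table, "decision_table"),
            length(grid) > 0, all(grid > 0))
  grid <- sort(grid)
  table <- normalize_min_max(table)
  cl_names <- vapply(classifiers, `[[`, character(1), "name")
  majority <- max(tabulate(table$labels)) / nrow(table$values)
  rows <- lapply(grid, function(delta) {
    fit <- bonje(table, delta = delta, p = p, log_base = log_base,
                 normalize = FALSE)
    if (length(fit$selected) > 0L) {
      acc <- vapply(classifiers, function(cl) {
        cross_validate(table, fit$selected, cl, k = k, seed = seed)
      }, numeric(1))
    } else {
      acc <- rep(majority, length(classifiers))
    }
    names(acc) <- cl_names
    list(row = data.frame(delta = delta, n_selected = length(fit$selected),
                          t(acc), mean_accuracy = mean(acc),
                          check.names = FALSE),
         selection = fit$feature_names)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  attr(out, "selections") <- lapply(rows, `[[`, "selection")
  class(out) <- c("radius_sweep", "data.frame")
  out
}

#' @export
plot.radius_sweep <- function(x, ...) {
  op <- graphics::par(mar = c(5, 4, 4, 4) + 0.1)
  on.exit(graphics::par(op))
  graphics::plot(x$delta, x$n_selected, type = "b", pch = 19,
                 xlab = expression(delta), ylab = "features selected",
                 main = "Radius sweep", ...)
  graphics::par(new = TRUE)
  graphics::plot(x$delta, x$mean_accuracy, type = "b", pch = 17, lty = 2,
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1),
                 col = "grey40")
  graphics::axis(4, col.axis = "grey40")
  graphics::mtext("mean accuracy", side = 4, line = 2.5, col = "grey40")
  invisible(x)
}

#' Write sweep results to TSV or JSON
#'
#' @param x A [radius_sweep()] result.
#' @param path Output path; `.json` selects JSON, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
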