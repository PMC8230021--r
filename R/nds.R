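#' Construct a neighborhood decision system
#'
#' Wraps a [decision_table] whose values lie in `[0, 1]` together with a
#' neighborhood radius `delta` and a Minkowski order `p`. Two samples are
#' neighbors on an attribute subset `B` when their Minkowski distance over
#' `B` is at most `delta` (inclusive boundary), so the radius controls the
#' granularity at which the continuous attributes discern samples.
#'
#' @param table A [decision_table]. Set `normalize = TRUE` (default) to
#'   min-max normalize first; with `normalize = FALSE` the values must
#'   already be in `[0, 1]`.
#' @param delta Neighborhood radius, a non-negative real.
#' @param p Minkowski order, a real `>= 1`. `p = 2` (Euclidean) is the
#'   conventional choice.
#' @param normalize Apply [normalize_min_max()] to the table first?
#' @return An object of class `nds`: list with `table`, `delta`, `p`.
#' @examples
#' nds <- neighborhood_system(toy_decision_table(), delta = 0.3)
#' neighborhood_granule(nds, 4, "a")
#' @export
neighborhood_system <- function(table, delta, p = 2, normalize = TRUE) {
  stopifnot(inherits(table, "decision_table"))
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0) {
    stop("'delta' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || p < 1) {
    stop("'p' must be a single number >= 1", call. = FALSE)
  }
  if (normalize) table <- normalize_min_max(table)
  v <- table$values
  if (min(v) < 0 || max(v) > 1) {
    stop("values must lie in [0, 1]; use normalize = TRUE", call. = FALSE)
  }
  structure(list(table = table, delta = delta, p = p), class = "nds")
}

#' @export
print.nds <- function(x, ...) {
  cat(sprintf("Neighborhood decision system: delta = %g, p = %g\n",
              x$delta, x$p))
  print(x$table)
  invisible(x)
}

n_samples <- function(nds) nrow(nds$table$values)

# Resolve a feature subset given by index or name to validated integer indices.
resolve_features <- function(nds, B) {
  nm <- colnames(nds$table$values)
  if (is.character(B)) {
    idx <- match(B, nm)
    if (anyNA(idx)) {
      stop("unknown feature(s): ", paste(B[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
  } else {
    idx <- as.integer(B)
    if (length(idx) && (min(idx) < 1L || max(idx) > length(nm))) {
      stop("feature index out of range", call. = FALSE)
    }
  }
  if (length(idx) == 0L) {
    stop("attribute subset B must be non-empty", call. = FALSE)
  }
  idx
}

#' Minkowski distance between two samples on an attribute subset
#'
#' `(sum_k |x_ik - x_jk|^p)^(1/p)` over the attributes in `B`.
#'
#' @param nds A [neighborhood_system()].
#' @param i,j Sample indices (1-based).
#' @param B Feature subset: integer indices or feature names; must be
#'   non-empty.
#' @return A single non-negative number.
#' @examples
#' nds <- neighborhood_system(toy_decision_table(), delta = 0.3)
#' minkowski_distance(nds, 1, 2, "a")  # 0.09
#' @export
minkowski_distance <- function(nds, i, j, B) {
  stopifnot(inherits(nds, "nds"))
  B <- resolve_features(nds, B)
  d <- abs(nds$table$values[i, B] - nds$table$values[j, B])
  sum(d^nds$p)^(1 / nds$p)
}

# Full pairwise Minkowski distance matrix over feature subset B (validated
# indices). The granule cache and every entropy measure are built on this.
distance_matrix <- function(nds, B) {
  v <- nds$table$values[, B, drop = FALSE]
  n <- nrow(v)
  p <- nds$p
  acc <- matrix(0, n, n)
  for (k in seq_along(B)) {
    acc <- acc + abs(outer(v[, k], v[, k], "-"))^p
  }
  acc^(1 / p)
}

# Neighborhood granules for every sample at once: list of index vectors
# {j : dist(i, j, B) <= delta}. Inclusive boundary, direct float comparison.
granules_for <- function(nds, B) {
  d <- distance_matrix(nds, B)
  lapply(seq_len(nrow(d)), function(i) which(d[i, ] <= nds$delta))
}

#' Neighborhood information granule of a sample
#'
#' The set of samples whose Minkowski distance from sample `i`, measured on
#' attribute subset `B`, is at most `delta`. The boundary is inclusive, so a
#' sample exactly at distance `delta` is a neighbor; `i` always belongs to
#' its own granule.
#'
#' @inheritParams minkowski_distance
#' @return Sorted integer vector of sample indices.
#' @examples
#' nds <- neighborhood_system(toy_decision_table(), delta = 0.3)
#' neighborhood_granule(nds, 4, "a")  # samples 3 and 4
#' @export
neighborhood_granule <- function(nds, i, B) {
  stopifnot(inherits(nds, "nds"))
  B <- resolve_features(nds, B)
  v <- nds$table$values
  d <- rowSums(abs(sweep(v[, B, drop = FALSE], 2L,
                         v[i, B], "-"))^nds$p)^(1 / nds$p)
  which(d <= nds$delta)
}

#' Decision class of a sample
#'
#' All samples carrying the same decision label as sample `i`. The decision
#' classes partition the universe.
#'
#' @inheritParams minkowski_distance
#' @return Sorted integer vector of sample indices.
#' @export
decision_class <- function(nds, i) {
  stopifnot(inherits(nds, "nds"))
  which(nds$table$labels == nds$table$labels[i])
}

#' Lower and upper approximation of a sample set
#'
#' Under the neighborhood relation on attribute subset `B`, the lower
#' approximation of `X` collects the samples whose whole granule lies inside
#' `X`; the upper approximation collects those whose granule touches `X`.
#'
#' @inheritParams minkowski_distance
#' @param X Integer vector of sample indices (the target set).
#' @return List with sorted integer vectors `lower` and `upper`;
#'   `lower` is always a subset of `upper`.
#' @export
lower_upper_approximation <- function(nds, B, X) {
  stopifnot(inherits(nds, "nds"))
  B <- resolve_features(nds, B)
  X <- as.integer(X)
  g <- granules_for(nds, B)
  inside <- vapply(g, function(gi) all(gi %in% X), logical(1))
  touches <- vapply(g, function(gi) any(gi %in% X), logical(1))
  list(lower = which(inside), upper = which(touches))
}

#' Neighborhood approximate precision of the decision
#'
#' The ratio `|union of lower approximations| / |union of upper
#' approximations|` taken over the decision classes. It measures, from the
#' algebraic view, how consistently the attributes in `B` discern the
#' classes: 1 when every granule is pure, 0 when no granule is.
#'
#' Since every granule contains its own sample, the upper union is the whole
#' universe and the denominator is always positive.
#'
#' @inheritParams minkowski_distance
#' @return A number in `[0, 1]`.
#' @examples
#' nds <- neighborhood_system(toy_decision_table(), delta = 0.3)
#' approximate_precision(nds, "a")  # 0.25
#' @export
approximate_precision <- function(nds, B) {
  stopifnot(inherits(nds, "nds"))
  B <- resolve_features(nds, B)
  labels <- nds$table$labels
  g <- granules_for(nds, B)
  lower_n <- 0L
  upper <- logical(length(g))
  for (lev in levels(labels)) {
    X <- which(labels == lev)
    inside <- vapply(g, function(gi) all(labels[gi] == lev), logical(1))
    touches <- vapply(g, function(gi) any(labels[gi] == lev), logical(1))
    lower_n <- lower_n + sum(inside)
    upper <- upper | touches
  }
  lower_n / sum(upper)
}
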