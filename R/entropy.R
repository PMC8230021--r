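#' Joint neighborhood information granule
#'
#' The union of sample `i`'s neighborhood granule on `B` with its decision
#' class. It augments the metric neighborhood with the class information, so
#' its size reflects how much of the class structure the neighborhood already
#' captures.
#'
#' @inheritParams minkowski_distance
#' @return Sorted integer vector of sample indices.
#' @examples
#' nds <- neighborhood_system(toy_decision_table(), delta = 0.3)
#' joint_granule(nds, 1, "a")  # samples 1, 2, 3
#' @export
joint_granule <- function(nds, i, B) {
  sort(union(neighborhood_granule(nds, i, B), decision_class(nds, i)))
}

#' Neighborhood credibility and coverage of a sample
#'
#' Per-sample sufficiency and necessity measures of the neighborhood with
#' respect to the decision: credibility is `|granule n class| / |joint
#' granule|`, coverage is `|granule n class| / |class|`. Both lie in
#' `(0, 1]` because every granule and class contain the sample itself.
#'
#' @inheritParams minkowski_distance
#' @return Named numeric vector `c(credibility = , coverage = )`.
#' @export
credibility_coverage <- function(nds, i, B) {
  g <- neighborhood_granule(nds, i, B)
  cls <- decision_class(nds, i)
  int <- length(intersect(g, cls))
  joint <- length(union(g, cls))
  c(credibility = int / joint, coverage = int / length(cls))
}

# Shared per-subset cache: granule sizes, class sizes, intersection and joint
# sizes, and the approximate precision, computed from one distance matrix.
# Every entropy measure reads from this so the greedy search never recomputes
# distances for the same B.
subset_measures <- function(nds, B) {
  B <- resolve_features(nds, B)
  labels <- nds$table$labels
  n <- length(labels)
  g <- granules_for(nds, B)
  class_idx <- lapply(levels(labels), function(lev) which(labels == lev))
  cls_of <- as.integer(labels)
  class_size <- lengths(class_idx)[cls_of]
  granule_size <- lengths(g)
  inter_size <- vapply(seq_len(n), function(i) {
    sum(labels[g[[i]]] == labels[i])
  }, integer(1))
  joint_size <- granule_size + class_size - inter_size
  pure <- inter_size == granule_size   # granule entirely inside its class
  precision <- sum(pure) / n           # upper union is always the universe
  list(granule_size = granule_size, class_size = class_size,
       inter_size = inter_size, joint_size = joint_size,
       precision = precision, n = n)
}

#' Classic average neighborhood entropy
#'
#' `-(1/n) * sum_i log(|granule_i| / n)`: the average information content of
#' the neighborhood granulation alone, ignoring the decision. Zero when every
#' granule is the whole universe; `log(n)` when every granule is a singleton.
#'
#' @inheritParams minkowski_distance
#' @param log_base Base of the logarithm (default 10).
#' @return A non-negative number.
#' @export
classic_neighborhood_entropy <- function(nds, B, log_base = 10) {
  m <- subset_measures(nds, B)
  -mean(log(m$granule_size / m$n, base = log_base))
}

#' Average neighborhood entropy (precision-weighted)
#'
#' `H_delta(B) = -(P_B(D)/n) * sum_i log(|granule_i| / |joint granule_i|)`.
#' Replacing the universe with the joint granule in the classic form makes
#' the measure decision-aware, and the approximate-precision weight `P_B(D)`
#' ties the information-theoretic view to the algebraic one.
#'
#' @inheritParams classic_neighborhood_entropy
#' @return A non-negative number; exactly 0 when `P_B(D) = 0`.
#' @export
average_neighborhood_entropy <- function(nds, B, log_base = 10) {
  m <- subset_measures(nds, B)
  if (m$precision == 0) return(0)
  -(m$precision / m$n) *
    sum(log(m$granule_size / m$joint_size, base = log_base))
}

#' Neighborhood conditional entropy of the decision given B
#'
#' `H_delta(D|B) = -(P_B(D)/n) * sum_i log(|granule_i n class_i|^2 /
#' (|granule_i| * |class_i|))`. Non-negative because the intersection is at
#' most each of the two sizes. Zero when every granule coincides with its
#' class and the precision is 1 -- i.e. when `B` leaves no uncertainty about
#' the decision.
#'
#' @inheritParams classic_neighborhood_entropy
#' @return A non-negative number; exactly 0 when `P_B(D) = 0`.
#' @export
neighborhood_conditional_entropy <- function(nds, B, log_base = 10) {
  m <- subset_measures(nds, B)
  if (m$precision == 0) return(0)
  -(m$precision / m$n) *
    sum(log(m$inter_size^2 / (m$granule_size * m$class_size),
            base = log_base))
}

#' Neighborhood joint entropy of the decision and B
#'
#' The selection criterion of the method:
#' `H_delta(D,B) = -(P_B(D)/n) * sum_i log(|granule_i n class_i|^2 /
#' (|joint granule_i| * |class_i|))`, equivalently
#' `-(P_B(D)/n) * sum_i log(credibility_i * coverage_i)`.
#' It fuses the algebraic view (the approximate-precision weight) with the
#' information-theoretic view (the credibility/coverage entropy). A larger
#' value means `B` carries more decision information; it is not monotone
#' under growing `B`, which is why the greedy search stops at the first
#' step with no strict improvement.
#'
#' @inheritParams classic_neighborhood_entropy
#' @return A non-negative number; exactly 0 when `P_B(D) = 0`.
#' @examples
#' nds <- neighborhood_system(toy_decision_table(), delta = 0.3)
#' round(neighborhood_joint_entropy(nds, "a"), 3)        # 0.041
#' round(neighborhood_joint_entropy(nds, c("a", "c")), 3)  # 0.345
#' @export
neighborhood_joint_entropy <- function(nds, B, log_base = 10) {
  m <- subset_measures(nds, B)
  if (m$precision == 0) return(0)
  -(m$precision / m$n) *
    sum(log(m$inter_size^2 / (m$joint_size * m$class_size),
            base = log_base))
}

#' Significance of an attribute relative to a subset
#'
#' The gain in neighborhood joint entropy from adding attribute `b` to `B`:
#' `Sig(b, B, D) = H_delta(D, B u {b}) - H_delta(D, B)`, with the convention
#' `Sig(b, {}, D) = H_delta(D, {b})`. May be negative: the joint entropy is
#' non-monotonic in `B`.
#'
#' @inheritParams classic_neighborhood_entropy
#' @param b A single feature (index or name), not already in `B`.
#' @param B Feature subset (possibly empty: `NULL` or `integer(0)`).
#' @return A real number (any sign).
#' @export
significance <- function(nds, b, B = NULL, log_base = 10) {
  stopifnot(inherits(nds, "nds"))
  b <- resolve_features(nds, b)
  if (length(b) != 1L) stop("'b' must be a single attribute", call. = FALSE)
  if (is.null(B) || length(B) == 0L) {
    return(neighborhood_joint_entropy(nds, b, log_base))
  }
  B <- resolve_features(nds, B)
  if (b %in% B) stop("'b' is already in B", call. = FALSE)
  neighborhood_joint_entropy(nds, c(B, b), log_base) -
    neighborhood_joint_entropy(nds, B, log_base)
}

#' Per-sample audit of the neighborhood measures for a subset
#'
#' Replays, for every sample, the quantities the entropy measures are built
#' from -- granule, joint granule, credibility, coverage -- together with the
#' approximate precision and all four entropies, formatted for auditing a
#' hand calculation.
#'
#' @inheritParams classic_neighborhood_entropy
#' @return An object of class `nds_explain`: list with `per_sample` (data
#'   frame), `granules` and `joint_granules` (lists of index vectors),
#'   `precision`, `entropies` (named numeric vector), `B` (feature names),
#'   `delta`, `log_base`.
#' @examples
#' explain_subset(neighborhood_system(toy_decision_table(), 0.3), "a")
#' @export
explain_subset <- function(nds, B, log_base = 10) {
  stopifnot(inherits(nds, "nds"))
  B <- resolve_features(nds, B)
  m <- subset_measures(nds, B)
  n <- m$n
  g <- granules_for(nds, B)
  cls <- lapply(seq_len(n), function(i) decision_class(nds, i))
  jg <- lapply(seq_len(n), function(i) sort(union(g[[i]], cls[[i]])))
  per_sample <- data.frame(
    sample = nds$table$sample_ids,
    label = as.character(nds$table$labels),
    granule_size = m$granule_size,
    class_size = m$class_size,
    intersection_size = m$inter_size,
    joint_granule_size = m$joint_size,
    credibility = m$inter_size / m$joint_size,
    coverage = m$inter_size / m$class_size,
    stringsAsFactors = FALSE
  )
  entropies <- c(
    classic = classic_neighborhood_entropy(nds, B, log_base),
    average = average_neighborhood_entropy(nds, B, log_base),
    conditional = neighborhood_conditional_entropy(nds, B, log_base),
    joint = neighborhood_joint_entropy(nds, B, log_base)
  )
  structure(
    list(per_sample = per_sample, granules = g, joint_granules = jg,
         precision = m$precision, entropies = entropies,
         B = colnames(nds$table$values)[B], delta = nds$delta,
         log_base = log_base),
    class = "nds_explain"
  )
}

#' @export
print.nds_explain <- function(x, digits = 4, ...) {
  fmt_set <- function(idx, ids) paste0("{", paste(ids[idx], collapse = ","), "}")
  ids <- x$per_sample$sample
  cat(sprintf("Subset B = {%s}, delta = %g, log base %g\n",
              paste(x$B, collapse = ","), x$delta, x$log_base))
  df <- x$per_sample
  df$granule <- vapply(x$granules, fmt_set, character(1), ids = ids)
  df$joint_granule <- vapply(x$joint_granules, fmt_set, character(1), ids = ids)
  print(df[, c("sample", "label", "granule", "joint_granule",
               "credibility", "coverage")],
        digits = digits, row.names = FALSE)
  cat(sprintf("Approximate precision P_B(D) = %.*g\n", digits, x$precision))
  e <- x$entropies
  cat(sprintf("H(B) classic = %.*g | H(B) = %.*g | H(D|B) = %.*g | H(D,B) = %.*g\n",
              digits, e[["classic"]], digits, e[["average"]],
              digits, e[["conditional"]], digits, e[["joint"]]))
  invisible(x)
}
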