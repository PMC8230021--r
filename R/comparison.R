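# Two-tailed Nemenyi critical values q_alpha = q_{alpha, M, Inf} / sqrt(2)
# (studentized range at infinite df over sqrt(2)), M = 2..20, as tabulated
# in Demsar (2006), "Statistical comparisons of classifiers over multiple
# data sets", JMLR 7:1-30, Table 5; reproducible as
# qtukey(1 - alpha, M, Inf) / sqrt(2).
.nemenyi_q <- list(
  "0.05" = c(1.960, 2.343, 2.569, 2.728, 2.850, 2.949, 3.031, 3.102, 3.164,
             3.219, 3.268, 3.313, 3.354, 3.391, 3.426, 3.458, 3.489, 3.517,
             3.544),
  "0.1"  = c(1.645, 2.052, 2.291, 2.459, 2.589, 2.693, 2.780, 2.855, 2.920,
             2.978, 3.030, 3.077, 3.120, 3.159, 3.196, 3.230, 3.261, 3.291,
             3.319)
)

#' Midranks of an accuracy matrix
#'
#' Ranks algorithms within each dataset: rank 1 for the highest accuracy,
#' tied values sharing the average of the positions they span (midranks), so
#' every dataset's ranks sum to `M(M+1)/2`.
#'
#' @param acc Numeric matrix, algorithms in rows, datasets in columns
#'   (values in `[0, 1]`); at least 2 of each.
#' @return List with `ranks` (same shape as `acc`) and `avg_rank`
#'   (row means, named by algorithm).
#' @examples
#' acc <- rbind(A = c(0.9, 0.8), B = c(0.9, 0.7), C = c(0.5, 0.9))
#' rank_with_ties(acc)
#' @export
rank_with_ties <- function(acc) {
  acc <- as.matrix(acc)
  if (nrow(acc) < 2L || ncol(acc) < 2L) {
    stop("need at least 2 algorithms and 2 datasets", call. = FALSE)
  }
  if (anyNA(acc)) stop("accuracy matrix has missing cells", call. = FALSE)
  ranks <- apply(acc, 2L, function(col) rank(-col, ties.method = "average"))
  dimnames(ranks) <- dimnames(acc)
  list(ranks = ranks, avg_rank = rowMeans(ranks))
}

#' Friedman rank statistic
#'
#' `chi2_F = 12 N / (M (M + 1)) * sum_i R_i^2 - 3 N (M + 1)`, where `R_i`
#' is algorithm `i`'s average rank over the `N` datasets and `M` the number
#' of algorithms.
#'
#' @param avg_rank Numeric vector of average ranks (length `M`), e.g. from
#'   [rank_with_ties()].
#' @param N Number of datasets the ranks were averaged over.
#' @return The statistic (non-negative up to rank rounding).
#' @examples
#' friedman_chi2(c(3.5, 4, 4.5, 1.5, 1.5), N = 4)  # 12.8
#' @export
friedman_chi2 <- function(avg_rank, N) {
  M <- length(avg_rank)
  12 * N / (M * (M + 1)) * sum(avg_rank^2) - 3 * N * (M + 1)
}

#' Iman-Davenport F statistic
#'
#' `F_F = (N - 1) chi2_F / (N (M - 1) - chi2_F)`, distributed as F with
#' `M - 1` and `(M - 1)(N - 1)` degrees of freedom under the null that all
#' algorithms perform alike. When the denominator is non-positive the
#' statistic is saturated (`chi2_F` at or beyond its ceiling `N(M-1)`) and
#' `Inf` is returned with a warning.
#'
#' @param chi2 Friedman statistic from [friedman_chi2()].
#' @param N Number of datasets.
#' @param M Number of algorithms.
#' @return The F statistic.
#' @examples
#' iman_davenport_ff(12.8, N = 4, M = 5)  # 12
#' @export
iman_davenport_ff <- function(chi2, N, M) {
  den <- N * (M - 1) - chi2
  if (den <= 0) {
    warning("Friedman statistic saturated: N(M-1) <= chi2; F_F degenerate",
            call. = FALSE)
    return(Inf)
  }
  (N - 1) * chi2 / den
}

#' Nemenyi critical distance
#'
#' `CD = q_alpha * sqrt(M (M + 1) / (6 N))`: two algorithms whose average
#' ranks differ by more than CD are declared significantly different by the
#' Nemenyi post-hoc test. `q_alpha` comes from the embedded two-tailed
#' critical-value table (see the in-source note for its origin).
#'
#' @param M Number of algorithms (2 to 20).
#' @param N Number of datasets.
#' @param alpha Significance level, 0.05 or 0.10.
#' @return List with `alpha`, `q_alpha`, `cd`.
#' @examples
#' nemenyi_cd(M = 5, N = 4, alpha = 0.10)
#' @export
nemenyi_cd <- function(M, N, alpha = 0.10) {
  key <- as.character(alpha)
  if (!key %in% names(.nemenyi_q)) {
    stop("alpha must be 0.05 or 0.1", call. = FALSE)
  }
  if (M < 2L || M > 20L) {
    stop("M must be between 2 and 20 (range of the embedded q table)",
         call. = FALSE)
  }
  q <- .nemenyi_q[[key]][M - 1L]
  list(alpha = alpha, q_alpha = q, cd = q * sqrt(M * (M + 1) / (6 * N)))
}

#' Full algorithm comparison: ranks, Friedman, Iman-Davenport, Nemenyi
#'
#' Runs the rank-based comparison pipeline on an accuracy matrix (or
#' directly on a supplied rank matrix, so published rank tables can be
#' replayed verbatim): midranks per dataset, the Friedman statistic, the
#' Iman-Davenport F with its critical value from the F inverse CDF at
#' `(M - 1, (M - 1)(N - 1))` degrees of freedom, and the Nemenyi critical
#' distance with the pairs of algorithms whose rank gap falls within it.
#'
#' @param acc Accuracy matrix (algorithms x datasets); ignored when `ranks`
#'   is given.
#' @param alpha Significance level (0.05 or 0.10).
#' @param ranks Optional rank matrix (algorithms x datasets) to use as-is.
#' @return An object of class `algorithm_comparison`: list with `ranks`,
#'   `avg_rank`, `M`, `N`, `friedman` (`chi2`, `ff`, `df1`, `df2`,
#'   `f_critical`, `reject_null`), `nemenyi` (plus `similar_pairs`), and
#'   `cd_diagram` (algorithms ordered by average rank).
#' @examples
#' acc <- rbind(A = c(0.9, 0.8, 0.7), B = c(0.85, 0.82, 0.65),
#'              C = c(0.6, 0.5, 0.4))
#' compare_algorithms(acc, alpha = 0.10)
#' @export
compare_algorithms <- function(acc = NULL, alpha = 0.10, ranks = NULL) {
  if (is.null(ranks)) {
    rk <- rank_with_ties(acc)
    ranks <- rk$ranks
  } else {
    ranks <- as.matrix(ranks)
  }
  avg <- rowMeans(ranks)
  M <- nrow(ranks); N <- ncol(ranks)
  if (is.null(names(avg))) names(avg) <- paste0("alg", seq_len(M))
  chi2 <- friedman_chi2(avg, N)
  ff <- iman_davenport_ff(chi2, N, M)
  df1 <- M - 1L
  df2 <- (M - 1L) * (N - 1L)
  f_crit <- stats::qf(1 - alpha, df1, df2)
  nem <- nemenyi_cd(M, N, alpha)
  ord <- order(avg)
  pairs <- utils::combn(M, 2L)
  gap <- abs(avg[pairs[1L, ]] - avg[pairs[2L, ]])
  similar <- which(gap <= nem$cd)
  similar_pairs <- lapply(similar, function(s) {
    names(avg)[pairs[, s]]
  })
  structure(
    list(ranks = ranks, avg_rank = avg, M = M, N = N,
         friedman = list(chi2 = chi2, ff = ff, df1 = df1, df2 = df2,
                         f_critical = f_crit, reject_null = ff > f_crit),
         nemenyi = c(nem, list(similar_pairs = similar_pairs)),
         cd_diagram = data.frame(algorithm = names(avg)[ord],
                                 avg_rank = avg[ord], row.names = NULL)),
    class = "algorithm_comparison"
  )
}

#' @export
print.algorithm_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Comparison of %d algorithms over %d datasets\n", x$M, x$N))
  cat("Average ranks (1 = best):\n")
  print(round(sort(x$avg_rank), digits))
  f <- x$friedman
  cat(sprintf("Friedman chi2 = %.*g; Iman-Davenport F = %.*g on (%d, %d) df\n",
              digits, f$chi2, digits, f$ff, f$df1, f$df2))
  cat(sprintf("F critical at alpha = %g: %.*g -> %s\n",
              x$nemenyi$alpha, digits, f$f_critical,
              if (f$reject_null) "reject equal performance"
              else "no significant difference"))
  cat(sprintf("Nemenyi CD = %.*g (q = %.*g)\n",
              digits, x$nemenyi$cd, digits, x$nemenyi$q_alpha))
  invisible(x)
}

#' @export
plot.algorithm_comparison <- function(x, ...) {
  avg <- sort(x$avg_rank)
  cd <- x$nemenyi$cd
  graphics::plot(avg, seq_along(avg), yaxt = "n", pch = 19,
                 xlab = "average rank", ylab = "",
                 xlim = range(avg) + c(-0.5, 0.5),
                 main = sprintf("Critical difference diagram (CD = %.3g)", cd),
                 ...)
  graphics::axis(2, at = seq_along(avg), labels = names(avg), las = 1,
                 cex.axis = 0.8)
  graphics::segments(avg[1L], 0.5, avg[1L] + cd, 0.5, lwd = 3)
  for (i in seq_along(avg)) {
    within <- which(avg - avg[i] <= cd & avg >= avg[i])
    if (length(within) > 1L) {
      graphics::segments(avg[i], i, avg[max(within)], i, col = "grey60")
    }
  }
  invisible(x)
}

#' Read an accuracy matrix from CSV/TSV
#'
#' First column = algorithm names, remaining columns = datasets.
#'
#' @param path Input path; tab-delimited unless it ends in `.csv`.
#' @return Numeric matrix with algorithm row names.
#' @export
read_accuracy_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
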