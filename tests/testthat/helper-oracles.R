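# Independent brute-force oracles and random-instance generators shared by
# the property tests. Each oracle re-derives its quantity from first
# principles (double loops, explicit set operations) without touching the
# package's cached code paths.

# sample() without the scalar-x surprise: always draws from the vector x.
resample <- function(x, size) x[sample.int(length(x), size)]

# Nested pair B1 strictly inside B2 (B2 of size >= 2) over f features.
nested_subsets <- function(f) {
  B2 <- resample(seq_len(f), sample.int(f - 1L, 1L) + 1L)
  list(B1 = B2[seq_len(sample.int(length(B2) - 1L, 1L))], B2 = B2)
}

# Random small neighborhood decision system with values already in [0, 1].
rand_nds <- function(seed, n_max = 10, f_max = 4, delta = NULL,
                     n_classes = 2) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  f <- sample(2:f_max, 1)
  dt <- decision_table(matrix(runif(n * f), n, f),
                       sample(paste0("k", seq_len(n_classes)), n, replace = TRUE))
  if (is.null(delta)) delta <- sample(seq(0.1, 0.9, by = 0.1), 1)
  neighborhood_system(dt, delta = delta, normalize = FALSE)
}

# Naive granule: explicit double loop over samples and features.
oracle_granule <- function(nds, i, B) {
  v <- nds$table$values
  p <- nds$p
  out <- integer(0)
  for (j in seq_len(nrow(v))) {
    s <- 0
    for (k in B) s <- s + abs(v[i, k] - v[j, k])^p
    if (s^(1 / p) <= nds$delta) out <- c(out, j)
  }
  out
}

# Naive lower/upper approximation from oracle granules.
oracle_approx <- function(nds, B, X) {
  n <- nrow(nds$table$values)
  lower <- integer(0); upper <- integer(0)
  for (i in seq_len(n)) {
    g <- oracle_granule(nds, i, B)
    if (all(g %in% X)) lower <- c(lower, i)
    if (any(g %in% X)) upper <- c(upper, i)
  }
  list(lower = lower, upper = upper)
}

# Naive approximate precision: unions of per-class approximations.
oracle_precision <- function(nds, B) {
  labels <- nds$table$labels
  low <- integer(0); up <- integer(0)
  for (lev in levels(labels)) {
    ap <- oracle_approx(nds, B, which(labels == lev))
    low <- union(low, ap$lower)
    up <- union(up, ap$upper)
  }
  length(low) / length(up)
}

# Midranks by sorting and averaging tied positions (descending values).
oracle_midrank <- function(x) {
  ord <- order(-x)
  r <- numeric(length(x))
  pos <- 1L
  while (pos <= length(x)) {
    tied <- which(x[ord] == x[ord[pos]])
    r[ord[tied]] <- mean(tied)
    pos <- max(tied) + 1L
  }
  r
}

# Exhaustive k-NN with the package's contract: Euclidean, majority vote,
# ties to the class of the single nearest neighbor.
oracle_knn <- function(train, labels, test, k = 3) {
  labels <- as.factor(labels)
  out <- character(nrow(test))
  for (q in seq_len(nrow(test))) {
    d <- numeric(nrow(train))
    for (i in seq_len(nrow(train))) {
      d[i] <- sqrt(sum((train[i, ] - test[q, ])^2))
    }
    nn <- order(d)[seq_len(min(k, length(d)))]
    tab <- table(labels[nn])
    winners <- names(tab)[tab == max(tab)]
    out[q] <- if (length(winners) == 1L) winners else
      as.character(labels[nn[1L]])
  }
  factor(out, levels = levels(labels))
}

toy_nds <- function(delta = 0.3, p = 2) {
  neighborhood_system(toy_decision_table(), delta = delta, p = p,
                      normalize = FALSE)
}
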