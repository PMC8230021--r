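test_that("midranks reproduce the published tie convention", {
  # WDBC row: accuracies (0.911, 0.923, 0.923, 0.930, 0.960)
  acc <- cbind(wdbc = c(0.911, 0.923, 0.923, 0.930, 0.960),
               other = c(0.5, 0.6, 0.7, 0.8, 0.9))
  rk <- rank_with_ties(acc)
  expect_equal(unname(rk$ranks[, "wdbc"]), c(5, 3.5, 3.5, 2, 1))
  # full tie: everyone gets (M+1)/2
  tied <- matrix(0.8, 5, 2)
  expect_equal(unname(rank_with_ties(tied)$ranks[, 1]), rep(3, 5))
  expect_error(rank_with_ties(matrix(1, 1, 3)), "at least 2")
})

test_that("midranks agree with a sort-and-average oracle and conserve rank sums", {
  for (seed in 1:20) {
    set.seed(seed)
    M <- sample(2:6, 1); N <- sample(2:5, 1)
    acc <- matrix(sample(seq(0.5, 0.9, by = 0.1), M * N, replace = TRUE), M, N)
    rk <- rank_with_ties(acc)
    for (j in seq_len(N)) {
      expect_equal(unname(rk$ranks[, j]), oracle_midrank(acc[, j]))
      expect_equal(sum(rk$ranks[, j]), M * (M + 1) / 2)
    }
    expect_equal(rk$avg_rank, rowMeans(rk$ranks))
  }
})

test_that("Friedman statistic reproduces the published pairs", {
  # low-dimensional comparison, 5 algorithms x 4 datasets
  expect_equal(friedman_chi2(c(3.5, 4, 4.5, 1.5, 1.5), N = 4), 12.8)
  expect_equal(friedman_chi2(c(2.25, 4.25, 3.5, 3.5, 1.5), N = 4), 7.8)
  # high-dimensional comparison, 5 algorithms x 5 datasets
  expect_equal(friedman_chi2(c(4, 4.6, 3.4, 1.7, 1.3), N = 5), 16.6)
  expect_equal(friedman_chi2(c(3.8, 4, 3.8, 2, 1.4), N = 5), 11.68)
  expect_equal(friedman_chi2(c(3.6, 4, 4, 2.2, 1.2), N = 5), 12.48)
  # all-tied ranks cancel algebraically
  expect_equal(friedman_chi2(rep(3, 5), N = 4), 0)
})

test_that("Friedman statistic matches stats::friedman.test on tie-free data", {
  for (seed in 1:10) {
    set.seed(seed)
    M <- sample(3:6, 1); N <- sample(3:5, 1)
    acc <- matrix(runif(M * N), M, N)  # ties have probability zero
    rk <- rank_with_ties(acc)
    ours <- friedman_chi2(rk$avg_rank, N)
    # friedman.test blocks over datasets; it ranks ascending, which leaves
    # the statistic unchanged
    ref <- unname(stats::friedman.test(t(acc))$statistic)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("Iman-Davenport F reproduces the published pairs", {
  expect_equal(iman_davenport_ff(12.8, N = 4, M = 5), 12)
  expect_equal(round(iman_davenport_ff(7.8, N = 4, M = 5), 4), 2.8537)
  expect_equal(round(iman_davenport_ff(16.6, N = 5, M = 5), 4), 19.5294)
  expect_equal(round(iman_davenport_ff(11.68, N = 5, M = 5), 4), 5.6154)
  expect_equal(round(iman_davenport_ff(12.48, N = 5, M = 5), 4), 6.6383)
  expect_equal(iman_davenport_ff(0, N = 4, M = 5), 0)
  expect_warning(out <- iman_davenport_ff(16, N = 4, M = 5), "saturated")
  expect_equal(out, Inf)
})

test_that("the 11-algorithm tumor comparison reproduces the published statistics", {
  avg_rank <- c(10, 4.67, 4.17, 8.33, 5, 6, 6.67, 7, 9, 3.33, 1.83)
  chi2 <- friedman_chi2(avg_rank, N = 3)
  expect_equal(round(chi2, 4), 17.0491)
  expect_equal(round(iman_davenport_ff(chi2, N = 3, M = 11), 4), 2.6329)
})

test_that("F criticals from the inverse CDF match the published values", {
  expect_equal(round(stats::qf(0.90, 4, 12), 3), 2.480)
  expect_equal(round(stats::qf(0.90, 10, 20), 4), 1.9367)
})

test_that("the embedded Nemenyi q table matches the studentized-range oracle", {
  for (alpha in c(0.05, 0.10)) {
    for (M in 2:20) {
      rep <- nemenyi_cd(M, N = 5, alpha = alpha)
      expect_equal(rep$q_alpha, qtukey(1 - alpha, M, Inf) / sqrt(2),
                   tolerance = 1e-3)
    }
  }
  expect_error(nemenyi_cd(25, 5, 0.05), "between 2 and 20")
  expect_error(nemenyi_cd(5, 5, 0.01), "alpha")
})

test_that("the critical distance follows its closed form and shrinks with N", {
  rep <- nemenyi_cd(M = 5, N = 4, alpha = 0.10)
  expect_equal(rep$cd, 2.459 * sqrt(30 / 24))
  expect_equal(round(rep$cd, 4), 2.7492)
  cds <- vapply(c(3, 10, 50, 200), function(N) nemenyi_cd(5, N, 0.10)$cd,
                numeric(1))
  expect_true(all(diff(cds) < 0))
  rep2 <- nemenyi_cd(M = 2, N = 7, alpha = 0.05)
  expect_equal(rep2$cd, 1.960 * sqrt(2 * 3 / (6 * 7)))
  expect_gt(rep2$cd, 0)
})

test_that("the full comparison pipeline decides the published tests", {
  # published rank tables: reject at alpha = 0.10
  t15 <- rbind(RS = c(3, 5, 3, 3), NRS = c(4, 3.5, 4.5, 4),
               CDA = c(5, 3.5, 4.5, 5), MDNRS = c(2, 2, 1, 1),
               BONJE = c(1, 1, 2, 2))
  cmp <- compare_algorithms(ranks = t15, alpha = 0.10)
  expect_equal(cmp$friedman$chi2, 12.8)
  expect_equal(cmp$friedman$ff, 12)
  expect_equal(c(cmp$friedman$df1, cmp$friedman$df2), c(4, 12))
  expect_true(cmp$friedman$reject_null)
  # MDNRS and BONJE tie for the best average rank (1.5)
  expect_true(cmp$cd_diagram$algorithm[1] %in% c("MDNRS", "BONJE"))
  expect_equal(cmp$cd_diagram$avg_rank[1], 1.5)
  # two identical algorithms: no rejection
  acc <- rbind(A = c(0.8, 0.7, 0.6), B = c(0.8, 0.7, 0.6))
  cmp2 <- compare_algorithms(acc, alpha = 0.10)
  expect_equal(cmp2$friedman$chi2, 0)
  expect_false(cmp2$friedman$reject_null)
  # similar pairs are those within the critical distance
  expect_true(all(vapply(cmp$nemenyi$similar_pairs, function(p) {
    abs(cmp$avg_rank[p[1]] - cmp$avg_rank[p[2]]) <= cmp$nemenyi$cd
  }, logical(1))))
})

test_that("accuracy matrices round-trip through the text reader", {
  acc <- rbind(A = c(0.9, 0.8), B = c(0.85, 0.7))
  colnames(acc) <- c("d1", "d2")
  path <- file.path(tempdir(), "acc.tsv")
  utils::write.table(data.frame(algorithm = rownames(acc), acc,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_accuracy_matrix(path)
  expect_equal(back, acc)
})
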