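test_that("joint granules match the worked example", {
  nds <- toy_nds()
  expect_equal(joint_granule(nds, 1, "a"), c(1L, 2L, 3L))
  expect_equal(joint_granule(nds, 4, "a"), c(3L, 4L))
  # absorption: class inside the granule leaves the granule unchanged
  expect_equal(joint_granule(nds, 3, "a"), neighborhood_granule(nds, 3, "a"))
})

test_that("credibility and coverage match hand counts and stay in (0,1]", {
  nds <- toy_nds()
  expect_equal(credibility_coverage(nds, 1, "a"),
               c(credibility = 2 / 3, coverage = 1))
  expect_equal(credibility_coverage(nds, 4, "a"),
               c(credibility = 1, coverage = 1))
  single <- neighborhood_system(
    decision_table(matrix(0.5, 1, 1), "z"), 0.3, normalize = FALSE)
  expect_equal(credibility_coverage(single, 1, 1),
               c(credibility = 1, coverage = 1))
  for (seed in 1:10) {
    nds <- rand_nds(seed)
    for (i in seq_len(nrow(nds$table$values))) {
      cc <- credibility_coverage(nds, i, 1)
      expect_true(all(cc > 0 & cc <= 1))
    }
  }
})

test_that("classic neighborhood entropy matches closed forms", {
  nds <- toy_nds()
  # granule sizes under {a} are 3, 3, 4, 2
  expect_equal(classic_neighborhood_entropy(nds, "a"),
               -(log10(3/4) + log10(3/4) + log10(1) + log10(2/4)) / 4)
  expect_equal(round(classic_neighborhood_entropy(nds, "a"), 5), 0.13773)
  # all granules = U
  expect_equal(classic_neighborhood_entropy(toy_nds(delta = 2), "a"), 0)
  # singletons: log(n)
  expect_equal(classic_neighborhood_entropy(toy_nds(delta = 0), c("a", "b", "c")),
               log10(4))
})

test_that("average neighborhood entropy matches the worked example", {
  nds <- toy_nds()
  expect_equal(average_neighborhood_entropy(nds, "a"), 0)
  expect_equal(average_neighborhood_entropy(nds, "c"),
               -(0.25 / 4) * (log10(1/2) + log10(3/4)))
  expect_equal(round(average_neighborhood_entropy(nds, "c"), 5), 0.02662)
  expect_equal(average_neighborhood_entropy(nds, "b"), 0)  # P = 0
})

test_that("joint and conditional entropies reproduce all printed values", {
  nds <- toy_nds()
  H <- function(B) neighborhood_joint_entropy(nds, B)
  expect_equal(round(H("a"), 3), 0.041)
  expect_equal(H("b"), 0)
  expect_equal(round(H("c"), 3), 0.116)
  expect_equal(round(H(c("a", "b")), 3), 0.195)
  expect_equal(round(H(c("a", "c")), 3), 0.345)
  expect_equal(round(H(c("b", "c")), 3), 0.116)
  expect_equal(round(H(c("a", "b", "c")), 3), 0.345)
  # H(D|a) = H(D,a) - H(a) and H(a) = 0 here
  expect_equal(round(neighborhood_conditional_entropy(nds, "a"), 3), 0.041)
  expect_equal(neighborhood_conditional_entropy(nds, "b"), 0)
})

test_that("conditional entropy vanishes for a perfectly separating subset", {
  # two tight clusters, one per class: each granule equals its class
  dt <- decision_table(cbind(x = c(0, 0.02, 0.98, 1)), c("u", "u", "v", "v"))
  nds <- neighborhood_system(dt, 0.1, normalize = FALSE)
  expect_equal(approximate_precision(nds, 1), 1)
  expect_equal(neighborhood_conditional_entropy(nds, 1), 0)
})

test_that("significance is the entropy gain, with the empty-set convention", {
  nds <- toy_nds()
  expect_equal(significance(nds, "a", "c"),
               neighborhood_joint_entropy(nds, c("c", "a")) -
                 neighborhood_joint_entropy(nds, "c"))
  expect_equal(round(significance(nds, "a", "c"), 3), 0.229)
  expect_equal(significance(nds, "b", c("a", "c")), 0)
  expect_equal(significance(nds, "b"), 0)  # B empty -> H(D,{b})
  expect_error(significance(nds, "a", c("a", "c")), "already in B")
})

test_that("credibility/coverage identity and chain rule hold to 1e-12", {
  for (seed in 1:50) {
    nds <- rand_nds(seed, n_classes = sample(2:3, 1))
    f <- ncol(nds$table$values)
    B <- sample(f, sample(f, 1))
    n <- nrow(nds$table$values)
    # identity: H(D,B) = -(P/n) sum log(credibility * coverage)
    P <- approximate_precision(nds, B)
    cc <- vapply(seq_len(n), function(i) {
      v <- credibility_coverage(nds, i, B)
      log10(v[["credibility"]] * v[["coverage"]])
    }, numeric(1))
    expect_equal(neighborhood_joint_entropy(nds, B), -(P / n) * sum(cc),
                 tolerance = 1e-12)
    # chain rule: H(D|B) = H(D,B) - H(B)
    expect_equal(neighborhood_conditional_entropy(nds, B),
                 neighborhood_joint_entropy(nds, B) -
                   average_neighborhood_entropy(nds, B),
                 tolerance = 1e-12)
    # non-negativity of all four measures
    expect_gte(classic_neighborhood_entropy(nds, B), 0)
    expect_gte(average_neighborhood_entropy(nds, B), 0)
    expect_gte(neighborhood_conditional_entropy(nds, B), 0)
    expect_gte(neighborhood_joint_entropy(nds, B), 0)
  }
})

test_that("below the minimum pairwise distance the joint entropy has a closed form", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:8, 1)
    v <- matrix(runif(n * 2), n, 2)  # distinct rows almost surely
    labels <- sample(c("u", "v"), n, replace = TRUE)
    dmin <- min(dist(v))
    nds <- neighborhood_system(decision_table(v, labels), delta = dmin / 2,
                               normalize = FALSE)
    class_sizes <- table(labels)[labels]
    expect_equal(approximate_precision(nds, 1:2), 1)
    expect_equal(neighborhood_joint_entropy(nds, 1:2),
                 (2 / n) * sum(log10(class_sizes)),
                 tolerance = 1e-12)
  }
})

test_that("joint entropy can both rise and fall as the subset grows", {
  nds <- toy_nds()
  H <- function(B) neighborhood_joint_entropy(nds, B)
  expect_gt(H(c("a", "c")), H("c"))       # growth
  expect_equal(H(c("a", "b", "c")), H(c("a", "c")))  # no growth
  # and a strict decrease exists: frozen random witness with B1 = {3},
  # B2 = {1, 3} at a coarse radius
  set.seed(3)
  n <- sample(4:10, 1)
  dt <- decision_table(matrix(runif(n * 3), n, 3),
                       sample(c("u", "v"), n, replace = TRUE))
  ndsw <- neighborhood_system(dt, 0.6, normalize = FALSE)
  expect_lt(neighborhood_joint_entropy(ndsw, c(1, 3)),
            neighborhood_joint_entropy(ndsw, 3) - 1e-9)
})

test_that("entropies rescale exactly with the log base", {
  nds <- toy_nds()
  for (B in list("a", "c", c("a", "c"))) {
    expect_equal(neighborhood_joint_entropy(nds, B, log_base = 2),
                 neighborhood_joint_entropy(nds, B, log_base = 10) / log10(2),
                 tolerance = 1e-12)
    expect_equal(classic_neighborhood_entropy(nds, B, log_base = exp(1)),
                 classic_neighborhood_entropy(nds, B, log_base = 10) * log(10),
                 tolerance = 1e-12)
  }
})

test_that("the explain report mirrors the hand walk-through", {
  nds <- toy_nds()
  ex <- explain_subset(nds, "a")
  expect_equal(ex$granules[[4]], c(3L, 4L))
  expect_equal(ex$joint_granules[[1]], c(1L, 2L, 3L))
  expect_equal(ex$precision, 0.25)
  expect_equal(ex$per_sample$credibility, c(2/3, 2/3, 1/2, 1))
  expect_equal(ex$per_sample$coverage, c(1, 1, 1, 1))
  expect_equal(round(ex$entropies[["joint"]], 3), 0.041)
  expect_output(print(ex), "P_B\\(D\\) = 0.25")
})
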