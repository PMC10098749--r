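test_that("the plug-in mutual information matches hand-computed tables", {
  x4 <- rep(1:4, each = 25)
  expect_equal(mutual_information(x4, x4), 2)        # H of 4 equiprobable values
  expect_equal(mutual_information(rep(1, 50), rep(1:2, 25)), 0)
  # joint counts [[2,1],[1,2]] over n = 6
  x <- c(1, 1, 1, 2, 2, 2); y <- c(1, 1, 2, 1, 2, 2)
  expected <- 2 * (1 / 3) * log2((1 / 3) / 0.25) + 2 * (1 / 6) * log2((1 / 6) / 0.25)
  expect_equal(mutual_information(x, y), expected, tolerance = 1e-12)
  expect_error(mutual_information(1:4, 1:5), "equal lengths")
})

test_that("mutual information is symmetric, non-negative, and entropy-bounded", {
  set.seed(111)
  for (rep in 1:10) {
    x <- sample(1:3, 80, replace = TRUE)
    y <- sample(1:4, 80, replace = TRUE)
    ixy <- mutual_information(x, y)
    expect_equal(ixy, mutual_information(y, x), tolerance = 1e-12)
    expect_gte(ixy, 0)
    hx <- mutual_information(x, x)
    hy <- mutual_information(y, y)
    expect_lte(ixy, min(hx, hy) + 1e-12)
  }
})

test_that("relevance and redundancy follow their subset-average definitions", {
  set.seed(121)
  y <- sample(1:2, 200, replace = TRUE)
  X <- cbind(as.numeric(y), rnorm(200), rnorm(200))
  fm <- feature_matrix(X, y)
  # a feature identical to the labels has relevance H(Y)
  expect_equal(relevance(fm, 1L), mutual_information(y, y), tolerance = 1e-12)
  # pure noise at this sample size stays within the small-sample bias bound
  expect_lt(relevance(fm, 2L), 0.15)
  # relevance over a set is the arithmetic mean of per-feature MI
  per <- vapply(1:3, function(j) mutual_information(X[, j], y), 1)
  expect_equal(relevance(fm, 1:3), mean(per), tolerance = 1e-12)
  # single-feature redundancy is the feature's self-information
  expect_equal(redundancy(fm, 2L), mutual_information(X[, 2], X[, 2]),
               tolerance = 1e-12)
  # duplicated feature: all four ordered-pair terms equal I(F, F)
  dup <- feature_matrix(cbind(X[, 2], X[, 2]), y)
  expect_equal(redundancy(dup, 1:2), mutual_information(X[, 2], X[, 2]),
               tolerance = 1e-12)
  expect_error(relevance(fm, integer(0)), "non-empty")
})

test_that("incremental greedy selection equals the brute-force oracle", {
  set.seed(131)
  for (rep in 1:4) {
    X <- matrix(rnorm(100 * 10), 100)
    y <- sample(1:3, 100, replace = TRUE)
    X[, 4] <- y + rnorm(100, sd = 0.4)        # one informative feature
    for (m in c(1, 2, 5, 10)) {
      for (crit in c("MID", "MIQ")) {
        got <- mrmr_select(feature_matrix(X, y), m, crit)$indices
        expect_identical(as.integer(got), naive_mrmr(X, y, m, crit),
                         info = sprintf("rep %d m %d %s", rep, m, crit))
      }
    }
  }
})

test_that("a duplicated top feature is deferred behind an independent informative one", {
  set.seed(141)
  n <- 60
  y <- sample(1:2, n, replace = TRUE)
  f1 <- y + rnorm(n, sd = 0.2)
  f3 <- ifelse(y == 1, 2, -2) + rnorm(n, sd = 0.5)
  X <- cbind(f1, f1, 0.5 * f3, rnorm(n))
  r <- mrmr_select(feature_matrix(X, y), 3, "MID")
  expect_identical(r$indices[1], 1L)          # most relevant, lowest index
  expect_false(2L %in% r$indices[1:2])        # duplicate deferred
  expect_identical(as.integer(r$indices), naive_mrmr(X, y, 3, "MID"))
})

test_that("selection results are well-formed, deterministic, and validated", {
  set.seed(151)
  X <- matrix(rnorm(80 * 12), 80)
  y <- sample(1:2, 80, replace = TRUE)
  r <- mrmr_select(feature_matrix(X, y), 6)
  expect_length(r$indices, 6)
  expect_false(anyDuplicated(r$indices) > 0)
  expect_length(r$V_trace, 6)
  expect_length(r$W_trace, 6)
  expect_equal(r$V_trace[6], relevance(feature_matrix(X, y), r$indices),
               tolerance = 1e-12)
  expect_equal(r$W_trace[6], redundancy(feature_matrix(X, y), r$indices),
               tolerance = 1e-12)
  expect_identical(mrmr_select(feature_matrix(X, y), 6)$indices, r$indices)
  expect_error(mrmr_select(feature_matrix(X, y), 13), "exceeds")
  expect_error(mrmr_select(feature_matrix(X, rep(1, 80)), 2), "2 classes")
})
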