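test_that("plain k-fold reproduces the printed train/test sizes at full scale", {
  plan <- kfold_partition(19221, 12)
  expect_length(plan$test_indices, 12)
  expect_true(all(lengths(plan$test_indices) == 1601L))
  expect_true(all(vapply(seq_len(12), function(i)
    19221L - length(plan$test_indices[[i]]), 1L) == 17620L))
  tiny <- kfold_partition(12, 12)
  expect_true(all(lengths(tiny$test_indices) == 1L))
  expect_error(kfold_partition(5, 6), "exceeds")
  expect_error(kfold_partition(10, 1), ">= 2")
})

test_that("fold plans are disjoint, covered by training, and subject-clean", {
  set.seed(191)
  for (rep in 1:3) {
    n <- sample(50:90, 1)
    k <- sample(3:6, 1)
    plan <- kfold_partition(n, k, seed = rep)
    all_test <- unlist(plan$test_indices)
    expect_false(anyDuplicated(all_test) > 0)
    expect_true(all(all_test %in% seq_len(n)))
    subj <- sample(sprintf("s%d", 1:8), n, replace = TRUE)
    bp <- kfold_partition(n, 4, subjects = subj, seed = rep, mode = "by-subject")
    expect_setequal(unlist(bp$test_indices), seq_len(n))
    for (i in 1:4) {
      test_subj <- subj[bp$test_indices[[i]]]
      train_subj <- subj[setdiff(seq_len(n), bp$test_indices[[i]])]
      expect_length(intersect(test_subj, train_subj), 0)
    }
  }
  expect_error(kfold_partition(10, 3, mode = "by-subject"), "subjects")
})

test_that("metrics match a hand-counted confusion matrix", {
  perfect <- classification_metrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(perfect$accuracy, 100)
  expect_true(all(perfect$per_class$f1 == 100))

  m <- classification_metrics(c(1, 2, 2, 2), c(1, 1, 2, 2))
  expect_equal(m$accuracy, 75)
  c2 <- m$per_class[m$per_class$class == "2", ]
  expect_equal(c2$precision, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(c2$recall, 100)
  expect_equal(c2$f1, 80)
  # confusion rows sum to class support; accuracy recomputable from trace
  expect_identical(unname(rowSums(m$confusion)), c(2, 2))
  expect_equal(100 * sum(diag(m$confusion)) / sum(m$confusion), m$accuracy)
  # accuracy is invariant to class relabelling
  swap <- function(v) ifelse(v == 1, 2, 1)
  m2 <- classification_metrics(swap(c(1, 2, 2, 2)), swap(c(1, 1, 2, 2)))
  expect_equal(m2$accuracy, m$accuracy)
  # a class never predicted gets precision 0, not NaN
  m3 <- classification_metrics(c("a", "a"), c("a", "b"))
  expect_equal(m3$per_class$precision[m3$per_class$class == "b"], 0)
})

test_that("diversity tables cross-tabulate correctness and conserve counts", {
  d <- diversity_table(c(1, 2, 2, 2), c(1, 1, 2, 1), c(1, 1, 2, 2))
  expect_identical(unname(unclass(d)),
                   matrix(c(2L, 1L, 1L, 0L), 2, byrow = TRUE))
  self <- diversity_table(c(1, 2, 1), c(1, 2, 1), c(1, 1, 1))
  expect_identical(unclass(self)[1, 2] + unclass(self)[2, 1], 0L)
  set.seed(201)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    a <- sample(1:3, n, TRUE); b <- sample(1:3, n, TRUE); y <- sample(1:3, n, TRUE)
    dt <- unclass(diversity_table(a, b, y))
    expect_identical(sum(dt), as.integer(n))
    # marginal identity: both-hit + A-only equals A's total hits
    expect_identical(dt[1, 1] + dt[1, 2], sum(a == y))
  }
  expect_error(diversity_table(1:3, 1:4, 1:4), "equal lengths")
})

test_that("the benchmark harness yields per-model reports and conserving diversity tables", {
  pool <- make_small_pool(n_per_class = 6, n_subjects = 4, seed = 211)
  res <- evaluate_system(pool, k = 2, models = c("ffm", "lstm", "cnn"),
                         stages = "stage1", lstm_epochs = 3, fcn_epochs = 40,
                         seed = 5)
  expect_named(res, "stage1")
  expect_named(res$stage1$metrics, c("ffm", "lstm", "cnn"))
  expect_named(res$stage1$diversity, c("ffm_vs_lstm", "ffm_vs_cnn"))
  n_eval <- length(res$stage1$truth)
  expect_identical(n_eval, 24L)               # both folds evaluated
  for (dt in res$stage1$diversity)
    expect_identical(sum(unclass(dt)), n_eval)
  for (m in res$stage1$metrics) expect_s3_class(m, "metrics_report")
})
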