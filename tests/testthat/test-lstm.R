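test_that("the LSTM cell follows the gate equations exactly", {
  # scalar case, all weights 0.5, biases 0, zero state, x = 1
  g <- list(W_i = matrix(0.5, 2, 1), W_f = matrix(0.5, 2, 1),
            W_c = matrix(0.5, 2, 1), W_o = matrix(0.5, 2, 1),
            b_i = 0, b_f = 0, b_c = 0, b_o = 0)
  st <- lstm_cell_step(1, list(h = 0, c = 0), g)
  sig <- 1 / (1 + exp(-0.5))              # all pre-activations are 0.5
  expect_equal(unname(st$i), sig, tolerance = 1e-10)
  expect_equal(unname(st$candidate), tanh(0.5), tolerance = 1e-10)
  expect_equal(unname(st$c), sig * tanh(0.5), tolerance = 1e-10)
  expect_equal(unname(st$h), sig * tanh(sig * tanh(0.5)), tolerance = 1e-10)
  # the hand-rounded values of the same arithmetic
  expect_equal(unname(st$c), 0.2877, tolerance = 1e-3)
  expect_equal(unname(st$h), 0.1743, tolerance = 1e-3)

  # all-zero parameters: candidate is tanh(0) = 0, so h = c = 0
  g0 <- lapply(g, function(w) w * 0)
  st0 <- lstm_cell_step(3, list(h = 0, c = 0), g0)
  expect_identical(unname(st0$h), 0)
  expect_identical(unname(st0$c), 0)

  # forget gate forced to 1 and input gate to 0 preserves the cell exactly
  gmem <- g
  gmem$b_f <- 100; gmem$b_i <- -100
  stm <- lstm_cell_step(1, list(h = 0.3, c = 0.75), gmem)
  expect_equal(unname(stm$c), 0.75)

  expect_error(lstm_cell_step(c(1, 2), list(h = 0, c = 0), g), "does not match")
})

test_that("the cell matches an independent scalar implementation on random cases", {
  set.seed(61)
  for (rep in 1:20) {
    w <- rnorm(8); b <- rnorm(4); x <- rnorm(1); h <- rnorm(1); cc <- rnorm(1)
    g <- list(W_i = matrix(w[1:2]), W_f = matrix(w[3:4]),
              W_c = matrix(w[5:6]), W_o = matrix(w[7:8]),
              b_i = b[1], b_f = b[2], b_c = b[3], b_o = b[4])
    got <- lstm_cell_step(x, list(h = h, c = cc), g)
    ref <- reference_cell(x, h, cc, w[1:2], w[3:4], w[5:6], w[7:8],
                          b[1], b[2], b[3], b[4])
    expect_equal(unname(got$h), ref$h, tolerance = 1e-10)
    expect_equal(unname(got$c), ref$c, tolerance = 1e-10)
    expect_true(all(got$i > 0 & got$i < 1))
    expect_true(all(got$f > 0 & got$f < 1))
    expect_true(all(got$o > 0 & got$o < 1))
    expect_true(abs(got$h) < 1)
  }
})

test_that("the batched encoder agrees with stepwise cell updates", {
  set.seed(71)
  params <- lstm_params(1, c(5, 4), seed = 8)
  x <- rnorm(12)
  # run the two layers by repeated single-cell stepping
  g1 <- lstm_gate_weights(params, 1)
  g2 <- lstm_gate_weights(params, 2)
  s1 <- list(h = numeric(5), c = numeric(5))
  s2 <- list(h = numeric(4), c = numeric(4))
  for (t in seq_along(x)) {
    s1 <- lstm_cell_step(x[t], s1, g1)
    s2 <- lstm_cell_step(s1$h, s2, g2)
  }
  enc <- lstm_encode(x, params)
  expect_equal(unname(enc), unname(s2$h), tolerance = 1e-10)
})

test_that("encoding is deterministic and 100-dimensional under the stage presets", {
  params <- lstm_params(1, c(150, 100), seed = 5)
  x <- matrix(rnorm(2 * 600), 2)
  f <- lstm_encode(x, params)
  expect_identical(dim(f), c(2L, 100L))
  expect_identical(lstm_encode(x, params), f)
  expect_true(all(abs(f) < 1))
  p2 <- ffm_preset("stage2")
  expect_identical(p2$lstm_hidden, c(150L, 100L))
  expect_identical(p2$lstm_dropout, c(0.2, 0.1))
  expect_identical(p2$batch_size, 256L)
})

test_that("branch training reduces the loss and is seed-reproducible", {
  set.seed(81)
  X <- rbind(matrix(rnorm(15 * 60), 15),
             matrix(rnorm(15 * 60, mean = 0.8), 15))
  lab <- rep(c("a", "b"), each = 15)
  p <- train_lstm_branch(X, lab, hidden_sizes = c(8, 6), epochs = 8,
                         batch_size = 16, seed = 4)
  lh <- attr(p, "loss_history")
  expect_lt(lh[length(lh)], lh[1])
  p2 <- train_lstm_branch(X, lab, hidden_sizes = c(8, 6), epochs = 8,
                          batch_size = 16, seed = 4)
  expect_identical(p$layers, p2$layers)
  expect_error(train_lstm_branch(X, rep("a", 30), hidden_sizes = c(4, 3)),
               "2 classes")
  expect_error(train_lstm_branch(X[0, , drop = FALSE], character(0)),
               "non-empty")
})
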