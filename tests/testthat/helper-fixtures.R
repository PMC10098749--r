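# Shared fixtures: small synthetic pools and an independent brute-force
# greedy MRMR oracle used to validate the incremental implementation.

make_small_pool <- function(n_per_class = 3L, n_subjects = 3L, seed = 101L) {
  generate_pool(n_per_class = n_per_class, n_subjects = n_subjects, seed = seed)
}

# Straight-from-definition greedy selection: recomputes every relevance and
# redundancy term with mutual_information() at every step.
naive_mrmr <- function(X, y, m, criterion = "MID", bins = 8L) {
  K <- ncol(X)
  rel <- vapply(seq_len(K), function(j) mutual_information(X[, j], y, bins), 1)
  S <- which(rel == max(rel))[1L]
  while (length(S) < m) {
    cand <- setdiff(seq_len(K), S)
    sc <- vapply(cand, function(j) {
      red <- mean(vapply(S, function(i)
        mutual_information(X[, i], X[, j], bins), 1))
      if (criterion == "MID") rel[j] - red
      else if (red > 0) rel[j] / red
      else rel[j] - red
    }, 1)
    S <- c(S, cand[which(sc == max(sc))[1L]])
  }
  as.integer(S)
}

# Independent scalar LSTM cell written directly from the gate equations.
reference_cell <- function(x, h, c, W_i, W_f, W_c, W_o, b_i, b_f, b_c, b_o) {
  sig <- function(z) 1 / (1 + exp(-z))
  hx <- c(h, x)
  i <- sig(sum(W_i * hx) + b_i)
  f <- sig(sum(W_f * hx) + b_f)
  o <- sig(sum(W_o * hx) + b_o)
  g <- tanh(sum(W_c * hx) + b_c)
  cn <- i * g + f * c
  list(h = o * tanh(cn), c = cn)
}

# A fitted cascade is expensive; fit it once per test run and share it
# between the routing tests.
.fixture_env <- new.env()
fitted_cascade_fixture <- function() {
  if (is.null(.fixture_env$cascade)) {
    .fixture_env$pool <- make_small_pool(n_per_class = 4L, n_subjects = 2L,
                                         seed = 171L)
    .fixture_env$cascade <- fit_cascade(.fixture_env$pool,
                                        branches = c("lstm", "spectral"),
                                        lstm_epochs = 4, fcn_epochs = 60,
                                        seed = 3)
  }
  list(pool = .fixture_env$pool, cascade = .fixture_env$cascade)
}
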