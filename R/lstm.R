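# Two-layer LSTM feature branch. The cell follows the standard gated
# recurrence: input/forget/output gates are logistic functions of
# W.[h_{t-1}, x_t] + b, the candidate cell is tanh(W_c.[h_{t-1}, x_t] + b_c),
# c_t = i*candidate + f*c_{t-1}, h_t = o*tanh(c_t). Features are the final
# time-step hidden state of the top layer (100 units under the presets).
#
# Internally each layer stores one combined weight matrix W [(H+in) x 4H]
# with gate blocks ordered i, f, candidate, o and rows ordered
# [h_{t-1}; x_t]; per-gate views are available via lstm_gate_weights().

GATE_NAMES <- c("i", "f", "c", "o")

#' Initialise two-layer LSTM parameters
#'
#' Weights are Glorot-uniform; forget-gate biases start at 1 (standard
#' remedy against early forgetting); all other biases at 0.
#'
#' @param input_size Input dimension per time step (1 for BOLD series).
#' @param hidden_sizes Integer vector of per-layer widths, e.g. `c(150, 100)`.
#' @param dropout Per-layer dropout rates in `[0, 1)`, applied to each
#'   layer's output during training only.
#' @param seed Integer seed for the initialisation.
#' @return An object of class `lstm_params`.
#' @export
lstm_params <- function(input_size = 1L, hidden_sizes = c(150L, 100L),
                        dropout = rep(0, length(hidden_sizes)), seed = 1L) {
  if (length(dropout) != length(hidden_sizes))
    stopf("`dropout` must have one rate per layer")
  if (any(dropout < 0 | dropout >= 1)) stopf("dropout rates must be in [0, 1)")
  layers <- with_local_seed(seed, {
    ins <- c(input_size, head(hidden_sizes, -1L))
    lapply(seq_along(hidden_sizes), function(l) {
      H <- hidden_sizes[l]; fan <- ins[l] + H
      lim <- sqrt(6 / (fan + H))
      W <- matrix(runif(fan * 4L * H, -lim, lim), nrow = fan)
      b <- numeric(4L * H)
      b[(H + 1L):(2L * H)] <- 1            # forget-gate bias block
      list(W = W, b = b, H = H, input = ins[l])
    })
  })
  structure(list(layers = layers, hidden_sizes = as.integer(hidden_sizes),
                 input_size = as.integer(input_size), dropout = dropout),
            class = "lstm_params")
}

#' Per-gate weight views of one LSTM layer
#'
#' @param params An [lstm_params()] object.
#' @param layer Layer index.
#' @return List with matrices `W_i`, `W_f`, `W_c`, `W_o` (each
#'   `(H + input) x H`, acting on the concatenation `c(h, x)`) and bias
#'   vectors `b_i`, `b_f`, `b_c`, `b_o`.
#' @export
lstm_gate_weights <- function(params, layer = 1L) {
  stopifnot(inherits(params, "lstm_params"))
  ly <- params$layers[[layer]]
  H <- ly$H
  out <- list()
  for (g in seq_along(GATE_NAMES)) {
    cols <- ((g - 1L) * H + 1L):(g * H)
    out[[paste0("W_", GATE_NAMES[g])]] <- ly$W[, cols, drop = FALSE]
    out[[paste0("b_", GATE_NAMES[g])]] <- ly$b[cols]
  }
  out
}

#' One LSTM cell update
#'
#' Applies the gate equations once: `i`, `f`, `o` are logistic in
#' `W.[h, x] + b`; the candidate cell is `tanh(W_c.[h, x] + b_c)`;
#' `c' = i*candidate + f*c`; `h' = o*tanh(c')`.
#'
#' @param x_t Input vector at time t.
#' @param state List with hidden vector `h` and cell vector `c` of equal
#'   length.
#' @param gates Per-gate weights as returned by [lstm_gate_weights()].
#' @return Updated state: list with `h`, `c`, and the gate activations
#'   `i`, `f`, `o`, `candidate`.
#' @export
lstm_cell_step <- function(x_t, state, gates) {
  if (length(state$h) != length(state$c))
    stopf("state h and c must have matching lengths")
  hx <- c(state$h, x_t)
  if (length(hx) != nrow(gates$W_i))
    stopf("input/state size (%d) does not match weights (%d rows)",
          length(hx), nrow(gates$W_i))
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(drop(hx %*% gates$W_i) + gates$b_i)
  f <- sig(drop(hx %*% gates$W_f) + gates$b_f)
  o <- sig(drop(hx %*% gates$W_o) + gates$b_o)
  g <- tanh(drop(hx %*% gates$W_c) + gates$b_c)
  c_new <- i * g + f * state$c
  list(h = o * tanh(c_new), c = c_new, i = i, f = f, o = o, candidate = g)
}

sigmoid_mat <- function(z) 1 / (1 + exp(-z))

# Batched forward pass of one layer. xin: [B, in, T] array. Returns the
# hidden trajectory and (optionally) all caches needed for BPTT.
lstm_layer_forward <- function(xin, layer, keep_cache = FALSE) {
  B <- dim(xin)[1L]; Tn <- dim(xin)[3L]
  H <- layer$H
  Wh <- layer$W[seq_len(H), , drop = FALSE]
  Wx <- layer$W[(H + 1L):nrow(layer$W), , drop = FALSE]
  bmat <- matrix(layer$b, nrow = B, ncol = 4L * H, byrow = TRUE)
  Hfull <- array(0, c(B, H, Tn + 1L))
  Cfull <- array(0, c(B, H, Tn + 1L))
  gi <- gf <- gg <- go <- if (keep_cache) array(0, c(B, H, Tn)) else NULL
  bi <- seq_len(H); bf <- H + bi; bg <- 2L * H + bi; bo <- 3L * H + bi
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  nin <- nrow(Wx)
  for (t in seq_len(Tn)) {
    Z <- h %*% Wh + matrix(xin[, , t], B, nin) %*% Wx + bmat
    I <- sigmoid_mat(Z[, bi, drop = FALSE])
    Fg <- sigmoid_mat(Z[, bf, drop = FALSE])
    G <- tanh(Z[, bg, drop = FALSE])
    O <- sigmoid_mat(Z[, bo, drop = FALSE])
    cc <- I * G + Fg * cc
    h <- O * tanh(cc)
    Hfull[, , t + 1L] <- h
    Cfull[, , t + 1L] <- cc
    if (keep_cache) { gi[, , t] <- I; gf[, , t] <- Fg; gg[, , t] <- G; go[, , t] <- O }
  }
  list(H = Hfull, C = Cfull, i = gi, f = gf, g = gg, o = go, xin = xin)
}

# Backward pass of one layer. dh_out: [B, H, T] gradient w.r.t. each h_t.
# need_dx = FALSE skips the input-gradient array (bottom layer).
lstm_layer_backward <- function(cache, layer, dh_out, need_dx = TRUE) {
  B <- dim(cache$H)[1L]; H <- layer$H; Tn <- dim(dh_out)[3L]
  Wh <- layer$W[seq_len(H), , drop = FALSE]
  Wx <- layer$W[(H + 1L):nrow(layer$W), , drop = FALSE]
  nin <- nrow(Wx)
  dWh <- matrix(0, H, 4L * H); dWx <- matrix(0, nin, 4L * H)
  db <- numeric(4L * H)
  dx <- if (need_dx) array(0, c(B, nin, Tn))
  bi <- seq_len(H); bf <- H + bi; bg <- 2L * H + bi; bo <- 3L * H + bi
  dHnext <- matrix(0, B, H); dCnext <- matrix(0, B, H)
  dZ <- matrix(0, B, 4L * H)
  for (t in seq(Tn, 1L)) {
    dh <- matrix(dh_out[, , t], B, H) + dHnext
    tc <- tanh(matrix(cache$C[, , t + 1L], B, H))
    O <- matrix(cache$o[, , t], B, H); I <- matrix(cache$i[, , t], B, H)
    Fg <- matrix(cache$f[, , t], B, H); G <- matrix(cache$g[, , t], B, H)
    Cprev <- matrix(cache$C[, , t], B, H)
    dc <- dh * O * (1 - tc^2) + dCnext
    dZ[, bo] <- (dh * tc) * O * (1 - O)
    dZ[, bi] <- (dc * G) * I * (1 - I)
    dZ[, bg] <- (dc * I) * (1 - G^2)
    dZ[, bf] <- (dc * Cprev) * Fg * (1 - Fg)
    dCnext <- dc * Fg
    dWh <- dWh + crossprod(matrix(cache$H[, , t], B, H), dZ)
    dWx <- dWx + crossprod(matrix(cache$xin[, , t], B, nin), dZ)
    db <- db + colSums(dZ)
    dHnext <- tcrossprod(dZ, Wh)
    if (need_dx) dx[, , t] <- tcrossprod(dZ, Wx)
  }
  list(dW = rbind(dWh, dWx), db = db, dx = dx)
}

# Forward through the whole stack. x: [B, T] matrix of (padded) signals.
# Dropout masks (variational: one mask per layer per call) are applied to
# layer outputs during training only.
lstm_stack_forward <- function(x, params, training = FALSE, keep_cache = FALSE) {
  B <- nrow(x); Tn <- ncol(x)
  xin <- array(x, c(B, 1L, Tn))
  caches <- vector("list", length(params$layers))
  masks <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    caches[[l]] <- lstm_layer_forward(xin, params$layers[[l]], keep_cache)
    Hs <- caches[[l]]$H[, , -1L, drop = FALSE]
    p <- params$dropout[l]
    if (training && p > 0) {
      mask <- matrix(stats::rbinom(B * params$layers[[l]]$H, 1L, 1 - p),
                     B) / (1 - p)
      masks[[l]] <- mask
      Hs <- Hs * as.vector(mask)          # mask recycled across time
    }
    xin <- Hs
  }
  top <- params$layers[[length(params$layers)]]
  hT <- caches[[length(caches)]]$H[, , Tn + 1L]
  hT <- matrix(hT, nrow = B, ncol = top$H)
  if (training && params$dropout[length(params$layers)] > 0)
    hT <- hT * masks[[length(masks)]]
  list(hT = hT, caches = caches, masks = masks)
}

#' Encode signals with a fitted LSTM branch
#'
#' Runs the two-layer stack over each (padded) signal with dropout disabled
#' and returns the final time-step hidden state of the top layer — a
#' 100-vector under the presets.
#'
#' @param x A [bold_signal()], a numeric vector, or an `n x T` matrix of
#'   signals in rows.
#' @param params An [lstm_params()] object (typically from
#'   [train_lstm_branch()]).
#' @return A feature vector of length `hidden_sizes[2]`, or an `n x H`
#'   matrix for matrix input.
#' @export
lstm_encode <- function(x, params) {
  stopifnot(inherits(params, "lstm_params"))
  single <- !is.matrix(x)
  if (single) x <- matrix(signal_values(x), nrow = 1L)
  out <- lstm_stack_forward(x, params, training = FALSE)$hT
  if (single) drop(out) else out
}

#' Train the LSTM branch with a temporary softmax head
#'
#' The two-layer stack plus a softmax readout on the final hidden state is
#' trained with Adam on the task labels; the readout is then discarded and
#' the recurrent weights kept as the feature encoder.
#'
#' @param x `n x T` matrix of conditioned, padded signals (rows), or a
#'   [signal_pool()] whose signals are conditioned and padded internally.
#' @param labels Length-n class labels (>= 2 distinct values required).
#' @param hidden_sizes,dropout Stack layout; the sub-phase stage preset is
#'   `c(150, 100)` hidden units with dropout `c(0.2, 0.1)`.
#' @param lr Adam learning rate (grid `{1e-2, 5e-3, 1e-3, 5e-4, 1e-4}`).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (default 256).
#' @param seed Integer seed; fixed seed gives identical parameters across
#'   runs.
#' @return An [lstm_params()] object with attributes `loss_history` and
#'   `classes`.
#' @export
train_lstm_branch <- function(x, labels, hidden_sizes = c(150L, 100L),
                              dropout = rep(0, length(hidden_sizes)),
                              lr = 1e-2, epochs = 20L, batch_size = 256L,
                              seed = 1L) {
  if (inherits(x, "signal_pool")) x <- pool_matrix(x)
  if (!is.matrix(x) || nrow(x) < 1L) stopf("`x` must be a non-empty matrix")
  if (length(labels) != nrow(x)) stopf("one label per signal required")
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L) stopf("training needs at least 2 classes")
  y <- match(as.character(labels), classes)
  n <- nrow(x); C <- length(classes)
  params <- lstm_params(1L, hidden_sizes, dropout, seed = seed)
  H2 <- tail(hidden_sizes, 1L)
  with_local_seed(seed + 1L, {
    head_W <- matrix(runif(H2 * C, -sqrt(6 / (H2 + C)), sqrt(6 / (H2 + C))), H2)
    head_b <- numeric(C)
    theta <- c(lapply(params$layers, `[[`, "W"), lapply(params$layers, `[[`, "b"),
               list(head_W, head_b))
    adam_m <- lapply(theta, function(p) p * 0)
    adam_v <- adam_m
    step <- 0L
    losses <- numeric(epochs)
    nl <- length(params$layers)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        B <- length(idx)
        fw <- lstm_stack_forward(x[idx, , drop = FALSE], params,
                                 training = TRUE, keep_cache = TRUE)
        logits <- fw$hT %*% theta[[2L * nl + 1L]] +
          matrix(theta[[2L * nl + 2L]], B, C, byrow = TRUE)
        logits <- logits - apply(logits, 1L, max)
        P <- exp(logits); P <- P / rowSums(P)
        ep_loss <- ep_loss - sum(log(pmax(P[cbind(seq_len(B), y[idx])], 1e-12)))
        dlogit <- P
        dlogit[cbind(seq_len(B), y[idx])] <- dlogit[cbind(seq_len(B), y[idx])] - 1
        dlogit <- dlogit / B
        grads <- vector("list", length(theta))
        grads[[2L * nl + 1L]] <- crossprod(fw$hT, dlogit)
        grads[[2L * nl + 2L]] <- colSums(dlogit)
        dh_top_T <- tcrossprod(dlogit, theta[[2L * nl + 1L]])
        if (!is.null(fw$masks[[nl]])) dh_top_T <- dh_top_T * fw$masks[[nl]]
        Tn <- ncol(x)
        dh_out <- array(0, c(B, tail(hidden_sizes, 1L), Tn))
        dh_out[, , Tn] <- dh_top_T
        for (l in seq(nl, 1L)) {
          bw <- lstm_layer_backward(fw$caches[[l]], params$layers[[l]],
                                    dh_out, need_dx = l > 1L)
          fw$caches[[l]] <- NULL          # free BPTT arrays as consumed
          grads[[l]] <- bw$dW
          grads[[nl + l]] <- bw$db
          if (l > 1L) {
            dh_out <- bw$dx
            if (!is.null(fw$masks[[l - 1L]]))
              dh_out <- dh_out * as.vector(fw$masks[[l - 1L]])
          }
        }
        rm(bw, fw, dh_out)
        # global-norm gradient clipping for recurrent stability
        gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 1)))
        if (is.finite(gn) && gn > 5) grads <- lapply(grads, `*`, 5 / gn)
        step <- step + 1L
        for (k in seq_along(theta)) {
          adam_m[[k]] <- 0.9 * adam_m[[k]] + 0.1 * grads[[k]]
          adam_v[[k]] <- 0.999 * adam_v[[k]] + 0.001 * grads[[k]]^2
          mhat <- adam_m[[k]] / (1 - 0.9^step)
          vhat <- adam_v[[k]] / (1 - 0.999^step)
          theta[[k]] <- theta[[k]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
        for (l in seq_len(nl)) {
          params$layers[[l]]$W <- theta[[l]]
          params$layers[[l]]$b <- theta[[nl + l]]
        }
      }
      losses[ep] <- ep_loss / n
    }
    attr(params, "loss_history") <- losses
    attr(params, "classes") <- classes
  })
  params
}

# Condition (zero-mean + detrend) then pad every signal of a pool; rows of
# the returned matrix are aligned with pool$signals.
pool_matrix <- function(pool, target = NULL) {
  stopifnot(inherits(pool, "signal_pool"))
  target <- target %||% pool$target_length
  t(vapply(pool$signals, function(s)
    pad_to_length(zero_mean_detrend(s), target)$values, numeric(target)))
}
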