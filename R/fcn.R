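# Two-layer fully-connected softmax classifier on selected features.
# Architecture: standardise -> dense(hidden, ReLU) -> dense(C) -> softmax,
# trained with Adam on cross-entropy.

#' Train the fully-connected classifier head
#'
#' @param x `n x K` feature matrix (training folds only).
#' @param labels Length-n class labels (>= 2 classes).
#' @param hidden Hidden width (default 128).
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (default 256).
#' @param seed Integer seed; fixed seed gives identical weights across runs.
#' @param standardize Standardise columns by training mean/sd (stored and
#'   re-applied at prediction).
#' @return An object of class `fcn_model`.
#' @export
train_fcn <- function(x, labels, hidden = 128L, lr = 1e-3, epochs = 300L,
                      batch_size = 256L, seed = 1L, standardize = TRUE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (length(labels) != nrow(x)) stopf("one label per row required")
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L)
    stopf("training needs at least 2 classes (got %d)", length(classes))
  y <- match(as.character(labels), classes)
  n <- nrow(x); K <- ncol(x); C <- length(classes)
  mu <- if (standardize) colMeans(x) else numeric(K)
  sdv <- if (standardize) pmax(apply(x, 2L, sd), 1e-8) else rep(1, K)
  xs <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  model <- with_local_seed(seed, {
    W1 <- matrix(rnorm(K * hidden, sd = sqrt(2 / K)), K)
    b1 <- numeric(hidden)
    W2 <- matrix(rnorm(hidden * C, sd = sqrt(2 / hidden)), hidden)
    b2 <- numeric(C)
    theta <- list(W1, b1, W2, b2)
    m <- lapply(theta, `*`, 0); v <- m
    step <- 0L
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        B <- length(idx)
        xb <- xs[idx, , drop = FALSE]
        Z1 <- xb %*% theta[[1L]] + matrix(theta[[2L]], B, hidden, byrow = TRUE)
        A1 <- pmax(Z1, 0)
        Z2 <- A1 %*% theta[[3L]] + matrix(theta[[4L]], B, C, byrow = TRUE)
        Z2 <- Z2 - apply(Z2, 1L, max)
        P <- exp(Z2); P <- P / rowSums(P)
        ep_loss <- ep_loss - sum(log(pmax(P[cbind(seq_len(B), y[idx])], 1e-12)))
        dZ2 <- P
        dZ2[cbind(seq_len(B), y[idx])] <- dZ2[cbind(seq_len(B), y[idx])] - 1
        dZ2 <- dZ2 / B
        gW2 <- crossprod(A1, dZ2); gb2 <- colSums(dZ2)
        dA1 <- tcrossprod(dZ2, theta[[3L]]) * (Z1 > 0)
        gW1 <- crossprod(xb, dA1); gb1 <- colSums(dA1)
        grads <- list(gW1, gb1, gW2, gb2)
        step <- step + 1L
        for (k in 1:4) {
          m[[k]] <- 0.9 * m[[k]] + 0.1 * grads[[k]]
          v[[k]] <- 0.999 * v[[k]] + 0.001 * grads[[k]]^2
          theta[[k]] <- theta[[k]] - lr * (m[[k]] / (1 - 0.9^step)) /
            (sqrt(v[[k]] / (1 - 0.999^step)) + 1e-8)
        }
      }
      losses[ep] <- ep_loss / n
    }
    list(W1 = theta[[1L]], b1 = theta[[2L]], W2 = theta[[3L]], b2 = theta[[4L]],
         mu = mu, sd = sdv, classes = classes, loss_history = losses)
  })
  structure(model, class = "fcn_model")
}

#' Class probabilities from a fitted classifier
#'
#' @param model A [train_fcn()] result.
#' @param x Feature matrix (or single feature vector).
#' @return `n x C` matrix of softmax probabilities (rows sum to 1) with
#'   class names as columns.
#' @export
predict_fcn <- function(model, x) {
  stopifnot(inherits(model, "fcn_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  xs <- sweep(sweep(x, 2L, model$mu), 2L, model$sd, "/")
  A1 <- pmax(xs %*% model$W1 + matrix(model$b1, nrow(x), length(model$b1),
                                      byrow = TRUE), 0)
  Z2 <- A1 %*% model$W2 + matrix(model$b2, nrow(x), length(model$b2),
                                 byrow = TRUE)
  Z2 <- Z2 - apply(Z2, 1L, max)
  P <- exp(Z2); P <- P / rowSums(P)
  colnames(P) <- model$classes
  P
}
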