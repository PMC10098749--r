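# Feature fusion module and two-stage cascade. Stage presets fix the
# branch dimensions: at the task stage (T = 600) the LSTM contributes a
# 100-vector, the residual CNN a 2048-vector and the FFT/DWT block a
# 607-vector, fused to 2755 and reduced to 512 by MRMR; at the sub-phase
# stage (T = 200) the wavelet depth drops to 6 levels (block length 207)
# and the MRMR target to 256.

#' Stage presets for the feature fusion module
#'
#' @param stage `"stage1"` (task classification, T = 600) or `"stage2"`
#'   (sub-phase classification on 1x200 segments).
#' @return Named list of preset values (`target_length`, `dwt_levels`,
#'   `wavelet`, `n_scales`, `lstm_hidden`, `lstm_dropout`, `lstm_lr`,
#'   `lstm_epochs`, `batch_size`, `n_select`, `criterion`, `fcn_hidden`,
#'   `fcn_lr`, `fcn_epochs`, `branch_dims`).
#' @export
ffm_preset <- function(stage = c("stage1", "stage2")) {
  stage <- match.arg(stage)
  p <- if (stage == "stage1") {
    list(target_length = 600L, dwt_levels = 8L, lstm_dropout = c(0, 0),
         lstm_epochs = 500L, n_select = 512L)
  } else {
    list(target_length = 200L, dwt_levels = 6L, lstm_dropout = c(0.2, 0.1),
         lstm_epochs = 500L, n_select = 256L)
  }
  p <- c(p, list(wavelet = "haar", n_scales = 64L,
                 lstm_hidden = c(150L, 100L), lstm_lr = 1e-2,
                 batch_size = 256L, criterion = "MID", fcn_hidden = 128L,
                 fcn_lr = 1e-3, fcn_epochs = 300L, stage = stage))
  p$branch_dims <- c(lstm = tail(p$lstm_hidden, 1L), cnn = 2048L,
                     spectral = 4L + dwt_total_length(p$target_length,
                                                      p$dwt_levels))
  p
}

# Coefficient count of the periodized DWT: sum of the ceil-halving chain
# plus the final approximation length.
dwt_total_length <- function(n, levels) {
  lens <- integer(levels)
  cur <- n
  for (l in seq_len(levels)) {
    cur <- as.integer(ceiling(cur / 2))
    lens[l] <- cur
  }
  sum(lens) + cur
}

#' Concatenate branch features in fixed order
#'
#' Fuses the LSTM, CNN and FFT/DWT branch features in that fixed order;
#' a disabled branch (`NULL`) is simply omitted, which is how the
#' single-branch ablations are built. Under the task-stage preset the
#' fused vector has `100 + 2048 + 607 = 2755` entries.
#'
#' @param fL,fR,fF Branch feature vectors (or `n x d` matrices), or `NULL`
#'   for a disabled branch.
#' @param expected_dims Optional named vector (`lstm`, `cnn`, `spectral`)
#'   against which supplied branch widths are checked.
#' @return Fused vector (or matrix) of width equal to the sum of the
#'   enabled branch widths.
#' @export
fuse_features <- function(fL = NULL, fR = NULL, fF = NULL,
                          expected_dims = NULL) {
  parts <- list(lstm = fL, cnn = fR, spectral = fF)
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) stopf("at least one branch must be enabled")
  single <- !is.matrix(parts[[1L]])
  parts <- lapply(parts, function(p) if (is.matrix(p)) p else matrix(p, nrow = 1L))
  if (!is.null(expected_dims)) {
    for (nm in names(parts)) {
      if (!is.na(expected_dims[nm]) && ncol(parts[[nm]]) != expected_dims[nm])
        stopf("branch '%s' has width %d, preset expects %d",
              nm, ncol(parts[[nm]]), expected_dims[nm])
    }
  }
  out <- do.call(cbind, parts)
  colnames(out) <- unlist(lapply(names(parts), function(nm)
    paste0(nm, "_", seq_len(ncol(parts[[nm]])))))
  if (single) drop(out) else out
}

# Spectral feature block for every row of a signal matrix.
spectral_features_matrix <- function(X, tr, preset) {
  d <- preset$branch_dims[["spectral"]]
  t(vapply(seq_len(nrow(X)), function(i)
    unname(spectral_block(X[i, ], tr_seconds = tr[i],
                          wavelet = preset$wavelet,
                          levels = preset$dwt_levels)),
    numeric(d)))
}

# CNN feature block: scalogram -> rendered image -> residual network.
cnn_features_matrix <- function(X, tr, preset, weights) {
  t(vapply(seq_len(nrow(X)), function(i) {
    sc <- cwt_scalogram(X[i, ], n_scales = preset$n_scales, tr_seconds = tr[i])
    cnn_scalogram_features(render_scalogram_image(sc), weights)
  }, numeric(2048L)))
}

#' Fit one feature fusion classification system
#'
#' Trains the LSTM branch (with a temporary softmax head) on the training
#' signals, extracts all enabled branch features, fuses them, selects
#' features by MRMR, and trains the fully-connected classifier — all on the
#' supplied (training) data only.
#'
#' @param X `n x T` matrix of conditioned, padded signals (rows), with `T`
#'   equal to the preset target length.
#' @param labels Length-n class labels.
#' @param tr_seconds Per-signal repetition times (scalar recycled).
#' @param preset A stage preset from [ffm_preset()].
#' @param branches Enabled branches, subset of
#'   `c("lstm", "cnn", "spectral")`.
#' @param lstm_epochs,fcn_epochs Optional overrides of the preset epoch
#'   counts (examples and tests use reduced epochs).
#' @param seed Integer seed controlling all stochastic fitting.
#' @param resnet_seed Seed of the fixed random CNN weights.
#' @param cache Optional list with precomputed feature matrices `fR`, `fF`
#'   (rows aligned with `X`), used to avoid recomputing training-independent
#'   branch features across folds and models.
#' @return An object of class `ffm_system`.
#' @export
fit_ffm <- function(X, labels, tr_seconds = 1, preset = ffm_preset("stage1"),
                    branches = c("lstm", "cnn", "spectral"),
                    lstm_epochs = NULL, fcn_epochs = NULL, seed = 1L,
                    resnet_seed = 42L, cache = NULL) {
  branches <- match.arg(branches, several.ok = TRUE)
  if (!is.matrix(X)) stopf("`X` must be a matrix of signals in rows")
  if (ncol(X) != preset$target_length)
    stopf("signals have length %d; preset expects %d (pad first)",
          ncol(X), preset$target_length)
  tr <- rep_len(tr_seconds, nrow(X))
  lstm <- NULL
  fL <- fR <- fF <- NULL
  if ("lstm" %in% branches) {
    lstm <- train_lstm_branch(X, labels, hidden_sizes = preset$lstm_hidden,
                              dropout = preset$lstm_dropout,
                              lr = preset$lstm_lr,
                              epochs = lstm_epochs %||% preset$lstm_epochs,
                              batch_size = preset$batch_size, seed = seed)
    fL <- lstm_encode(X, lstm)
  }
  if ("cnn" %in% branches) {
    fR <- cache$fR %||% cnn_features_matrix(X, tr, preset,
                                            resnet50_weights(seed = resnet_seed))
  }
  if ("spectral" %in% branches) {
    fF <- cache$fF %||% spectral_features_matrix(X, tr, preset)
  }
  fused <- fuse_features(fL, fR, fF)
  m <- min(preset$n_select, ncol(fused))
  selection <- NULL
  idx <- seq_len(ncol(fused))
  if (m < ncol(fused)) {
    selection <- mrmr_select(feature_matrix(fused, labels), m = m,
                             criterion = preset$criterion)
    idx <- selection$indices
  }
  fcn <- train_fcn(fused[, idx, drop = FALSE], labels,
                   hidden = preset$fcn_hidden, lr = preset$fcn_lr,
                   epochs = fcn_epochs %||% preset$fcn_epochs,
                   batch_size = preset$batch_size, seed = seed + 7L)
  structure(list(preset = preset, branches = branches, lstm = lstm,
                 resnet_seed = resnet_seed, selection = selection,
                 sel_indices = idx, fcn = fcn, classes = fcn$classes),
            class = "ffm_system")
}

#' @export
print.ffm_system <- function(x, ...) {
  cat(sprintf("<ffm_system> %s | branches: %s | %d selected features | classes: %s\n",
              x$preset$stage, paste(x$branches, collapse = "+"),
              length(x$sel_indices), paste(x$classes, collapse = ", ")))
  invisible(x)
}

# Branch features + fused matrix for prediction.
ffm_feature_matrix <- function(system, X, tr, cache = NULL) {
  tr <- rep_len(tr, nrow(X))
  fL <- if ("lstm" %in% system$branches) lstm_encode(X, system$lstm)
  fR <- if ("cnn" %in% system$branches)
    cache$fR %||% cnn_features_matrix(X, tr, system$preset,
                                      resnet50_weights(seed = system$resnet_seed))
  fF <- if ("spectral" %in% system$branches)
    cache$fF %||% spectral_features_matrix(X, tr, system$preset)
  fuse_features(fL, fR, fF)
}

#' Predict with a fitted feature fusion system
#'
#' @param object A fitted [fit_ffm()] system.
#' @param X `n x T` matrix of conditioned, padded signals.
#' @param tr_seconds Per-signal repetition times.
#' @param cache Optional precomputed `fR`/`fF` feature matrices.
#' @param ... Unused.
#' @return List with `labels` (predicted classes) and `scores`
#'   (`n x C` softmax matrix).
#' @export
predict.ffm_system <- function(object, X, tr_seconds = 1, cache = NULL, ...) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != object$preset$target_length)
    stopf("signals have length %d; system expects %d", ncol(X),
          object$preset$target_length)
  fused <- ffm_feature_matrix(object, X, tr_seconds, cache)
  if (!is.matrix(fused)) fused <- matrix(fused, nrow = 1L)
  P <- predict_fcn(object$fcn, fused[, object$sel_indices, drop = FALSE])
  list(labels = colnames(P)[max.col(P, ties.method = "first")], scores = P)
}
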