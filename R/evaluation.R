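# Cross-validation planning, classification metrics, and pairwise
# classifier-diversity tables; plus the benchmark harness comparing the
# fused system against its single-branch ablations on shared folds.

#' Plan a k-fold cross-validation split
#'
#' Plain mode shuffles indices and gives every test fold exactly
#' `floor(n/k)` samples, with the remainder always retained in training
#' (for n = 19221 and k = 12 this yields the 17620/1601 train/test split).
#' By-subject mode partitions subjects across folds so no subject ever
#' appears in both the training and test side of a fold.
#'
#' @param n Number of samples (>= k).
#' @param k Number of folds (>= 2).
#' @param subjects Per-sample subject ids (required for by-subject mode).
#' @param seed Optional shuffling seed.
#' @param mode `"plain"` or `"by-subject"`.
#' @return An object of class `fold_plan` with per-fold test index lists.
#' @export
kfold_partition <- function(n, k, subjects = NULL, seed = NULL,
                            mode = c("plain", "by-subject")) {
  mode <- match.arg(mode)
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) stopf("k must be >= 2")
  if (k > n) stopf("k (%d) exceeds the number of samples (%d)", k, n)
  test_sets <- if (mode == "plain") {
    ord <- with_local_seed(seed, sample.int(n))
    size <- n %/% k
    lapply(seq_len(k), function(i) sort(ord[((i - 1L) * size + 1L):(i * size)]))
  } else {
    if (is.null(subjects)) stopf("by-subject mode needs `subjects`")
    if (length(subjects) != n) stopf("`subjects` must have length n")
    u <- unique(subjects)
    if (k > length(u))
      stopf("k (%d) exceeds the number of subjects (%d)", k, length(u))
    u <- with_local_seed(seed, sample(u))
    fold_of <- rep(seq_len(k), length.out = length(u))
    lapply(seq_len(k), function(i)
      which(subjects %in% u[fold_of == i]))
  }
  structure(list(k = k, n = n, mode = mode, test_indices = test_sets,
                 subjects = subjects),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k=%d, n=%d, mode=%s, test sizes: %s\n", x$k, x$n,
              x$mode, paste(lengths(x$test_indices), collapse = ", ")))
  invisible(x)
}

fold_test <- function(plan, i) plan$test_indices[[i]]
fold_train <- function(plan, i) setdiff(seq_len(plan$n), plan$test_indices[[i]])

#' Classification metrics report
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 (harmonic
#' mean), reported as percentages, plus overall accuracy and the confusion
#' matrix (true classes in rows). A class never predicted gets precision 0.
#'
#' @param predictions Predicted class labels.
#' @param labels True class labels (same length).
#' @param classes Optional class set (defaults to the union observed).
#' @return An object of class `metrics_report`: `confusion`, `per_class`
#'   (data.frame of percentages), `accuracy` (percent), `n`.
#' @export
classification_metrics <- function(predictions, labels, classes = NULL) {
  if (length(predictions) != length(labels))
    stopf("`predictions` and `labels` must have equal lengths")
  classes <- classes %||% sort(unique(c(as.character(labels),
                                        as.character(predictions))))
  truth <- factor(as.character(labels), levels = classes)
  pred <- factor(as.character(predictions), levels = classes)
  if (anyNA(truth) || anyNA(pred)) stopf("labels outside the class set")
  cm <- table(truth = truth, predicted = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    confusion = cm,
    per_class = data.frame(class = classes, precision = 100 * prec,
                           recall = 100 * rec, f1 = 100 * f1,
                           row.names = NULL),
    accuracy = 100 * sum(tp) / length(labels),
    n = length(labels)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d, accuracy=%.2f%%\n", x$n, x$accuracy))
  pc <- x$per_class
  pc[-1L] <- round(pc[-1L], 2L)
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Pairwise classifier-diversity table
#'
#' Cross-tabulates the per-sample correctness of two classifiers: both hit,
#' A hits/B misses, A misses/B hits, both miss. Cells always sum to the
#' number of evaluated samples.
#'
#' @param predsA,predsB Predictions of the two classifiers.
#' @param labels True labels.
#' @return A 2x2 integer matrix of class `diversity_table` (rows: A
#'   hit/miss, columns: B hit/miss).
#' @export
diversity_table <- function(predsA, predsB, labels) {
  if (length(predsA) != length(labels) || length(predsB) != length(labels))
    stopf("predictions and labels must have equal lengths")
  hitA <- factor(predsA == labels, levels = c(TRUE, FALSE))
  hitB <- factor(predsB == labels, levels = c(TRUE, FALSE))
  tab <- table(A = hitA, B = hitB)
  dimnames(tab) <- list(A = c("hit", "miss"), B = c("hit", "miss"))
  structure(unclass(tab), class = "diversity_table")
}

#' @export
print.diversity_table <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

# Fit selection + classifier on the training rows of a precomputed fused
# feature matrix and predict the test rows (branch features are extracted
# once and shared across models; selection and the classifier only ever see
# training rows).
fit_eval_model <- function(fused, labels, train, test, n_select, criterion,
                           fcn_hidden, fcn_lr, fcn_epochs, batch_size, seed) {
  m <- min(n_select, ncol(fused))
  idx <- seq_len(ncol(fused))
  if (m < ncol(fused)) {
    sel <- mrmr_select(feature_matrix(fused[train, , drop = FALSE],
                                      labels[train]),
                       m = m, criterion = criterion)
    idx <- sel$indices
  }
  fcn <- train_fcn(fused[train, idx, drop = FALSE], labels[train],
                   hidden = fcn_hidden, lr = fcn_lr, epochs = fcn_epochs,
                   batch_size = batch_size, seed = seed)
  P <- predict_fcn(fcn, fused[test, idx, drop = FALSE])
  colnames(P)[max.col(P, ties.method = "first")]
}

# One stage of the benchmark: given branch feature blocks for the whole
# dataset and a fold plan over it, evaluate each model on each fold.
evaluate_stage <- function(blocks, labels, plan, folds, models, preset,
                           lstm_spec, fcn_epochs, seed, batch_size) {
  branch_sets <- list(ffm = c("lstm", "cnn", "spectral"), lstm = "lstm",
                      cnn = "cnn")
  preds <- lapply(models, function(m) character(0))
  names(preds) <- models
  truth <- character(0)
  per_fold <- list()
  for (f in folds) {
    train <- fold_train(plan, f); test <- fold_test(plan, f)
    lstm_fit <- train_lstm_branch(
      lstm_spec$X[train, , drop = FALSE], labels[train],
      hidden_sizes = preset$lstm_hidden, dropout = preset$lstm_dropout,
      lr = preset$lstm_lr, epochs = lstm_spec$epochs,
      batch_size = batch_size, seed = seed + f)
    fL <- lstm_encode(lstm_spec$X, lstm_fit)
    fold_preds <- list()
    for (mod in models) {
      br <- branch_sets[[mod]]
      fused <- fuse_features(
        fL = if ("lstm" %in% br) fL,
        fR = if ("cnn" %in% br) blocks$fR,
        fF = if ("spectral" %in% br) blocks$fF)
      fold_preds[[mod]] <- fit_eval_model(
        fused, labels, train, test, preset$n_select, preset$criterion,
        preset$fcn_hidden, preset$fcn_lr, fcn_epochs, batch_size,
        seed + 100L + f)
      preds[[mod]] <- c(preds[[mod]], fold_preds[[mod]])
    }
    truth <- c(truth, labels[test])
    per_fold[[length(per_fold) + 1L]] <-
      lapply(fold_preds, function(p) classification_metrics(p, labels[test]))
  }
  metrics <- lapply(models, function(mod) classification_metrics(preds[[mod]], truth))
  names(metrics) <- models
  fold_acc <- vapply(models, function(mod)
    mean(vapply(per_fold, function(pf) pf[[mod]]$accuracy, 1)), 1)
  diversity <- list()
  if ("ffm" %in% models) {
    for (other in intersect(c("lstm", "cnn"), models))
      diversity[[paste0("ffm_vs_", other)]] <-
        diversity_table(preds$ffm, preds[[other]], truth)
  }
  list(metrics = metrics, mean_fold_accuracy = fold_acc,
       per_fold = per_fold, diversity = diversity, predictions = preds,
       truth = truth)
}

#' Benchmark the fused system against single-branch models
#'
#' On shared cross-validation folds, fits and evaluates the full feature
#' fusion model and its LSTM-only and CNN-only ablations, for the task
#' stage and (optionally) the emotion and memory sub-phase stages. The
#' training-independent branch features (spectral block, fixed-weight CNN
#' embedding) are extracted once and shared; the LSTM branch is retrained
#' per fold on training signals only, as are MRMR selection and the
#' classifier.
#'
#' @param pool A labelled [signal_pool()].
#' @param k Folds of the by-subject (default) or plain partition.
#' @param mode Partition mode, see [kfold_partition()].
#' @param folds Which folds to evaluate (default all).
#' @param models Subset of `c("ffm", "lstm", "cnn")`.
#' @param stages Subset of `c("stage1", "emotion", "memory")`.
#' @param lstm_epochs,fcn_epochs Training epochs (desk-scale defaults).
#' @param batch_size Minibatch size for the LSTM branch and classifier
#'   head (desk-scale default 100; the sub-phase stage preset's nominal
#'   value is 256).
#' @param seed Integer seed.
#' @param resnet_seed Seed of the fixed random CNN weights.
#' @return List with one element per stage, each holding pooled `metrics`
#'   per model, `mean_fold_accuracy`, per-fold reports, and pairwise
#'   `diversity` tables of the fused model against each ablation.
#' @export
evaluate_system <- function(pool, k = 3L, mode = c("by-subject", "plain"),
                            folds = NULL, models = c("ffm", "lstm", "cnn"),
                            stages = c("stage1", "emotion", "memory"),
                            lstm_epochs = 10L, fcn_epochs = 150L,
                            batch_size = 100L, seed = 1L,
                            resnet_seed = 42L) {
  stopifnot(inherits(pool, "signal_pool"))
  mode <- match.arg(mode)
  models <- match.arg(models, several.ok = TRUE)
  cond <- condition_pool(pool)
  tasks <- pool_tasks(pool)
  subjects <- pool_subjects(pool)
  tr <- vapply(pool$signals, function(s) s$tr_seconds, 1)
  weights <- resnet50_weights(seed = resnet_seed)
  out <- list()
  if ("stage1" %in% stages) {
    p1 <- ffm_preset("stage1")
    X <- t(vapply(cond, function(s) pad_to_length(s, p1$target_length)$values,
                  numeric(p1$target_length)))
    plan <- kfold_partition(length(cond), k, subjects = subjects, seed = seed,
                            mode = mode)
    blocks <- list(fF = spectral_features_matrix(X, tr, p1),
                   fR = if (any(c("ffm", "cnn") %in% models))
                     cnn_features_matrix(X, tr, p1, weights))
    out$stage1 <- evaluate_stage(blocks, tasks, plan, folds %||% seq_len(k),
                                 models, p1,
                                 list(X = X, epochs = lstm_epochs),
                                 fcn_epochs, seed, batch_size)
  }
  p2 <- ffm_preset("stage2")
  for (task in intersect(stages, c("emotion", "memory"))) {
    sel <- which(tasks == task)
    if (!length(sel)) next
    ds <- if (task == "emotion") emotion_segments(cond[sel], p2$target_length)
          else memory_segments(cond[sel], p2$target_length)
    seg_subj <- subjects[sel][ds$parent]
    plan <- kfold_partition(nrow(ds$values), k, subjects = seg_subj,
                            seed = seed, mode = mode)
    blocks <- list(fF = spectral_features_matrix(ds$values, ds$tr, p2),
                   fR = if (any(c("ffm", "cnn") %in% models))
                     cnn_features_matrix(ds$values, ds$tr, p2, weights))
    out[[paste0("stage2_", task)]] <-
      evaluate_stage(blocks, ds$labels, plan, folds %||% seq_len(k), models,
                     p2, list(X = ds$values, epochs = lstm_epochs),
                     fcn_epochs, seed, batch_size)
  }
  out
}
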