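# Minimum-redundancy maximum-relevance feature selection with a plug-in
# (histogram) mutual-information estimator in bits. Continuous features are
# discretised by quantile binning (8 bins by default) before estimation;
# the greedy search uses the incremental criterion: the first feature
# maximises relevance I(Y; F), each later feature maximises
#   MID:  I(Y; F_j) - (1/|S|) * sum_{i in S} I(F_i; F_j)
#   MIQ:  I(Y; F_j) / ((1/|S|) * sum_{i in S} I(F_i; F_j))
# so only O(K * m) pairwise MI evaluations are needed.

#' Quantile-discretise a numeric vector
#'
#' Values are cut at equally spaced quantiles (duplicate break points are
#' collapsed, so low-cardinality or constant inputs get fewer bins).
#' Inputs with at most `bins` distinct values are treated as categorical
#' and left as-is.
#'
#' @param x Numeric (or already discrete) vector.
#' @param bins Maximum number of bins (default 8).
#' @return Integer codes in `1..bins`.
#' @export
discretize_quantile <- function(x, bins = 8L) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                        names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))
  codes <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(codes)
}

mi_from_table <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Plug-in mutual information in bits
#'
#' Histogram estimator on the joint distribution of the (discretised) input
#' and a discrete target; symmetric and non-negative by construction.
#'
#' @param x Numeric sequence (quantile-discretised with `bins` bins) or an
#'   already discrete sequence.
#' @param y Discrete sequence of the same length.
#' @param bins Bin count for continuous `x` (default 8).
#' @return Mutual information I(x; y) in bits.
#' @export
mutual_information <- function(x, y, bins = 8L) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal lengths")
  if (length(x) < 2L) stopf("mutual_information() needs length >= 2")
  cx <- if (is.numeric(x)) discretize_quantile(x, bins) else match(x, unique(x))
  cy <- if (is.numeric(y)) discretize_quantile(y, bins) else match(y, unique(y))
  mi_from_table(table(cx, cy))
}

#' A labelled feature matrix
#'
#' @param values `n x K` numeric matrix (samples in rows); all entries must
#'   be finite.
#' @param labels Length-n class labels.
#' @param feature_ids Optional K feature names (defaults to column names or
#'   `f1..fK`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, feature_ids = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!all(is.finite(values))) stopf("feature matrix contains non-finite entries")
  if (length(labels) != nrow(values)) stopf("one label per sample required")
  feature_ids <- feature_ids %||% colnames(values) %||%
    paste0("f", seq_len(ncol(values)))
  structure(list(values = values, labels = as.character(labels),
                 feature_ids = feature_ids),
            class = "feature_matrix")
}

as_feature_matrix <- function(features, labels = NULL) {
  if (inherits(features, "feature_matrix")) features
  else feature_matrix(features, labels)
}

# Discretised codes for every column, plus a sparse one-hot expansion used
# to count joint histograms of one feature against all others in one
# crossprod.
discretize_matrix <- function(X, bins) {
  codes <- vapply(seq_len(ncol(X)), function(j) discretize_quantile(X[, j], bins),
                  integer(nrow(X)))
  nb <- apply(codes, 2L, max)
  offsets <- c(0L, cumsum(nb))[seq_len(ncol(X))]
  onehot <- Matrix::sparseMatrix(
    i = rep(seq_len(nrow(X)), ncol(X)),
    j = as.vector(codes + rep(offsets, each = nrow(X))),
    x = 1, dims = c(nrow(X), sum(nb)))
  list(codes = codes, nbins = nb, offsets = offsets, onehot = onehot,
       col_feature = rep(seq_len(ncol(X)), nb))
}

# MI (bits) between the discretised feature `j` and every feature, via one
# sparse crossprod: joint counts are an nb_j x sum(nb) block matrix.
mi_feature_vs_all <- function(disc, j) {
  n <- nrow(disc$codes)
  oh_j <- Matrix::sparseMatrix(i = seq_len(n), j = disc$codes[, j], x = 1,
                               dims = c(n, disc$nbins[j]))
  cnt <- as.matrix(Matrix::crossprod(oh_j, disc$onehot)) / n
  px <- rowSums(cnt[, disc$col_feature == j, drop = FALSE])
  py <- Matrix::colSums(disc$onehot) / n
  terms <- cnt * log2(cnt / (outer(px, py)))
  terms[cnt == 0] <- 0
  as.numeric(rowsum(colSums(terms), disc$col_feature))
}

mi_labels_vs_all <- function(disc, labels) {
  n <- length(labels)
  cy <- match(labels, unique(labels))
  oh_y <- Matrix::sparseMatrix(i = seq_len(n), j = cy, x = 1,
                               dims = c(n, max(cy)))
  cnt <- as.matrix(Matrix::crossprod(oh_y, disc$onehot)) / n
  px <- tabulate(cy) / n
  py <- Matrix::colSums(disc$onehot) / n
  terms <- cnt * log2(cnt / outer(px, py))
  terms[cnt == 0] <- 0
  as.numeric(rowsum(colSums(terms), disc$col_feature))
}

#' Mean relevance of a feature subset
#'
#' `V = (1/|S|) * sum_{j in S} I(Y; F_j)`.
#'
#' @param features A [feature_matrix()] (or matrix plus `labels`).
#' @param S Non-empty integer vector of feature indices.
#' @param labels Class labels when `features` is a plain matrix.
#' @param bins Discretisation bins.
#' @return Relevance V in bits.
#' @export
relevance <- function(features, S, labels = NULL, bins = 8L) {
  fm <- as_feature_matrix(features, labels)
  if (!length(S)) stopf("`S` must be non-empty")
  mean(vapply(S, function(j)
    mutual_information(fm$values[, j], fm$labels, bins), 1))
}

#' Mean pairwise redundancy of a feature subset
#'
#' `W = (1/|S|^2) * sum_{i,j in S} I(F_i; F_j)` over all ordered pairs,
#' including `i = j` (so a single feature has redundancy equal to its own
#' entropy).
#'
#' @inheritParams relevance
#' @return Redundancy W in bits.
#' @export
redundancy <- function(features, S, labels = NULL, bins = 8L) {
  fm <- as_feature_matrix(features, labels)
  if (!length(S)) stopf("`S` must be non-empty")
  tot <- 0
  for (i in S) for (j in S)
    tot <- tot + mutual_information(fm$values[, i], fm$values[, j], bins)
  tot / length(S)^2
}

#' Greedy MRMR feature selection
#'
#' The first feature maximises relevance to the labels; each subsequent
#' feature maximises the mutual-information difference (MID) or quotient
#' (MIQ) between its relevance and its mean redundancy to the already
#' selected set. Ties break to the lowest feature index; an MIQ candidate
#' with zero mean redundancy falls back to its MID score (recorded in the
#' result's `miq_fallbacks`).
#'
#' @param features A [feature_matrix()], or an `n x K` matrix with `labels`.
#' @param m Number of features to select (`1 <= m <= K`).
#' @param criterion `"MID"` (default) or `"MIQ"`.
#' @param labels Class labels when `features` is a plain matrix.
#' @param bins Discretisation bins (default 8).
#' @return An object of class `mrmr_result`: ordered `indices`, per-step
#'   `scores`, relevance trace `V_trace`, redundancy trace `W_trace`
#'   (mean pairwise MI over the selected set after each step), `criterion`,
#'   and `feature_ids`.
#' @export
mrmr_select <- function(features, m, criterion = c("MID", "MIQ"),
                        labels = NULL, bins = 8L) {
  criterion <- match.arg(criterion)
  fm <- as_feature_matrix(features, labels)
  K <- ncol(fm$values)
  m <- as.integer(assert_scalar_number(m, "m", positive = TRUE))
  if (m > K) stopf("m (%d) exceeds the number of features (%d)", m, K)
  if (length(unique(fm$labels)) < 2L)
    stopf("selection needs at least 2 classes")
  disc <- discretize_matrix(fm$values, bins)
  rel <- mi_labels_vs_all(disc, fm$labels)
  # self-information H(F_k), used for the redundancy trace
  self_mi <- vapply(seq_len(K), function(j) {
    p <- tabulate(disc$codes[, j]) / nrow(disc$codes)
    -sum(p[p > 0] * log2(p[p > 0]))
  }, 1)

  selected <- integer(m)
  scores <- numeric(m)
  V_trace <- numeric(m)
  W_trace <- numeric(m)
  miq_fallbacks <- integer()
  redsum <- numeric(K)               # sum_{i in S} I(F_i; F_j) per candidate
  pairsum <- 0                       # sum over ordered pairs within S
  remaining <- rep(TRUE, K)

  pick <- which(remaining & rel == max(rel[remaining]))[1L]
  for (step in seq_len(m)) {
    if (step > 1L) {
      sc <- rep(-Inf, K)
      meanred <- redsum / (step - 1L)
      if (criterion == "MID") {
        sc[remaining] <- rel[remaining] - meanred[remaining]
      } else {
        zero <- remaining & meanred <= 0
        pos <- remaining & meanred > 0
        sc[pos] <- rel[pos] / meanred[pos]
        sc[zero] <- rel[zero] - meanred[zero]
        if (any(zero)) miq_fallbacks <- c(miq_fallbacks, which(zero))
      }
      pick <- which(remaining & sc == max(sc[remaining]))[1L]
      scores[step] <- sc[pick]
    } else {
      scores[step] <- rel[pick]
    }
    selected[step] <- pick
    remaining[pick] <- FALSE
    pairsum <- pairsum + 2 * redsum[pick] + self_mi[pick]
    V_trace[step] <- mean(rel[selected[seq_len(step)]])
    W_trace[step] <- pairsum / step^2
    if (step < m) redsum <- redsum + mi_feature_vs_all(disc, pick)
  }
  structure(list(indices = selected, scores = scores, V_trace = V_trace,
                 W_trace = W_trace, criterion = criterion,
                 feature_ids = fm$feature_ids[selected],
                 miq_fallbacks = unique(miq_fallbacks)),
            class = "mrmr_result")
}

#' @export
print.mrmr_result <- function(x, ...) {
  cat(sprintf("<mrmr_result> %s, %d features selected\n", x$criterion,
              length(x$indices)))
  cat("first indices:", head(x$indices, 10L), "\n")
  invisible(x)
}
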