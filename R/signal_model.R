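#' @useDynLib boldcascade, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft dgamma filter rnorm runif quantile sd
#' @importFrom utils head tail
NULL

TASK_LEVELS <- c("emotion", "memory", "motor", "resting")
SUBPHASE_LEVELS <- c("high", "medium", "low", "encode", "recall")

#' Construct a labelled BOLD time series
#'
#' A `bold_signal` holds one ROI-averaged (or voxel) BOLD time series sampled
#' at a fixed repetition time (TR), together with the task label, the subject
#' it was recorded from, and an optional block-design annotation giving
#' labelled segments (e.g. the encode/recall blocks of a memory run).
#'
#' @param values Numeric vector, one sample per TR (arbitrary units).
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param task_label One of `"emotion"`, `"memory"`, `"motor"`, `"resting"`,
#'   or `"unknown"`.
#' @param subject_id Subject identifier string.
#' @param design Optional `data.frame` with columns `label`, `start`, `end`
#'   (1-based inclusive sample indices) annotating block phases. Blocks must
#'   lie within the signal and must not overlap.
#'
#' @return An object of class `bold_signal`.
#' @export
bold_signal <- function(values, tr_seconds, task_label = "unknown",
                        subject_id = "unknown", design = NULL) {
  if (!is.numeric(values) || length(values) < 1L)
    stopf("`values` must be a non-empty numeric vector")
  if (anyNA(values)) stopf("`values` must not contain NA")
  assert_scalar_number(tr_seconds, "tr_seconds", positive = TRUE)
  task_label <- match.arg(task_label, c(TASK_LEVELS, "unknown"))
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    stopf("`subject_id` must be a non-empty string")
  if (!is.null(design)) design <- validate_design(design, length(values))
  structure(
    list(values = as.numeric(values), tr_seconds = as.numeric(tr_seconds),
         task_label = task_label, subject_id = subject_id, design = design),
    class = "bold_signal")
}

validate_design <- function(design, n) {
  if (!is.data.frame(design) || !all(c("label", "start", "end") %in% names(design)))
    stopf("`design` must be a data.frame with columns label, start, end")
  design <- data.frame(label = as.character(design$label),
                       start = as.integer(design$start),
                       end = as.integer(design$end),
                       stringsAsFactors = FALSE)
  if (nrow(design)) {
    if (any(design$start < 1L) || any(design$end > n) || any(design$end < design$start))
      stopf("design blocks must satisfy 1 <= start <= end <= %d", n)
    o <- order(design$start)
    design <- design[o, , drop = FALSE]
    if (nrow(design) > 1L && any(design$start[-1L] <= design$end[-nrow(design)]))
      stopf("design blocks must not overlap")
    rownames(design) <- NULL
  }
  design
}

#' Per-segment sub-phase labels of a signal's design annotation
#'
#' @param signal A [bold_signal()].
#' @return Character vector of the non-rest block labels, in temporal order
#'   (empty when no design is present).
#' @export
subphase_labels <- function(signal) {
  stopifnot(inherits(signal, "bold_signal"))
  if (is.null(signal$design)) return(character())
  lab <- signal$design$label
  lab[lab %in% SUBPHASE_LEVELS]
}

#' @export
print.bold_signal <- function(x, ...) {
  cat(sprintf("<bold_signal> %s | subject %s | %d samples @ TR=%gs",
              x$task_label, x$subject_id, length(x$values), x$tr_seconds))
  if (!is.null(x$design))
    cat(sprintf(" | %d design blocks", nrow(x$design)))
  cat("\n")
  invisible(x)
}

#' Construct a pool of BOLD signals
#'
#' A `signal_pool` is the dataset container for classification: a list of
#' [bold_signal()] objects together with the common length every signal is
#' padded to before entering the networks.
#'
#' @param signals List of [bold_signal()] objects; every one must carry a
#'   `subject_id`.
#' @param target_length Common post-padding length (default 600).
#' @param provenance Free-text description of where the pool came from.
#' @return An object of class `signal_pool`.
#' @export
signal_pool <- function(signals, target_length = 600L, provenance = "") {
  if (!is.list(signals) || !all(vapply(signals, inherits, TRUE, "bold_signal")))
    stopf("`signals` must be a list of bold_signal objects")
  target_length <- as.integer(assert_scalar_number(target_length, "target_length",
                                                   positive = TRUE))
  lens <- vapply(signals, function(s) length(s$values), 1L)
  if (any(lens > target_length))
    stopf("signal %d is longer (%d) than target_length (%d)",
          which.max(lens), max(lens), target_length)
  structure(list(signals = signals, target_length = target_length,
                 provenance = as.character(provenance)[1L]),
            class = "signal_pool")
}

#' @export
print.signal_pool <- function(x, ...) {
  tasks <- vapply(x$signals, function(s) s$task_label, "")
  cat(sprintf("<signal_pool> %d signals, target length %d\n",
              length(x$signals), x$target_length))
  print(table(task = tasks))
  invisible(x)
}

#' @export
length.signal_pool <- function(x) length(x$signals)

#' Task labels / subject ids of all signals in a pool
#'
#' @param pool A [signal_pool()].
#' @return Character vector, one entry per signal.
#' @export
pool_tasks <- function(pool) vapply(pool$signals, function(s) s$task_label, "")

#' @rdname pool_tasks
#' @export
pool_subjects <- function(pool) vapply(pool$signals, function(s) s$subject_id, "")

#' Remove the mean and the best-fit line from a signal
#'
#' Standard pool-level conditioning: the least-squares straight line
#' (intercept + slope) is removed, so the output has exactly zero mean and
#' zero linear trend. Applied to whole signals before padding, so the zero
#' pad value equals the conditioned signal's mean.
#'
#' @param signal A [bold_signal()] with at least 2 samples.
#' @return The conditioned `bold_signal` (metadata unchanged).
#' @export
zero_mean_detrend <- function(signal) {
  stopifnot(inherits(signal, "bold_signal"))
  v <- signal$values
  n <- length(v)
  if (n < 2L) stopf("zero_mean_detrend() needs at least 2 samples")
  t <- seq_len(n) - (n + 1) / 2          # centred time axis
  slope <- sum(t * v) / sum(t * t)
  signal$values <- v - mean(v) - slope * t
  signal
}

#' Zero-pad a signal at the end to a target length
#'
#' Samples are preserved at the start and the tail is filled with zeros;
#' signals longer than `target` raise an error (no silent truncation).
#'
#' @param signal A [bold_signal()].
#' @param target Target length (>= current length).
#' @return The padded `bold_signal`.
#' @export
pad_to_length <- function(signal, target) {
  stopifnot(inherits(signal, "bold_signal"))
  target <- as.integer(assert_scalar_number(target, "target", positive = TRUE))
  n <- length(signal$values)
  if (n > target)
    stopf("signal length (%d) exceeds target (%d); refusing to truncate", n, target)
  if (n < target) signal$values <- c(signal$values, numeric(target - n))
  signal
}

#' Split a signal into equal contiguous phases
#'
#' Used for the sub-phase stage of emotion runs, whose three support phases
#' are sequential and equally spaced: a length-600 run splits into three
#' 1x200 segments.
#'
#' @param signal A [bold_signal()] whose length is divisible by `n_segments`.
#' @param n_segments Number of equal segments (>= 1).
#' @return List of `n_segments` `bold_signal` segments in temporal order;
#'   their concatenation reproduces the input exactly.
#' @export
split_into_phases <- function(signal, n_segments) {
  stopifnot(inherits(signal, "bold_signal"))
  n_segments <- as.integer(assert_scalar_number(n_segments, "n_segments",
                                                positive = TRUE))
  n <- length(signal$values)
  if (n %% n_segments != 0L)
    stopf("signal length %d is not divisible by %d segments", n, n_segments)
  w <- n %/% n_segments
  lapply(seq_len(n_segments), function(i) {
    seg <- signal
    seg$values <- signal$values[((i - 1L) * w + 1L):(i * w)]
    seg$design <- NULL
    seg
  })
}

#' Extract labelled design blocks of a signal
#'
#' For block designs with explicit phase annotations (the memory task's
#' rest/encode/rest/recall layout), returns one segment per labelled
#' non-rest block, carrying its sub-phase label.
#'
#' @param signal A [bold_signal()] with design metadata.
#' @return A list with one element per labelled block, each a list with
#'   fields `signal` (the segment as a `bold_signal`) and `label`.
#' @export
extract_design_segments <- function(signal) {
  stopifnot(inherits(signal, "bold_signal"))
  if (is.null(signal$design))
    stopf("signal has no design metadata; cannot extract labelled segments")
  keep <- signal$design$label %in% SUBPHASE_LEVELS
  blocks <- signal$design[keep, , drop = FALSE]
  lapply(seq_len(nrow(blocks)), function(i) {
    seg <- signal
    seg$values <- signal$values[blocks$start[i]:blocks$end[i]]
    seg$design <- NULL
    list(signal = seg, label = blocks$label[i])
  })
}
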