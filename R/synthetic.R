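# Synthetic block-design BOLD generator: boxcar stimulus convolved with a
# canonical double-gamma HRF, plus AR(1) noise and slow polynomial drift.
# Default specs mirror the acquisition layout of the four tasks: resting
# 180 samples (TR=3), motor 200 samples (TR=2, 10 x [20 s rest + 20 s
# movement]), emotion 600 samples with three equal sequential support
# phases, memory 600 samples with rest/encode/rest/recall blocks.

#' Noise specification for the synthetic generator
#'
#' @param white_sd Innovation standard deviation of the AR(1) process (>= 0).
#' @param drift_amplitude Standard deviation of the random low-order
#'   polynomial drift coefficients (>= 0).
#' @param ar1_coefficient AR(1) coefficient in `[0, 1)`.
#' @param seed Optional integer seed making one signal reproducible on its
#'   own; when `NULL` the surrounding RNG stream is used.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 0.4, drift_amplitude = 0.6,
                       ar1_coefficient = 0.3, seed = NULL) {
  if (white_sd < 0 || drift_amplitude < 0)
    stopf("noise magnitudes must be >= 0")
  if (ar1_coefficient < 0 || ar1_coefficient >= 1)
    stopf("`ar1_coefficient` must be in [0, 1)")
  structure(list(white_sd = white_sd, drift_amplitude = drift_amplitude,
                 ar1_coefficient = ar1_coefficient, seed = seed),
            class = "noise_spec")
}

#' Task design specification for the synthetic generator
#'
#' @param task Task class, one of `"emotion"`, `"memory"`, `"motor"`,
#'   `"resting"`.
#' @param tr_seconds Repetition time in seconds.
#' @param n_samples Number of samples acquired.
#' @param blocks `data.frame` with columns `label`, `onset` (1-based sample),
#'   `duration` (samples), `amplitude`; stimulus boxcar blocks. May be empty
#'   only for the resting task.
#' @param noise A [noise_spec()].
#' @return A list of class `task_design_spec`.
#' @export
task_design_spec <- function(task, tr_seconds, n_samples, blocks,
                             noise = noise_spec()) {
  task <- match.arg(task, TASK_LEVELS)
  n_samples <- as.integer(assert_scalar_number(n_samples, "n_samples",
                                               positive = TRUE))
  assert_scalar_number(tr_seconds, "tr_seconds", positive = TRUE)
  if (!is.data.frame(blocks) ||
      !all(c("label", "onset", "duration", "amplitude") %in% names(blocks)))
    stopf("`blocks` must have columns label, onset, duration, amplitude")
  if (nrow(blocks)) {
    if (any(blocks$onset < 1L) ||
        any(blocks$onset + blocks$duration - 1L > n_samples))
      stopf("blocks must lie within [1, n_samples]")
  }
  stopifnot(inherits(noise, "noise_spec"))
  structure(list(task = task, tr_seconds = tr_seconds, n_samples = n_samples,
                 blocks = blocks, noise = noise),
            class = "task_design_spec")
}

#' Canonical double-gamma haemodynamic response function
#'
#' The BOLD response to a stimulus is modelled as the convolution of the
#' stimulus boxcar with this kernel: a gamma density peaking around 5 s
#' minus a scaled, later gamma density modelling the post-stimulus
#' undershoot. The kernel is normalised to a peak of 1.
#'
#' @param tr_seconds Sampling interval in seconds (> 0).
#' @param duration_seconds Kernel support in seconds (> 0, default 32).
#' @param params List with positive gamma-shape parameters `peak_shape`,
#'   `undershoot_shape`, `rate`, and the `undershoot_ratio` subtracted from
#'   the peak response.
#' @return Numeric kernel sampled at `0, tr, 2*tr, ...` up to
#'   `duration_seconds`.
#' @export
canonical_hrf <- function(tr_seconds, duration_seconds = 32,
                          params = list(peak_shape = 6, undershoot_shape = 16,
                                        rate = 1, undershoot_ratio = 1 / 6)) {
  assert_scalar_number(tr_seconds, "tr_seconds", positive = TRUE)
  assert_scalar_number(duration_seconds, "duration_seconds", positive = TRUE)
  p <- utils::modifyList(list(peak_shape = 6, undershoot_shape = 16, rate = 1,
                              undershoot_ratio = 1 / 6), params)
  if (p$peak_shape <= 0 || p$undershoot_shape <= 0 || p$rate <= 0)
    stopf("gamma-shape parameters must be positive")
  t <- seq(0, duration_seconds, by = tr_seconds)
  h <- dgamma(t, shape = p$peak_shape, rate = p$rate) -
    p$undershoot_ratio * dgamma(t, shape = p$undershoot_shape, rate = p$rate)
  h / max(abs(h))
}

# Phase annotation derived from stimulus blocks: one block per distinct
# non-rest label spanning its first onset to its last offset (event trains
# such as the recall mini-blocks collapse into a single annotated phase).
blocks_to_design <- function(blocks) {
  labs <- setdiff(unique(blocks$label), "rest")
  if (!length(labs)) return(NULL)
  design <- do.call(rbind, lapply(labs, function(l) {
    b <- blocks[blocks$label == l, , drop = FALSE]
    data.frame(label = l, start = min(b$onset),
               end = max(b$onset + b$duration - 1L), stringsAsFactors = FALSE)
  }))
  design[order(design$start), , drop = FALSE]
}

#' Generate one synthetic BOLD signal
#'
#' The stimulus boxcar defined by `spec$blocks` is convolved with the
#' canonical HRF; AR(1) noise and a random quadratic drift are added. The
#' phase annotation derived from the blocks is embedded in the returned
#' signal's design metadata.
#'
#' @param spec A [task_design_spec()].
#' @param subject_id Subject identifier stored on the signal.
#' @return A [bold_signal()] of length `spec$n_samples`.
#' @export
generate_signal <- function(spec, subject_id = "sim") {
  stopifnot(inherits(spec, "task_design_spec"))
  if (spec$task != "resting" && nrow(spec$blocks) == 0L)
    stopf("non-resting task '%s' needs at least one stimulus block", spec$task)
  n <- spec$n_samples
  box <- numeric(n)
  for (i in seq_len(nrow(spec$blocks))) {
    idx <- spec$blocks$onset[i]:(spec$blocks$onset[i] + spec$blocks$duration[i] - 1L)
    box[idx] <- box[idx] + spec$blocks$amplitude[i]
  }
  h <- canonical_hrf(spec$tr_seconds)
  clean <- convolve_signal(box, h)
  ns <- spec$noise
  values <- with_local_seed(ns$seed, {
    ar <- if (ns$white_sd > 0) {
      innov <- rnorm(n, sd = ns$white_sd)
      if (ns$ar1_coefficient > 0)
        as.numeric(filter(innov, ns$ar1_coefficient, method = "recursive"))
      else innov
    } else numeric(n)
    u <- seq(-1, 1, length.out = n)
    drift <- if (ns$drift_amplitude > 0)
      rnorm(1, sd = ns$drift_amplitude) * u +
        rnorm(1, sd = ns$drift_amplitude) * (u^2 - 1 / 3)
    else numeric(n)
    clean + ar + drift
  })
  bold_signal(values, tr_seconds = spec$tr_seconds, task_label = spec$task,
              subject_id = subject_id, design = blocks_to_design(spec$blocks))
}

# Linear convolution truncated to the signal length.
convolve_signal <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(x, rev(kernel), type = "open")
  out[seq_len(n)]
}

#' Default per-task design specifications
#'
#' * resting: 180 samples at TR=3 s, noise only.
#' * motor: 200 samples at TR=2 s, ten repeats of 20 s rest + 20 s movement.
#' * emotion: 600 samples at TR=3 s, three equal sequential support phases
#'   modelled as reward-event trains whose event rate and response
#'   amplitude both follow the support level (high: 16 events at amplitude
#'   1.0 > medium: 8 at 0.8 > low: 3 at 0.6), so each phase has a
#'   monotone activation level and a distinct temporal signature that
#'   survives pool-level detrending.
#' * memory: 600 samples at TR=3 s, rest/encode/rest/recall; encode is one
#'   sustained block, recall a train of short event blocks, giving the two
#'   phases distinct amplitude and frequency signatures.
#'
#' @param noise A [noise_spec()] shared by all four tasks.
#' @return Named list of [task_design_spec()] objects.
#' @export
default_class_specs <- function(noise = noise_spec()) {
  blocks <- function(label, onset, duration, amplitude)
    data.frame(label = label, onset = as.integer(onset),
               duration = as.integer(duration), amplitude = amplitude,
               stringsAsFactors = FALSE)
  empty <- blocks(character(), integer(), integer(), numeric())
  list(
    resting = task_design_spec("resting", 3, 180L, empty, noise),
    motor = task_design_spec("motor", 2, 200L,
      blocks("move", seq(11L, 191L, by = 20L), 10L, 1.0), noise),
    emotion = task_design_spec("emotion", 3, 600L,
      rbind(blocks("high", seq(5L, by = 12L, length.out = 16L), 4L, 1.0),
            blocks("medium", seq(205L, by = 25L, length.out = 8L), 4L, 0.8),
            blocks("low", seq(405L, by = 64L, length.out = 3L), 4L, 0.6)),
      noise),
    memory = task_design_spec("memory", 3, 600L,
      rbind(blocks("encode", 101L, 200L, 1.0),
            blocks("recall", seq(401L, 581L, by = 20L), 10L, 1.2)), noise))
}

#' Generate a balanced labelled pool of synthetic signals
#'
#' Subjects are assigned round-robin within each class, so every subject
#' contributes signals of every class (as required for leave-subjects-out
#' evaluation). A per-signal amplitude factor drawn from U(0.8, 1.2) mimics
#' inter-subject response variability.
#'
#' @param n_per_class Signals per task class (>= 1).
#' @param n_subjects Number of subjects (>= 2).
#' @param class_specs Named list of [task_design_spec()], one per class
#'   (default [default_class_specs()]).
#' @param seed Integer seed; the whole pool is reproducible given it.
#' @param target_length Pool padding length (default 600).
#' @return A [signal_pool()] of `n_per_class * length(class_specs)` signals.
#' @export
generate_pool <- function(n_per_class = 150L, n_subjects = 12L,
                          class_specs = default_class_specs(), seed = 1L,
                          target_length = 600L) {
  if (n_per_class < 1L) stopf("`n_per_class` must be >= 1")
  if (n_subjects < 2L) stopf("`n_subjects` must be >= 2")
  unknown <- setdiff(names(class_specs), TASK_LEVELS)
  if (length(unknown) || is.null(names(class_specs)))
    stopf("unknown class key(s): %s", paste(unknown, collapse = ", "))
  subjects <- sprintf("sub-%02d", seq_len(n_subjects))
  signals <- with_local_seed(seed, {
    out <- vector("list", n_per_class * length(class_specs))
    k <- 0L
    for (cls in names(class_specs)) {
      spec <- class_specs[[cls]]
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        gain <- runif(1, 0.8, 1.2)
        s <- spec
        if (nrow(s$blocks)) s$blocks$amplitude <- s$blocks$amplitude * gain
        s$noise$seed <- NULL              # draw from the pool-level stream
        out[[k]] <- generate_signal(s, subject_id = subjects[(i - 1L) %% n_subjects + 1L])
      }
    }
    out
  })
  signal_pool(signals, target_length = target_length,
              provenance = sprintf("synthetic pool (n_per_class=%d, n_subjects=%d, seed=%d)",
                                   n_per_class, n_subjects, seed))
}
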