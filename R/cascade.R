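# Two-stage cascade: Stage I labels the task of every signal; signals
# labelled emotion or memory are then split into sub-phase segments and
# re-run through a second feature fusion system fitted at T = 200.
# Conditioning happens once at pool level (zero-mean + detrend of the whole
# signal, before padding or splitting), so sub-phase segments keep their
# relative activation levels.

# Conditioned (unpadded) signals of a pool.
condition_pool <- function(pool) lapply(pool$signals, zero_mean_detrend)

# Emotion segment dataset: equal thirds of each conditioned signal, padded
# to the sub-phase length; labels from the design annotation when present
# (in temporal order), else high/medium/low by position.
emotion_segments <- function(signals, target = 200L) {
  segs <- list(); labs <- character(); parent <- integer()
  for (i in seq_along(signals)) {
    s <- signals[[i]]
    padded <- pad_to_length(s, 3L * target)
    parts <- split_into_phases(padded, 3L)
    dl <- subphase_labels(s)
    l3 <- if (length(dl) == 3L) dl else c("high", "medium", "low")
    segs <- c(segs, parts)
    labs <- c(labs, l3)
    parent <- c(parent, rep(i, 3L))
  }
  list(values = t(vapply(segs, function(s) s$values, numeric(target))),
       labels = labs, parent = parent,
       tr = vapply(segs, function(s) s$tr_seconds, 1))
}

# Memory segment dataset: labelled design blocks padded to the sub-phase
# length; signals without design metadata fall back to equal halves.
memory_segments <- function(signals, target = 200L) {
  vals <- list(); labs <- character(); parent <- integer(); tr <- numeric()
  for (i in seq_along(signals)) {
    s <- signals[[i]]
    pieces <- if (!is.null(s$design) && length(subphase_labels(s))) {
      extract_design_segments(s)
    } else {
      halves <- split_into_phases(pad_to_length(s, 2L * target), 2L)
      list(list(signal = halves[[1L]], label = "encode"),
           list(signal = halves[[2L]], label = "recall"))
    }
    for (p in pieces) {
      seg <- pad_to_length(p$signal, target)
      vals <- c(vals, list(seg$values))
      labs <- c(labs, p$label)
      parent <- c(parent, i)
      tr <- c(tr, s$tr_seconds)
    }
  }
  list(values = do.call(rbind, vals), labels = labs, parent = parent, tr = tr)
}

#' Fit the full two-stage cascade
#'
#' Fits the Stage I task classifier on all (conditioned, padded) signals
#' and the two Stage II sub-phase classifiers on the emotion thirds and the
#' memory design segments of the corresponding training signals.
#'
#' @param pool A [signal_pool()] of labelled training signals.
#' @param branches Enabled feature branches for all systems.
#' @param lstm_epochs,fcn_epochs Optional epoch overrides.
#' @param seed Integer seed.
#' @param resnet_seed Seed of the fixed random CNN weights.
#' @param stages Which systems to fit (default all three).
#' @return An object of class `cascade_system`.
#' @export
fit_cascade <- function(pool, branches = c("lstm", "cnn", "spectral"),
                        lstm_epochs = NULL, fcn_epochs = NULL, seed = 1L,
                        resnet_seed = 42L,
                        stages = c("stage1", "emotion", "memory")) {
  stopifnot(inherits(pool, "signal_pool"))
  cond <- condition_pool(pool)
  tasks <- pool_tasks(pool)
  tr <- vapply(pool$signals, function(s) s$tr_seconds, 1)
  p1 <- ffm_preset("stage1"); p2 <- ffm_preset("stage2")
  out <- list(stage1 = NULL, stage2_emotion = NULL, stage2_memory = NULL)
  if ("stage1" %in% stages) {
    X <- t(vapply(cond, function(s) pad_to_length(s, p1$target_length)$values,
                  numeric(p1$target_length)))
    out$stage1 <- fit_ffm(X, tasks, tr_seconds = tr, preset = p1,
                          branches = branches, lstm_epochs = lstm_epochs,
                          fcn_epochs = fcn_epochs, seed = seed,
                          resnet_seed = resnet_seed)
  }
  if ("emotion" %in% stages && any(tasks == "emotion")) {
    em <- emotion_segments(cond[tasks == "emotion"], p2$target_length)
    out$stage2_emotion <- fit_ffm(em$values, em$labels, tr_seconds = em$tr,
                                  preset = p2, branches = branches,
                                  lstm_epochs = lstm_epochs,
                                  fcn_epochs = fcn_epochs, seed = seed + 1L,
                                  resnet_seed = resnet_seed)
  }
  if ("memory" %in% stages && any(tasks == "memory")) {
    me <- memory_segments(cond[tasks == "memory"], p2$target_length)
    out$stage2_memory <- fit_ffm(me$values, me$labels, tr_seconds = me$tr,
                                 preset = p2, branches = branches,
                                 lstm_epochs = lstm_epochs,
                                 fcn_epochs = fcn_epochs, seed = seed + 2L,
                                 resnet_seed = resnet_seed)
  }
  structure(out, class = "cascade_system")
}

#' Stage I task classification of one signal
#'
#' @param signal A conditioned [bold_signal()] already padded to the Stage I
#'   length (unpadded signals raise an error).
#' @param system A [fit_cascade()] result (or a Stage I `ffm_system`).
#' @return List with `label` (one of emotion/memory/motor/resting) and
#'   `scores` (length-4 named probabilities).
#' @export
stage1_classify <- function(signal, system) {
  s1 <- if (inherits(system, "cascade_system")) system$stage1 else system
  stopifnot(inherits(s1, "ffm_system"), inherits(signal, "bold_signal"))
  if (length(signal$values) != s1$preset$target_length)
    stopf("signal has length %d; Stage I expects signals padded to %d",
          length(signal$values), s1$preset$target_length)
  pr <- predict(s1, matrix(signal$values, nrow = 1L),
                tr_seconds = signal$tr_seconds)
  list(label = pr$labels[1L], scores = pr$scores[1L, ])
}

#' Stage II sub-phase classification of one signal
#'
#' Routes by the Stage I label: emotion signals are split into three equal
#' 1x200 segments classified into high/medium/low support; memory signals
#' contribute their design blocks (equal halves when no design metadata is
#' available) classified into encode/recall. Any other Stage I label is an
#' error — motor and resting runs have no sub-phases.
#'
#' @param signal A conditioned, padded [bold_signal()].
#' @param stage1_label The Stage I label deciding the route.
#' @param system A [fit_cascade()] result.
#' @return List of per-segment predictions, each with `segment`, `label`,
#'   `scores`.
#' @export
stage2_classify <- function(signal, stage1_label, system) {
  stopifnot(inherits(system, "cascade_system"), inherits(signal, "bold_signal"))
  if (!stage1_label %in% c("emotion", "memory"))
    stopf("Stage II is defined only for emotion/memory signals (got '%s')",
          stage1_label)
  if (stage1_label == "emotion") {
    sys2 <- system$stage2_emotion
    if (is.null(sys2)) stopf("no fitted emotion sub-phase system")
    segs <- split_into_phases(signal, 3L)
  } else {
    sys2 <- system$stage2_memory
    if (is.null(sys2)) stopf("no fitted memory sub-phase system")
    ds <- memory_segments(list(signal), sys2$preset$target_length)
    segs <- lapply(seq_len(nrow(ds$values)), function(i)
      bold_signal(ds$values[i, ], signal$tr_seconds,
                  task_label = signal$task_label,
                  subject_id = signal$subject_id))
  }
  target <- sys2$preset$target_length
  lapply(seq_along(segs), function(i) {
    seg <- pad_to_length(segs[[i]], target)
    pr <- predict(sys2, matrix(seg$values, nrow = 1L),
                  tr_seconds = seg$tr_seconds)
    list(segment = i, label = pr$labels[1L], scores = pr$scores[1L, ])
  })
}

#' Run the fitted cascade over a pool
#'
#' Each signal is conditioned, padded and given a Stage I prediction;
#' signals predicted emotion or memory additionally receive Stage II
#' sub-phase predictions via [stage2_classify()] (following the predicted —
#' not the true — route, so misrouting propagates observably).
#'
#' @param pool A [signal_pool()].
#' @param system A [fit_cascade()] result.
#' @return List of per-signal predictions, each with `signal_id`, `stage1`
#'   (list of `label`, `scores`) and `stage2` (list of segment predictions,
#'   or `NULL` for motor/resting routes).
#' @export
run_cascade <- function(pool, system) {
  stopifnot(inherits(pool, "signal_pool"), inherits(system, "cascade_system"))
  target <- system$stage1$preset$target_length
  lapply(seq_along(pool$signals), function(i) {
    s <- pad_to_length(zero_mean_detrend(pool$signals[[i]]), target)
    s1 <- stage1_classify(s, system)
    s2 <- if (s1$label %in% c("emotion", "memory"))
      stage2_classify(s, s1$label, system)
    list(signal_id = sprintf("%s#%d", s$subject_id, i), stage1 = s1,
         stage2 = s2)
  })
}
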