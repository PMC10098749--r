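test_that("bold_signal and signal_pool validate their invariants", {
  s <- bold_signal(1:10, tr_seconds = 2, task_label = "motor",
                   subject_id = "s1")
  expect_s3_class(s, "bold_signal")
  expect_error(bold_signal(numeric(0), 2), "non-empty")
  expect_error(bold_signal(1:10, 0), "must be > 0")
  expect_error(bold_signal(1:10, 2, design = data.frame(
    label = c("a", "b"), start = c(1, 4), end = c(5, 8))), "overlap")
  expect_error(bold_signal(1:10, 2, design = data.frame(
    label = "a", start = 1, end = 11)), "start <= end")
  expect_error(signal_pool(list(bold_signal(1:700, 2)), target_length = 600),
               "longer")
})

test_that("pool save/load round-trips values bit-exactly and metadata field-for-field", {
  pool <- generate_pool(n_per_class = 25L, n_subjects = 4L, seed = 77L)
  path <- withr::local_tempfile(fileext = ".csv")
  save_pool(pool, path)
  back <- load_pool(path)
  expect_length(back$signals, length(pool$signals))
  expect_identical(lapply(pool$signals, `[[`, "values"),
                   lapply(back$signals, `[[`, "values"))
  expect_identical(lapply(pool$signals, `[[`, "design"),
                   lapply(back$signals, `[[`, "design"))
  expect_identical(pool_subjects(pool), pool_subjects(back))
  expect_identical(pool_tasks(pool), pool_tasks(back))
  expect_identical(vapply(pool$signals, `[[`, 1, "tr_seconds"),
                   vapply(back$signals, `[[`, 1, "tr_seconds"))
})

test_that("a small hand-written pool file loads, and malformed files name the line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,task_label,subphase_spec,tr_seconds,s0,s1,s2,s3",
    "a,motor,,2,0.5,1,1.5,2",
    "b,resting,,3,1,2,3,",
    "a,memory,encode:1:2;recall:3:4,3,4,3,2,1"), path)
  pool <- load_pool(path)
  expect_length(pool$signals, 3L)
  expect_identical(pool$signals[[2]]$values, c(1, 2, 3))
  expect_identical(subphase_labels(pool$signals[[3]]), c("encode", "recall"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,subphase_spec,tr_seconds,s0", "a,,2,1"), bad)
  expect_error(load_pool(bad), "task_label")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,task_label,subphase_spec,tr_seconds,s0,s1",
               "a,motor,,2,0.5,oops"), bad2)
  expect_error(load_pool(bad2), "line 2")
  expect_error(load_pool(withr::local_tempfile(fileext = ".csv")), "exist")
})

test_that("zero_mean_detrend removes mean and slope, and is idempotent", {
  ramp <- bold_signal(as.numeric(1:5), 1)
  expect_equal(zero_mean_detrend(ramp)$values, rep(0, 5), tolerance = 1e-12)
  set.seed(11)
  for (rep in 1:5) {
    s <- bold_signal(rnorm(97) + 0.3 * seq_len(97), 2)
    out <- zero_mean_detrend(s)$values
    expect_lt(abs(mean(out)), 1e-9)
    t <- seq_along(out)
    expect_lt(abs(coef(lm(out ~ t))[2]), 1e-9)
    twice <- zero_mean_detrend(zero_mean_detrend(s))$values
    expect_equal(twice, out, tolerance = 1e-9)
  }
  expect_error(zero_mean_detrend(bold_signal(1, 2)), "at least 2")
})

test_that("padding appends zeros, preserves the head, and refuses truncation", {
  s <- bold_signal(rnorm(180), 3, task_label = "resting")
  p <- pad_to_length(s, 600)
  expect_length(p$values, 600)
  expect_identical(p$values[1:180], s$values)
  expect_identical(p$values[181:600], rep(0, 420))
  s600 <- bold_signal(rnorm(600), 3)
  expect_identical(pad_to_length(s600, 600)$values, s600$values)
  expect_error(pad_to_length(bold_signal(rnorm(601), 3), 600), "truncate")
})

test_that("phase splitting partitions the signal exactly", {
  s <- bold_signal(rnorm(600), 3, task_label = "emotion")
  segs <- split_into_phases(s, 3)
  expect_length(segs, 3)
  expect_true(all(vapply(segs, function(x) length(x$values), 1L) == 200L))
  expect_identical(unlist(lapply(segs, `[[`, "values")), s$values)
  expect_identical(split_into_phases(s, 1)[[1]]$values, s$values)
  expect_error(split_into_phases(bold_signal(rnorm(10), 1), 3), "divisible")
})

test_that("design-block extraction returns one labelled segment per non-rest block", {
  design <- data.frame(label = c("rest", "encode", "rest", "recall"),
                       start = c(1, 101, 301, 401), end = c(100, 300, 400, 590))
  s <- bold_signal(rnorm(600), 3, task_label = "memory", design = design)
  segs <- extract_design_segments(s)
  expect_length(segs, 2)
  expect_identical(vapply(segs, `[[`, "", "label"), c("encode", "recall"))
  expect_identical(segs[[1]]$signal$values, s$values[101:300])
  norest <- bold_signal(rnorm(10), 1,
                        design = data.frame(label = "rest", start = 1, end = 10))
  expect_length(extract_design_segments(norest), 0)
  expect_error(extract_design_segments(bold_signal(rnorm(10), 1)), "design")
})

test_that("generator design metadata matches the generated boxcar onsets", {
  specs <- default_class_specs()
  s <- generate_signal(specs$memory, subject_id = "s1")
  blocks <- specs$memory$blocks
  enc <- blocks[blocks$label == "encode", ]
  rec <- blocks[blocks$label == "recall", ]
  expect_identical(s$design$start[s$design$label == "encode"], min(enc$onset))
  expect_identical(s$design$end[s$design$label == "encode"],
                   max(enc$onset + enc$duration - 1L))
  expect_identical(s$design$start[s$design$label == "recall"], min(rec$onset))
  expect_identical(s$design$end[s$design$label == "recall"],
                   max(rec$onset + rec$duration - 1L))
})
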