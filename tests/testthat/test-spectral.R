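test_that("one-sided FFT magnitude follows the unnormalised DFT convention", {
  expect_length(fft_magnitude(rnorm(600)), 301)
  const <- rep(2.5, 600)
  m <- fft_magnitude(const)
  expect_equal(m[1], 600 * 2.5)
  expect_lt(max(m[-1]), 1e-9)
  cosx <- cos(2 * pi * 10 * (0:599) / 600)
  mc <- fft_magnitude(cosx)
  expect_equal(mc[11], 300, tolerance = 1e-9)
  expect_error(fft_magnitude(numeric(0)), "at least 2")
})

test_that("FFT summary matches closed forms for pure tones, silence, and noise", {
  n <- 600
  cosx <- cos(2 * pi * 10 * (0:(n - 1)) / n)
  fs <- fft_summary(cosx, tr_seconds = 2)
  expect_equal(unname(fs["centroid_hz"]), 10 / (n * 2), tolerance = 1e-9)
  expect_equal(unname(fs["peak_hz"]), 10 / (n * 2), tolerance = 1e-9)
  expect_equal(unname(fs["entropy_bits"]), 0, tolerance = 1e-9)
  expect_identical(unname(fft_summary(numeric(600))), c(0, 0, 0, 0))
  set.seed(21)
  ent <- vapply(1:5, function(i)
    unname(fft_summary(rnorm(n))["entropy_bits"]), 1)
  # flat-spectrum limit: entropy near log2(number of non-DC bins)
  expect_true(all(abs(ent - log2(300)) / log2(300) < 0.1))
})

test_that("the DWT coefficient layout follows the ceil-halving chain", {
  d <- dwt_coefficients(rnorm(600), "haar", 8)
  expect_length(d, 603)
  expect_identical(as.integer(attr(d, "lengths")),
                   c(3L, 3L, 5L, 10L, 19L, 38L, 75L, 150L, 300L))
  const <- dwt_coefficients(rep(3, 600), "haar", 8)
  expect_equal(const[1:3], rep(16 * 3, 3), tolerance = 1e-9)  # (sqrt 2)^8 gain
  expect_lt(max(abs(const[-(1:3)])), 1e-9)
  expect_error(dwt_coefficients(rnorm(100), "haar", 8), "length >= 256")
})

test_that("the DWT reconstructs random signals exactly and preserves energy", {
  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(600)
    d <- dwt_coefficients(x, "haar", 8)
    expect_lt(max(abs(dwt_reconstruct(d) - x)), 1e-8)
    # orthonormal transform on the (even-length) record: energy preserved
    x2 <- rnorm(512)
    d2 <- dwt_coefficients(x2, "db2", 5)
    expect_lt(max(abs(dwt_reconstruct(d2) - x2)), 1e-8)
    expect_equal(sum(d2^2), sum(x2^2), tolerance = 1e-10)
    # Parseval for the FFT convention used by the summary features
    expect_equal(sum(x^2), sum(Mod(fft(x))^2) / length(x), tolerance = 1e-6)
  }
})

test_that("the combined frequency block is 607-dimensional under the paper preset", {
  set.seed(41)
  x <- rnorm(600)
  sb <- spectral_block(x, tr_seconds = 3)
  expect_length(sb, 607)
  expect_identical(unname(spectral_block(numeric(600))), rep(0, 607))
  y <- rnorm(600)
  expect_false(isTRUE(all.equal(unname(spectral_block(x)), unname(spectral_block(y)))))
  # the length contract generalises: 4 + sum of level lengths for other presets
  sb200 <- spectral_block(rnorm(200), levels = 6)
  expect_length(sb200, 4 + (100 + 50 + 25 + 13 + 7 + 4 + 4))
})

test_that("the scalogram is non-negative, time-aligned, and tracks a chirp ridge", {
  n <- 512
  t <- seq(0, 1, length.out = n)
  chirp <- sin(2 * pi * (8 + 56 * t) * t)     # frequency rises 8 -> 120 Hz-ish
  sc <- cwt_scalogram(chirp, n_scales = 48, tr_seconds = 1 / n)
  expect_identical(dim(sc$magnitude), c(48L, as.integer(n)))
  expect_true(all(sc$magnitude >= 0))
  mid <- 64:(n - 64)
  ridge <- apply(sc$magnitude[, mid], 2, which.max)
  # rising frequency -> shrinking scale index; demand a strong monotone trend
  expect_lt(cor(mid, ridge, method = "spearman"), -0.9)
  zero <- cwt_scalogram(numeric(64), n_scales = 8)
  expect_identical(max(zero$magnitude), 0)
  expect_error(cwt_scalogram(c(rnorm(63), NA)), "non-finite")
})

test_that("scalogram rendering is deterministic, 224x224x3, in [0, 255]", {
  set.seed(51)
  sc <- cwt_scalogram(rnorm(600), n_scales = 64, tr_seconds = 3)
  img <- render_scalogram_image(sc)
  expect_identical(dim(img), c(224L, 224L, 3L))
  expect_true(all(img >= 0 & img <= 255))
  expect_identical(render_scalogram_image(sc), img)
  flat <- sc
  flat$magnitude[] <- 1
  fimg <- render_scalogram_image(flat)
  for (ch in 1:3) expect_equal(length(unique(as.vector(fimg[, , ch]))), 1L)
})
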