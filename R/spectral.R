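# Hand-crafted frequency features: one-sided FFT magnitude, a 4-scalar FFT
# summary, and a periodized multilevel DWT coefficient vector. Under the
# default preset for length-600 signals (4 summary scalars + 8-level Haar
# DWT, 603 coefficients) the combined block has exactly 607 entries.

#' One-sided FFT magnitude spectrum
#'
#' Unnormalised convention: the DC bin equals the absolute sum of the
#' samples. Output length is `floor(T/2) + 1` (301 for T = 600).
#'
#' @param x Numeric vector of length >= 2 (or a [bold_signal()]).
#' @return Numeric vector of one-sided magnitudes.
#' @export
fft_magnitude <- function(x) {
  x <- signal_values(x)
  n <- length(x)
  if (n < 2L) stopf("fft_magnitude() needs at least 2 samples")
  Mod(fft(x))[seq_len(n %/% 2L + 1L)]
}

signal_values <- function(x) {
  if (inherits(x, "bold_signal")) x$values
  else if (is.numeric(x)) as.numeric(x)
  else stopf("expected a numeric vector or bold_signal")
}

#' Four-scalar FFT summary of a signal
#'
#' Computed on the non-DC one-sided power spectrum (signals are zero-mean
#' after conditioning, so the DC bin is uninformative): total power,
#' spectral centroid (Hz), peak frequency (Hz), and spectral entropy (bits)
#' of the normalised power distribution. An all-zero signal returns
#' `c(0, 0, 0, 0)` by convention.
#'
#' @param x Numeric vector (length >= 2) or [bold_signal()].
#' @param tr_seconds Sampling interval used to express frequencies in Hz;
#'   taken from the signal when a [bold_signal()] is given.
#' @return Named numeric vector
#'   `c(total_power, centroid_hz, peak_hz, entropy_bits)`.
#' @export
fft_summary <- function(x, tr_seconds = 1) {
  if (inherits(x, "bold_signal")) tr_seconds <- x$tr_seconds
  v <- signal_values(x)
  n <- length(v)
  if (n < 2L) stopf("fft_summary() needs at least 2 samples")
  mag <- fft_magnitude(v)[-1L]                 # drop DC
  p <- mag^2
  total <- sum(p)
  if (total <= 0)
    return(c(total_power = 0, centroid_hz = 0, peak_hz = 0, entropy_bits = 0))
  freqs <- seq_along(p) / (n * tr_seconds)     # bin k -> k/(T*TR) Hz
  q <- p / total
  nz <- q > 0
  c(total_power = total,
    centroid_hz = sum(freqs * q),
    peak_hz = freqs[which.max(p)],
    entropy_bits = -sum(q[nz] * log2(q[nz])))
}

# Orthonormal analysis filters. The quadrature mirror highpass is derived
# from the lowpass as g[m] = (-1)^m h[L-1-m] (0-based).
wavelet_filters <- function(wavelet) {
  lo <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.482962913144534, 0.836516303737808,
            0.224143868042013, -0.129409522551260),
    stopf("unknown wavelet '%s' (available: haar, db2)", wavelet))
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)
  list(lo = lo, hi = hi)
}

# One periodized analysis step. Odd-length inputs are extended by one
# sample (wrap-around) before filtering, so coefficient lengths follow the
# ceil(n/2) halving chain 600,300,150,75,38,19,10,5,3.
dwt_step <- function(x, f) {
  odd <- length(x) %% 2L == 1L
  if (odd) x <- c(x, x[1L])
  n <- length(x)
  L <- length(f$lo)
  half <- n %/% 2L
  idx <- outer((seq_len(half) - 1L) * 2L, seq_len(L) - 1L, `+`) %% n + 1L
  xm <- matrix(x[idx], nrow = half)
  list(cA = as.numeric(xm %*% f$lo), cD = as.numeric(xm %*% f$hi), odd = odd)
}

idwt_step <- function(cA, cD, f, odd) {
  half <- length(cA)
  n <- 2L * half
  L <- length(f$lo)
  x <- numeric(n)
  for (m in seq_len(L)) {
    pos <- ((seq_len(half) - 1L) * 2L + (m - 1L)) %% n + 1L
    x[pos] <- x[pos] + f$lo[m] * cA + f$hi[m] * cD
  }
  if (odd) x[-n] else x
}

#' Multilevel periodized DWT coefficient vector
#'
#' Decomposes a signal into `levels` octaves and returns the concatenation
#' `cA_L, cD_L, ..., cD_1` (coarsest first). For T = 600 with the Haar
#' wavelet and 8 levels the vector has 603 entries
#' (3 + 3 + 5 + 10 + 19 + 38 + 75 + 150 + 300).
#'
#' @param x Numeric vector or [bold_signal()].
#' @param wavelet `"haar"` (default) or `"db2"`.
#' @param levels Number of decomposition levels (>= 1, requires
#'   `2^levels <= length(x)`).
#' @return Numeric coefficient vector with attributes recording the layout
#'   so that [dwt_reconstruct()] can invert it exactly.
#' @export
dwt_coefficients <- function(x, wavelet = "haar", levels = 8L) {
  x <- signal_values(x)
  levels <- as.integer(assert_scalar_number(levels, "levels", positive = TRUE))
  if (2^levels > length(x))
    stopf("%d levels need length >= %d (got %d)", levels, 2^levels, length(x))
  f <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  odd_flags <- logical(levels)
  cur <- x
  for (l in seq_len(levels)) {
    s <- dwt_step(cur, f)
    details[[l]] <- s$cD
    odd_flags[l] <- s$odd
    cur <- s$cA
  }
  out <- c(cur, unlist(rev(details)))
  structure(out,
            lengths = c(length(cur), vapply(rev(details), length, 1L)),
            odd = odd_flags, wavelet = wavelet, levels = levels)
}

#' Invert a multilevel DWT coefficient vector
#'
#' @param coefs Output of [dwt_coefficients()] (its layout attributes are
#'   required).
#' @return The reconstructed signal (exact up to floating-point rounding).
#' @export
dwt_reconstruct <- function(coefs) {
  lens <- attr(coefs, "lengths")
  odd <- attr(coefs, "odd")
  if (is.null(lens) || is.null(odd))
    stopf("`coefs` lacks the layout attributes written by dwt_coefficients()")
  f <- wavelet_filters(attr(coefs, "wavelet"))
  levels <- attr(coefs, "levels")
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  cA <- coefs[starts[1L]:ends[1L]]
  for (l in seq_len(levels)) {                 # blocks 2.. are cD_L..cD_1
    cD <- coefs[starts[l + 1L]:ends[l + 1L]]
    cA <- idwt_step(cA, cD, f, odd[levels - l + 1L])
  }
  as.numeric(cA)
}

#' Combined frequency-domain feature block
#'
#' Concatenates the 4-scalar FFT summary with the full multilevel DWT
#' coefficient vector. Under the default preset (length-600 input, Haar,
#' 8 levels) the block has 607 entries.
#'
#' @param x Numeric vector or [bold_signal()] (padded length, default 600).
#' @param tr_seconds Sampling interval for the FFT summary frequencies.
#' @param wavelet,levels Passed to [dwt_coefficients()].
#' @return Numeric feature vector of length `4 + sum(DWT level lengths)`.
#' @export
spectral_block <- function(x, tr_seconds = 1, wavelet = "haar", levels = 8L) {
  if (inherits(x, "bold_signal")) tr_seconds <- x$tr_seconds
  v <- signal_values(x)
  fs <- fft_summary(v, tr_seconds = tr_seconds)
  dc <- dwt_coefficients(v, wavelet = wavelet, levels = levels)
  out <- c(unname(fs), as.numeric(dc))
  names(out) <- c(names(fs), paste0("dwt", seq_along(dc)))
  out
}
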