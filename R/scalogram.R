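# Continuous wavelet transform scalograms and their rendering as fixed-size
# colour images for the convolutional feature branch. The analytic Morlet
# wavelet is evaluated in the frequency domain; scales form a geometric grid
# between the Nyquist period and the record length.

MORLET_OMEGA0 <- 6
# Fourier period of the Morlet at scale s: lambda = 4*pi*s / (w0 + sqrt(2 + w0^2))
morlet_period_factor <- function()
  4 * pi / (MORLET_OMEGA0 + sqrt(2 + MORLET_OMEGA0^2))

#' Continuous wavelet transform scalogram
#'
#' Computes `|CWT|` of a signal with the analytic Morlet wavelet over a
#' geometric scale grid, giving the time-frequency magnitude image used by
#' the convolutional branch.
#'
#' @param x Numeric vector (length >= 8) or [bold_signal()]; values must be
#'   finite.
#' @param n_scales Number of geometric scales (>= 2, default 64).
#' @param tr_seconds Sampling interval; taken from a [bold_signal()] input.
#' @return An object of class `scalogram`: list with `magnitude`
#'   (`n_scales` x `length(x)` non-negative matrix, coarse scales in the
#'   last rows), `scales`, `periods_seconds`, `tr_seconds`.
#' @export
cwt_scalogram <- function(x, n_scales = 64L, tr_seconds = 1) {
  if (inherits(x, "bold_signal")) tr_seconds <- x$tr_seconds
  v <- signal_values(x)
  n <- length(v)
  if (n < 8L) stopf("cwt_scalogram() needs at least 8 samples")
  if (n_scales < 2L) stopf("`n_scales` must be >= 2")
  if (!all(is.finite(v))) stopf("input contains non-finite values")
  dt <- tr_seconds
  pf <- morlet_period_factor()
  # periods from 2*dt (Nyquist) to n*dt/2, geometric
  s_min <- 2 * dt / pf
  s_max <- n * dt / (2 * pf)
  scales <- exp(seq(log(s_min), log(s_max), length.out = n_scales))
  xh <- fft(v)
  omega <- 2 * pi * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / (n * dt)
  mag <- matrix(0, nrow = n_scales, ncol = n)
  for (j in seq_len(n_scales)) {
    s <- scales[j]
    psi <- ifelse(omega > 0,
                  pi^(-0.25) * exp(-(s * omega - MORLET_OMEGA0)^2 / 2), 0)
    w <- fft(xh * sqrt(2 * pi * s / dt) * psi, inverse = TRUE) / n
    mag[j, ] <- Mod(w)
  }
  structure(list(magnitude = mag, scales = scales,
                 periods_seconds = scales * pf, tr_seconds = dt),
            class = "scalogram")
}

#' Render a scalogram as a fixed-size colour image
#'
#' Deterministic rendering: the magnitude is normalised to `[0, 1]` by its
#' maximum, resized to 224 x 224 with bilinear interpolation, and mapped
#' through a fixed perceptually-uniform (viridis) colour map, matching the
#' input size expected by the 50-layer residual network.
#'
#' @param scalogram A [cwt_scalogram()] result.
#' @param size Output side length in pixels (default 224).
#' @return `size` x `size` x 3 numeric array with values in `[0, 255]`.
#' @export
render_scalogram_image <- function(scalogram, size = 224L) {
  stopifnot(inherits(scalogram, "scalogram"))
  mag <- scalogram$magnitude
  if (!length(mag)) stopf("empty scalogram magnitude")
  mx <- max(mag)
  norm <- if (mx > 0) mag / mx else mag
  resized <- EBImage::imageData(EBImage::resize(EBImage::Image(norm),
                                                w = size, h = size))
  resized <- pmin(pmax(resized, 0), 1)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))
  idx <- matrix(pmin(255L, as.integer(floor(resized * 256))) + 1L, nrow = size)
  img <- array(0, dim = c(size, size, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(pal[ch, idx], nrow = size)
  img
}
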