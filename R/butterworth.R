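## Butterworth low-pass design and zero-phase filtering.
##
## No DSP package is assumed: the digital filter is designed from the analog
## Butterworth prototype via the bilinear transform, and zero-phase filtering
## follows the usual forward-backward scheme with odd-extension padding and
## steady-state initial conditions, so that filter delay cannot bias peak
## times.

## expand a monic polynomial from its (complex) roots; returns coefficients
## in decreasing degree, length(roots)+1
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design an order-n digital Butterworth low-pass filter
#'
#' @param order filter order (default 5).
#' @param cutoff_hz -3 dB corner frequency in Hz.
#' @param fs_hz sampling frequency in Hz (2000 for the 0.5-ms grid).
#' @return list with numerator `b` and denominator `a` coefficients
#'   (direct-form, `a[1] = 1`).
#' @export
butter_lowpass <- function(order = 5L, cutoff_hz, fs_hz = 2000) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2)
    stopf("cutoff must lie in (0, fs/2)")
  n <- as.integer(order)
  k <- seq_len(n)
  ## analog prototype poles on the unit circle, left half-plane
  theta <- pi * (2 * k + n - 1) / (2 * n)
  p <- exp(1i * theta)
  warped <- 2 * fs_hz * tan(pi * cutoff_hz / fs_hz)
  p <- warped * p
  gain <- warped^n
  ## bilinear transform
  fs2 <- 2 * fs_hz
  pz <- (fs2 + p) / (fs2 - p)
  gain_z <- Re(gain / prod(fs2 - p))
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, n))) * gain_z
  list(b = b, a = a)
}

## steady-state initial conditions for a unit-amplitude step (scipy-style):
## solve (I - A^T) zi = B with A the companion matrix of `a`
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1] / a[1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(comp), B)
}

## direct-form-II-transposed IIR filter applied down the rows of a matrix
## (each column an independent trace); zi is the per-unit-input initial
## state, scaled by the first row of x
lfilter_mat <- function(b, a, x, zi = NULL) {
  x <- as.matrix(x)
  nb <- length(b)
  m <- nrow(x); nc <- ncol(x)
  y <- matrix(0, m, nc)
  z <- matrix(0, nb - 1, nc)
  if (!is.null(zi)) z <- zi %o% x[1, ]
  for (i in seq_len(m)) {
    xi <- x[i, ]
    yi <- b[1] * xi + z[1, ]
    for (j in seq_len(nb - 2)) {
      z[j, ] <- b[j + 1] * xi + z[j + 1, ] - a[j + 1] * yi
    }
    z[nb - 1, ] <- b[nb] * xi - a[nb] * yi
    y[i, ] <- yi
  }
  y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter twice, once forward and once reversed, after extending
#' the trace at both ends by an odd reflection of length
#' `3 * max(length(a), length(b))`, with steady-state initial conditions at
#' each pass. The result has zero phase shift, so detected peak times are not
#' biased by filter delay.
#'
#' @param b,a filter coefficients from [butter_lowpass()].
#' @param x numeric vector, or a matrix whose columns are traces.
#' @return filtered vector or matrix matching the input shape.
#' @export
filtfilt <- function(b, a, x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  m <- nrow(x)
  pad <- 3L * max(length(a), length(b))
  if (m <= pad) stopf("trace too short for filtfilt (need > %d samples)", pad)
  ## odd extension at both ends
  top <- 2 * matrix(x[1, ], pad, ncol(x), byrow = TRUE) -
    x[pad:1 + 1, , drop = FALSE]
  bot <- 2 * matrix(x[m, ], pad, ncol(x), byrow = TRUE) -
    x[m - (1:pad), , drop = FALSE]
  ext <- rbind(top, x, bot)
  zi <- lfilter_zi(b, a)
  yf <- lfilter_mat(b, a, ext, zi)
  yb <- lfilter_mat(b, a, yf[nrow(yf):1, , drop = FALSE], zi)
  y <- yb[nrow(yb):1, , drop = FALSE][pad + seq_len(m), , drop = FALSE]
  if (vec) drop(y) else y
}
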