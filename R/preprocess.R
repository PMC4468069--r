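#' @include AllClasses.R
NULL

#' Savitzky-Golay smoothing configuration
#'
#' @param order polynomial order N (default 3).
#' @param halfWidth half width M in data points (default 50; frame 2M+1 = 101).
#' @param enabled logical (default TRUE).
#' @return a [SmoothingConfig-class].
#' @export
smoothingConfig <- function(order = 3L, halfWidth = 50L, enabled = TRUE) {
  new("SmoothingConfig", order = as.integer(order),
      halfWidth = as.integer(halfWidth), enabled = enabled)
}

# Least-squares polynomial-fit weights: row vector w such that w %*% y is the
# value at position `at` (1-based within the window) of the order-N polynomial
# fitted to y at abscissae 1..len. Solved via QR on the centred Vandermonde.
polyFitWeights <- function(len, order, at) {
  x <- seq_len(len) - (len + 1) / 2
  X <- outer(x, 0:order, `^`)
  # hat-matrix row `at` only: X[at, ] (X'X)^-1 X'
  coefW <- qr.coef(qr(X), diag(len))   # (order+1) x len coefficient weights
  drop(X[at, , drop = FALSE] %*% coefW)
}

#' Savitzky-Golay convolution weights
#'
#' Mid-point weights of the least-squares polynomial smoother of order N over
#' a frame of 2M+1 points: the smoothed value is the centre value of the
#' order-N polynomial least-squares fitted to the frame. Weights are
#' symmetric and sum to 1.
#'
#' @param config a [SmoothingConfig-class].
#' @return numeric vector of length 2M+1.
#' @examples
#' sgCoefficients(smoothingConfig(order = 0, halfWidth = 1))  # 1/3, 1/3, 1/3
#' @export
sgCoefficients <- function(config) {
  stopifnot(is(config, "SmoothingConfig"))
  validObject(config)
  len <- 2L * config@halfWidth + 1L
  polyFitWeights(len, config@order, config@halfWidth + 1L)
}

# Precompute edge-position weights: list over i = 1..M of the weight vector
# (length M+i) giving the truncated-window polynomial fit evaluated at
# position i of the trace. Used mirrored for the right edge.
sgEdgeWeights <- function(config) {
  M <- config@halfWidth
  N <- config@order
  lapply(seq_len(M), function(i) {
    len <- M + i
    ord <- min(N, len - 1L)  # guard: fit must stay determined in tiny windows
    polyFitWeights(len, ord, i)
  })
}

#' Smooth a single trace with a Savitzky-Golay filter
#'
#' Interior points are the convolution of the trace with
#' [sgCoefficients()]. At the 2M edge positions, where the centred frame
#' would run off the trace, the order-N polynomial is least-squares fitted to
#' the largest available truncated window and evaluated at that position, so
#' polynomials up to order N are reproduced exactly at every point.
#'
#' @param trace numeric vector, length >= 2M+1.
#' @param config a [SmoothingConfig-class].
#' @return numeric vector of the same length.
#' @export
sgSmooth <- function(trace, config = smoothingConfig()) {
  w <- sgCoefficients(config)
  sgSmoothMatrix(matrix(trace, ncol = 1), config, weights = w)[, 1]
}

# Matrix form: smooth every column. Shared by sgSmooth and smoothRecording.
sgSmoothMatrix <- function(mat, config, weights = sgCoefficients(config)) {
  M <- config@halfWidth
  n <- nrow(mat)
  if (n < 2L * M + 1L)
    stop("trace length ", n, " shorter than frame size ", 2L * M + 1L)
  out <- apply(mat, 2, function(v)
    stats::filter(v, weights, method = "convolution", sides = 2))
  out <- matrix(out, nrow = n, dimnames = dimnames(mat))
  ew <- sgEdgeWeights(config)
  for (i in seq_len(M)) {
    wi <- ew[[i]]
    len <- length(wi)
    out[i, ] <- wi %*% mat[seq_len(len), , drop = FALSE]
    out[n - i + 1L, ] <- rev(wi) %*% mat[(n - len + 1L):n, , drop = FALSE]
  }
  if (!all(is.finite(out))) stop("smoothing produced non-finite values")
  out
}

#' Attach Savitzky-Golay smoothed traces to a recording
#'
#' Smoothing is applied once to every electrode; the raw samples are retained
#' alongside (3D rendering displays raw data, detection uses the smoothed
#' traces).
#'
#' @param recording an [MEARecording-class].
#' @param config a [SmoothingConfig-class].
#' @return the recording with the \code{smoothed} traces filled in (a copy of
#'   the raw samples if \code{config@enabled} is FALSE).
#' @export
smoothRecording <- function(recording, config = smoothingConfig()) {
  stopifnot(is(recording, "MEARecording"))
  recording@smoothed <- if (config@enabled)
    sgSmoothMatrix(recording@samples, config)
  else recording@samples
  recording
}

#' Predicted normalized cutoff frequency of the smoother
#'
#' The dimensionless cutoff f_c = w_c / pi of the order-N, half-width-M
#' Savitzky-Golay smoother, predicted as (N + 1) / (3.2 M - 4.6). For the
#' defaults N = 3, M = 50 this evaluates to 4 / 155.4 = 0.025740.
#'
#' @param config a [SmoothingConfig-class].
#' @return normalized cutoff (dimensionless, relative to Nyquist).
#' @export
predictedCutoff <- function(config) {
  stopifnot(is(config, "SmoothingConfig"))
  den <- 3.2 * config@halfWidth - 4.6
  if (den <= 0) stop("cutoff undefined: 3.2 M - 4.6 must be positive")
  (config@order + 1) / den
}

#' Cutoff frequency in Hz
#'
#' Converts [predictedCutoff()] to Hz. Since f_c = w_c / pi is normalized to
#' the Nyquist frequency, the default reference is fs / 2
#' (\code{convention = "nyquist"}); \code{convention = "fs"} multiplies by
#' the sampling rate instead, for compatibility with tools that use that
#' convention.
#'
#' @param config a [SmoothingConfig-class].
#' @param samplingRate sampling rate in Hz.
#' @param convention "nyquist" (default) or "fs".
#' @return cutoff frequency in Hz.
#' @export
cutoffHz <- function(config, samplingRate, convention = c("nyquist", "fs")) {
  convention <- match.arg(convention)
  ref <- if (convention == "nyquist") samplingRate / 2 else samplingRate
  predictedCutoff(config) * ref
}
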