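#' @include AllClasses.R preprocess.R
NULL

#' Analysis window constructor
#'
#' @param start window start in ms.
#' @param size window length in ms; the window is \[start, start + size).
#' @return an [AnalysisWindow-class].
#' @export
analysisWindow <- function(start, size) new("AnalysisWindow", start = start, size = size)

#' Numeric gradient of a sampled series
#'
#' Central differences (v\[i+1\] - v\[i-1\]) / (2 dt) at interior points and
#' one-sided differences at the two ends, the convention of numerical
#' gradient routines: exact for linear series at every point and for
#' quadratics at interior points.
#'
#' @param values numeric vector (>= 2 values).
#' @param dt sample spacing (ms).
#' @return numeric vector of the same length (units of values per ms).
#' @export
numericGradient <- function(values, dt) {
  n <- length(values)
  if (n < 2L) stop("numericGradient needs at least 2 values")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  g <- numeric(n)
  g[1] <- (values[2] - values[1]) / dt
  g[n] <- (values[n] - values[n - 1]) / dt
  if (n > 2L)
    g[2:(n - 1)] <- (values[3:n] - values[1:(n - 2)]) / (2 * dt)
  g
}

# Indices of samples whose time falls in [start, start+size).
windowIndices <- function(times, window) {
  which(times >= window@start - 1e-9 & times < window@start + window@size - 1e-9)
}

#' Detect the activation time on a single trace
#'
#' Activation is the time of the steepest negative voltage slope
#' (dV/dt minimum): the gradient of the (smoothed) trace is evaluated over
#' the whole trace and its minimum located within the analysis window. Ties
#' are broken toward the earliest sample; no sub-sample interpolation is
#' performed, so resolution is one sample. If the minimum slope is
#' non-negative (no downstroke in the window) the result is still returned
#' and flagged.
#'
#' @param trace numeric voltage vector (uV), assumed already smoothed if
#'   smoothing is desired.
#' @param times numeric vector of sample times (ms), same length.
#' @param window an [AnalysisWindow-class].
#' @return list with \code{time} (ms), \code{slope} (uV/ms, the minimum
#'   gradient), and \code{nonNegative} (TRUE when slope >= 0).
#' @export
detectActivationTime <- function(trace, times, window) {
  if (length(trace) != length(times)) stop("trace and times lengths differ")
  dt <- times[2] - times[1]
  idx <- windowIndices(times, window)
  if (length(idx) == 0L) stop("analysis window contains no samples")
  g <- numericGradient(trace, dt)
  gw <- g[idx]
  k <- which.min(gw)          # which.min returns the first (earliest) minimum
  list(time = times[idx[k]], slope = gw[k], nonNegative = gw[k] >= 0)
}

#' Detect activation times on every electrode
#'
#' Applies [detectActivationTime()] with the same window to every
#' non-silenced electrode of the recording, using the smoothed traces (the
#' raw traces if \code{useRaw = TRUE}). If the recording carries no smoothed
#' traces yet they are computed with \code{config}.
#'
#' @param recording an [MEARecording-class].
#' @param window an [AnalysisWindow-class].
#' @param mask a [SilenceMask-class] (default: nothing silenced).
#' @param config [SmoothingConfig-class] used if smoothing must be computed.
#' @param useRaw detect on raw traces instead of smoothed ones.
#' @return an [ActivationMap-class].
#' @export
detectActivationMap <- function(recording, window, mask = new("SilenceMask"),
                                config = smoothingConfig(), useRaw = FALSE) {
  stopifnot(is(recording, "MEARecording"), is(window, "AnalysisWindow"))
  lab <- recording@layout@labels
  bad <- setdiff(mask@silenced, lab)
  if (length(bad)) stop("silenced label(s) not in layout: ", paste(bad, collapse = ", "))
  active <- setdiff(lab, mask@silenced)
  if (length(active) == 0L) stop("all electrodes are silenced")
  mat <- if (useRaw) {
    recording@samples
  } else {
    if (nrow(recording@smoothed) == 0L)
      recording <- smoothRecording(recording, config)
    recording@smoothed
  }
  tvec <- sampleTimes(recording)
  times <- stats::setNames(rep(NA_real_, length(lab)), lab)
  slopes <- stats::setNames(rep(NA_real_, length(lab)), lab)
  for (el in active) {
    d <- detectActivationTime(mat[, el], tvec, window)
    times[el] <- d$time
    slopes[el] <- d$slope
  }
  new("ActivationMap", times = times, minGradient = slopes,
      window = window, mask = mask, layout = recording@layout)
}

#' Silence / unsilence electrodes
#'
#' Add or remove electrode labels from a silence mask; both operations are
#' idempotent. Labels are validated against the layout.
#'
#' @param mask a [SilenceMask-class].
#' @param labels character vector of electrode labels.
#' @param layout the [ElectrodeLayout-class] the labels must belong to.
#' @return the updated [SilenceMask-class].
#' @export
silenceElectrodes <- function(mask, labels, layout = standardLayout()) {
  labels <- as.character(labels)
  bad <- setdiff(labels, layout@labels)
  if (length(bad)) stop("unknown electrode label(s): ", paste(bad, collapse = ", "))
  new("SilenceMask", silenced = sort(union(mask@silenced, labels)))
}

#' @rdname silenceElectrodes
#' @export
unsilenceElectrodes <- function(mask, labels, layout = standardLayout()) {
  labels <- as.character(labels)
  bad <- setdiff(labels, layout@labels)
  if (length(bad)) stop("unknown electrode label(s): ", paste(bad, collapse = ", "))
  new("SilenceMask", silenced = sort(setdiff(mask@silenced, labels)))
}

# Robust SD with a documented fallback: median absolute deviation scaled by
# 1.4826 for consistency at the normal; traces dominated by an exactly flat
# baseline have MAD 0, in which case the plain SD is used so that a relative
# threshold/noise scale remains meaningful.
robustSD <- function(x) {
  s <- stats::mad(x)
  full <- stats::sd(x)
  if (!is.finite(s) || !is.finite(full)) return(0)
  # a MAD negligible against the overall spread means the trace is mostly a
  # flat baseline (e.g. one transient in a long quiet recording); the plain
  # SD is then the meaningful scale
  if (s < 1e-6 * full) s <- full
  s
}

#' Detect beats on a single electrode trace
#'
#' Events are the times where the gradient of the Savitzky-Golay smoothed
#' trace falls below -k robust SDs of the gradient series (robust SD =
#' 1.4826 x median absolute deviation, falling back to the plain SD for
#' flat-baseline traces); within each refractory period only the steepest
#' point is kept. This reuses the steepest-downstroke feature of activation
#' detection as a relative-threshold event detector, so events are invariant
#' to trace rescaling.
#'
#' @param trace numeric voltage vector (uV).
#' @param samplingRate sampling rate in Hz.
#' @param thresholdK threshold in robust SDs of the gradient (default 5).
#' @param refractoryMs minimum separation between events in ms (default 100).
#' @param config [SmoothingConfig-class] for the pre-detection smoothing.
#' @return sorted numeric vector of event times (ms), pairwise gaps >=
#'   \code{refractoryMs}.
#' @export
detectBeats <- function(trace, samplingRate, thresholdK = 5, refractoryMs = 100,
                        config = smoothingConfig()) {
  if (!is.finite(refractoryMs) || refractoryMs <= 0)
    stop("refractoryMs must be positive")
  sm <- if (config@enabled && length(trace) >= 2 * config@halfWidth + 1)
    sgSmooth(trace, config) else trace
  dtMs <- 1000 / samplingRate
  g <- numericGradient(sm, dtMs)
  thr <- -thresholdK * robustSD(g)
  cand <- which(g < thr & g < 0)
  if (config@enabled && length(trace) >= 2 * config@halfWidth + 1) {
    # truncated-window smoothing amplifies noise near the trace ends; keep
    # candidates out of the edge-transient region
    M <- config@halfWidth
    cand <- cand[cand > M & cand <= length(trace) - M]
  }
  if (length(cand) == 0L) return(numeric(0))
  tvec <- (seq_along(trace) - 1) * dtMs
  # greedily keep the steepest candidate, exclude its refractory neighbourhood
  events <- numeric(0)
  ord <- cand[order(g[cand])]
  taken <- rep(FALSE, length(trace))
  for (i in ord) {
    if (taken[i]) next
    events <- c(events, tvec[i])
    lo <- max(1L, i - as.integer(ceiling(refractoryMs / dtMs)))
    hi <- min(length(trace), i + as.integer(ceiling(refractoryMs / dtMs)))
    taken[lo:hi] <- TRUE
  }
  sort(events)
}

#' Beats per minute from event times
#'
#' @param eventTimes numeric vector of event times (ms).
#' @param durationMs recording duration in ms (> 0).
#' @return beats per minute; 0 when no events.
#' @examples
#' beatRate(seq(0, 9500, by = 500), 10000)  # 20 events in 10 s -> 120 bpm
#' @export
beatRate <- function(eventTimes, durationMs) {
  if (!is.finite(durationMs) || durationMs <= 0)
    stop("durationMs must be positive")
  length(eventTimes) * 60000 / durationMs
}
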