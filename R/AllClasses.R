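#' @import methods
NULL

#' ElectrodeLayout: planar electrode geometry
#'
#' Labels and planar coordinates of an MEA electrode grid. The standard
#' layout ([standardLayout()]) is the 8x8-minus-corners 60-electrode grid at
#' 200 um pitch used by TiN glass arrays. Labels follow the column-row
#' convention: label \code{"CR"} sits in grid column \code{C} and row
#' \code{R}. Coordinates are in micrometres, x increasing rightward with
#' column number, y increasing upward with row number (row 1 at the bottom).
#'
#' @slot labels character vector of two-digit electrode labels.
#' @slot positions numeric matrix (n x 2, columns \code{x}, \code{y}, um),
#'   row names equal to \code{labels}.
#' @slot pitch nearest-neighbour electrode spacing in um.
#' @export
setClass("ElectrodeLayout",
  representation(labels = "character", positions = "matrix", pitch = "numeric"),
  validity = function(object) {
    msg <- character(0)
    n <- length(object@labels)
    if (anyDuplicated(object@labels)) msg <- c(msg, "duplicate electrode labels")
    if (!is.numeric(object@positions) || ncol(object@positions) != 2L)
      msg <- c(msg, "positions must be an n x 2 numeric matrix")
    else {
      if (nrow(object@positions) != n)
        msg <- c(msg, "positions row count must equal number of labels")
      if (!identical(rownames(object@positions), object@labels))
        msg <- c(msg, "positions row names must equal labels")
      if (anyDuplicated(object@positions, MARGIN = 1))
        msg <- c(msg, "electrode positions must be distinct")
    }
    if (length(object@pitch) != 1L || !is.finite(object@pitch) || object@pitch <= 0)
      msg <- c(msg, "pitch must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' MEARecording: a multi-electrode voltage recording
#'
#' Voltage samples (uV) on a regular time grid for every electrode of a
#' layout. Raw samples are always retained; a smoothed copy (Savitzky-Golay,
#' see [smoothRecording()]) may be stored alongside, and detection operates
#' on the smoothed traces by default while 3D rendering shows raw data.
#'
#' @slot samples numeric matrix, rows = time points, columns = electrodes in
#'   layout label order (uV).
#' @slot smoothed numeric matrix of the same shape, or a 0 x 0 matrix when no
#'   smoothing has been applied yet.
#' @slot samplingRate sampling rate in Hz.
#' @slot startTime time of the first sample in ms.
#' @slot layout an [ElectrodeLayout-class].
#' @export
setClass("MEARecording",
  representation(samples = "matrix", smoothed = "matrix",
                 samplingRate = "numeric", startTime = "numeric",
                 layout = "ElectrodeLayout"),
  prototype(smoothed = matrix(numeric(0), 0, 0), startTime = 0),
  validity = function(object) {
    msg <- character(0)
    if (ncol(object@samples) != length(object@layout@labels))
      msg <- c(msg, "sample column count must equal layout label count")
    if (!identical(colnames(object@samples), object@layout@labels))
      msg <- c(msg, "sample column names must equal layout labels")
    if (nrow(object@samples) < 2L)
      msg <- c(msg, "recording needs at least 2 time points")
    if (!all(is.finite(object@samples)))
      msg <- c(msg, "all samples must be finite")
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
      msg <- c(msg, "samplingRate must be a single positive number")
    if (nrow(object@smoothed) > 0L &&
        !identical(dim(object@smoothed), dim(object@samples)))
      msg <- c(msg, "smoothed matrix must match sample dimensions")
    if (length(msg)) msg else TRUE
  })

#' SmoothingConfig: Savitzky-Golay filter parameters
#'
#' Polynomial order N and half width M (frame size 2M + 1 data points) of the
#' least-squares mid-point smoother applied to every electrode trace.
#' Defaults are order 3 with half width 50 (101-point frame), the standard
#' setting for 20 kHz cardiac field-potential recordings.
#'
#' @slot order polynomial order N (integer >= 0).
#' @slot halfWidth half width M in data points (integer >= 1); frame = 2M + 1.
#' @slot enabled logical; if FALSE the pipeline skips smoothing.
#' @export
setClass("SmoothingConfig",
  representation(order = "integer", halfWidth = "integer", enabled = "logical"),
  prototype(order = 3L, halfWidth = 50L, enabled = TRUE),
  validity = function(object) {
    msg <- character(0)
    if (object@order < 0L) msg <- c(msg, "order must be >= 0")
    if (object@halfWidth < 1L) msg <- c(msg, "halfWidth must be >= 1")
    if (2L * object@halfWidth + 1L <= object@order)
      msg <- c(msg, "frame size 2M+1 must exceed polynomial order N")
    if (length(msg)) msg else TRUE
  })

#' AnalysisWindow: time window for activation analysis
#'
#' Mirrors the time / window-size controls of interactive MEA viewers: the
#' same window is applied to every electrode so one wavefront is analysed.
#'
#' @slot start window start in ms.
#' @slot size window length in ms (> 0); the window is \[start, start+size).
#' @export
setClass("AnalysisWindow",
  representation(start = "numeric", size = "numeric"),
  validity = function(object) {
    if (length(object@size) != 1L || !is.finite(object@size) || object@size <= 0)
      "window size must be a single positive number (ms)"
    else if (length(object@start) != 1L || !is.finite(object@start))
      "window start must be a single finite number (ms)"
    else TRUE
  })

#' SilenceMask: electrodes excluded from analysis
#'
#' Set of electrode labels removed from detection and fitting (artefactual or
#' dead channels). Operations validate labels against the layout in use.
#'
#' @slot silenced character vector of silenced electrode labels.
#' @export
setClass("SilenceMask",
  representation(silenced = "character"),
  prototype(silenced = character(0)),
  validity = function(object) {
    if (anyDuplicated(object@silenced)) "silenced labels must be unique" else TRUE
  })

#' ActivationMap: per-electrode activation times
#'
#' Activation time (time of steepest negative voltage slope within the
#' analysis window) and the slope at that time for every non-silenced
#' electrode. Silenced electrodes carry NA.
#'
#' @slot times named numeric vector of activation times in ms (NA = silenced).
#' @slot minGradient named numeric vector, steepest slope in uV/ms (NA = silenced).
#' @slot window the [AnalysisWindow-class] used.
#' @slot mask the [SilenceMask-class] applied.
#' @slot layout the [ElectrodeLayout-class] of the recording.
#' @export
setClass("ActivationMap",
  representation(times = "numeric", minGradient = "numeric",
                 window = "AnalysisWindow", mask = "SilenceMask",
                 layout = "ElectrodeLayout"),
  validity = function(object) {
    msg <- character(0)
    lab <- object@layout@labels
    if (!identical(names(object@times), lab))
      msg <- c(msg, "times must be named by layout labels")
    if (!identical(names(object@minGradient), lab))
      msg <- c(msg, "minGradient must be named by layout labels")
    sil <- object@mask@silenced
    if (!all(sil %in% lab)) msg <- c(msg, "silenced labels must exist in layout")
    if (any(!is.na(object@times[sil])))
      msg <- c(msg, "silenced electrodes must have NA times")
    pres <- object@times[!is.na(object@times)]
    w0 <- object@window@start; w1 <- w0 + object@window@size
    if (length(pres) && (any(pres < w0 - 1e-9) || any(pres >= w1 + 1e-9)))
      msg <- c(msg, "every present activation time must lie inside the window")
    if (length(msg)) msg else TRUE
  })

#' SurfaceFit: least-squares quadratic activation surface
#'
#' Coefficients of T(x, y) = a x^2 + b y^2 + c x y + d x + e y + f fitted by
#' ordinary least squares to observed (x, y, t) electrode activation data.
#' x, y in um, T in ms. Internally the design is centred and scaled to unit
#' RMS for conditioning; coefficients are stored back-transformed to um/ms
#' units. Rank-deficient designs are resolved by the minimum-norm solution
#' (with a warning at fit time).
#'
#' @slot coefficients named numeric vector (a, b, c, d, e, f).
#' @slot residuals named numeric vector, observed - predicted (ms), one per
#'   fitted electrode.
#' @slot fitted named numeric vector of predicted times (ms).
#' @slot rss residual sum of squares (ms^2).
#' @slot nPoints number of electrodes used in the fit.
#' @slot transform list with the centring/scaling used internally
#'   (\code{cx}, \code{cy}, \code{sx}, \code{sy}).
#' @slot rank numeric rank of the scaled design matrix.
#' @export
setClass("SurfaceFit",
  representation(coefficients = "numeric", residuals = "numeric",
                 fitted = "numeric", rss = "numeric", nPoints = "integer",
                 transform = "list", rank = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!identical(names(object@coefficients), c("a", "b", "c", "d", "e", "f")))
      msg <- c(msg, "coefficients must be named a..f")
    if (object@nPoints < 6L) msg <- c(msg, "fit requires at least 6 points")
    if (length(object@residuals) != object@nPoints)
      msg <- c(msg, "one residual per fitted electrode required")
    if (length(msg)) msg else TRUE
  })

#' VelocityField: per-electrode conduction-velocity vectors
#'
#' Velocity vectors V = (Tx, Ty) / (Tx^2 + Ty^2) derived from the spatial
#' gradient of a fitted activation surface, evaluated at each non-silenced
#' electrode position. With Tx, Ty in ms/um the vector comes out in um/ms,
#' numerically equal to mm/s. Electrodes whose gradient magnitude falls below
#' the degeneracy tolerance are flagged undefined and excluded from the mean.
#'
#' @slot vectors n x 2 matrix (vx, vy) in mm/s, row names = labels; NA rows
#'   for undefined/silenced electrodes.
#' @slot speeds named numeric vector |V| in mm/s.
#' @slot directions named numeric vector, direction in degrees (atan2(vy, vx)).
#' @slot gradients n x 2 matrix (Tx, Ty) in ms/um.
#' @slot meanSpeed arithmetic mean of defined speeds (mm/s).
#' @slot undefined character vector of labels with degenerate gradient.
#' @slot layout the [ElectrodeLayout-class] used.
#' @export
setClass("VelocityField",
  representation(vectors = "matrix", speeds = "numeric", directions = "numeric",
                 gradients = "matrix", meanSpeed = "numeric",
                 undefined = "character", layout = "ElectrodeLayout"),
  validity = function(object) {
    msg <- character(0)
    lab <- object@layout@labels
    if (!identical(rownames(object@vectors), lab))
      msg <- c(msg, "vector rows must be named by layout labels")
    if (!identical(names(object@speeds), lab))
      msg <- c(msg, "speeds must be named by layout labels")
    if (!all(object@undefined %in% lab))
      msg <- c(msg, "undefined labels must exist in layout")
    if (length(msg)) msg else TRUE
  })

#' FPTemplate: idealized biphasic field-potential waveform
#'
#' The simulator's waveform g(tau) = -A (tau/w) exp((1 - (tau/w)^2) / 2):
#' one positive lobe followed by one dominant downstroke, with peak
#' amplitude A (uV, at tau = -w / +w) and a unique steepest-descent point at
#' tau = 0 by construction, so simulated activation times have an analytic
#' truth.
#'
#' @slot amplitude peak absolute amplitude A in uV.
#' @slot width lobe half-width w in ms.
#' @export
setClass("FPTemplate",
  representation(amplitude = "numeric", width = "numeric"),
  prototype(amplitude = 500, width = 1),
  validity = function(object) {
    if (object@amplitude <= 0 || !is.finite(object@amplitude))
      "amplitude must be positive"
    else if (object@width <= 0 || !is.finite(object@width))
      "width must be positive"
    else TRUE
  })

#' WaveSpec: ground-truth wavefront specification for the simulator
#'
#' Defines the propagating wavefront a synthetic recording carries: planar
#' (constant speed and direction), focal (isotropic spread from an origin
#' point), or quadratic (activation times drawn directly from a quadratic
#' surface T(x, y) so the fitting model is exactly correct). Constructed via
#' [planarWave()], [focalWave()] or [quadraticWave()].
#'
#' @slot kind one of "planar", "focal", "quadratic".
#' @slot speed wavefront speed in mm/s (planar/focal).
#' @slot direction propagation direction in degrees (planar).
#' @slot origin numeric (x, y) in um (focal).
#' @slot coefficients named numeric a..f (quadratic).
#' @slot t0 activation time offset in ms.
#' @slot template the [FPTemplate-class] waveform.
#' @slot noiseLevel additive white-noise level in robust-SD multiples.
#' @slot seed integer RNG seed for the noise draw.
#' @export
setClass("WaveSpec",
  representation(kind = "character", speed = "numeric", direction = "numeric",
                 origin = "numeric", coefficients = "numeric", t0 = "numeric",
                 template = "FPTemplate", noiseLevel = "numeric",
                 seed = "integer"),
  prototype(speed = NA_real_, direction = NA_real_,
            origin = c(NA_real_, NA_real_),
            coefficients = c(a = NA_real_, b = NA_real_, c = NA_real_,
                             d = NA_real_, e = NA_real_, f = NA_real_),
            t0 = 0, noiseLevel = 0, seed = 1L),
  validity = function(object) {
    msg <- character(0)
    if (!object@kind %in% c("planar", "focal", "quadratic"))
      msg <- c(msg, "kind must be planar, focal or quadratic")
    if (object@kind %in% c("planar", "focal") &&
        (!is.finite(object@speed) || object@speed <= 0))
      msg <- c(msg, "speed must be positive for planar/focal waves")
    if (object@kind == "planar" && !is.finite(object@direction))
      msg <- c(msg, "planar wave needs a direction")
    if (object@kind == "focal" && !all(is.finite(object@origin)))
      msg <- c(msg, "focal wave needs a finite origin")
    if (object@kind == "quadratic" && !all(is.finite(object@coefficients)))
      msg <- c(msg, "quadratic wave needs finite coefficients a..f")
    if (object@noiseLevel < 0) msg <- c(msg, "noiseLevel must be >= 0")
    if (length(msg)) msg else TRUE
  })
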