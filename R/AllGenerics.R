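#' @include AllClasses.R
NULL

#' Accessors for MEAflow objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a MEAflow object.
#' @param ... unused.
#' @return the requested component; see the individual class pages for units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("electrodeLabels", function(x, ...) standardGeneric("electrodeLabels"))
#' @rdname accessors
#' @export
setGeneric("electrodePositions", function(x, ...) standardGeneric("electrodePositions"))
#' @rdname accessors
#' @export
setGeneric("layoutPitch", function(x, ...) standardGeneric("layoutPitch"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x, ...) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x, ...) standardGeneric("sampleTimes"))
#' @rdname accessors
#' @export
setGeneric("rawSamples", function(x, ...) standardGeneric("rawSamples"))
#' @rdname accessors
#' @export
setGeneric("smoothedSamples", function(x, ...) standardGeneric("smoothedSamples"))
#' @rdname accessors
#' @export
setGeneric("recordingLayout", function(x, ...) standardGeneric("recordingLayout"))
#' @rdname accessors
#' @export
setGeneric("activationTimes", function(x, ...) standardGeneric("activationTimes"))
#' @rdname accessors
#' @export
setGeneric("minGradients", function(x, ...) standardGeneric("minGradients"))
#' @rdname accessors
#' @export
setGeneric("silencedLabels", function(x, ...) standardGeneric("silencedLabels"))
#' @rdname accessors
#' @export
setGeneric("velocityVectorMatrix", function(x, ...) standardGeneric("velocityVectorMatrix"))
#' @rdname accessors
#' @export
setGeneric("speeds", function(x, ...) standardGeneric("speeds"))
#' @rdname accessors
#' @export
setGeneric("meanSpeed", function(x, ...) standardGeneric("meanSpeed"))
#' @rdname accessors
#' @export
setGeneric("undefinedElectrodes", function(x, ...) standardGeneric("undefinedElectrodes"))

setMethod("electrodeLabels", "ElectrodeLayout", function(x, ...) x@labels)
setMethod("electrodePositions", "ElectrodeLayout", function(x, ...) x@positions)
setMethod("layoutPitch", "ElectrodeLayout", function(x, ...) x@pitch)
setMethod("electrodeLabels", "MEARecording", function(x, ...) x@layout@labels)
setMethod("samplingRate", "MEARecording", function(x, ...) x@samplingRate)
setMethod("sampleTimes", "MEARecording", function(x, ...)
  x@startTime + (seq_len(nrow(x@samples)) - 1) * 1000 / x@samplingRate)
setMethod("rawSamples", "MEARecording", function(x, ...) x@samples)
setMethod("smoothedSamples", "MEARecording", function(x, ...) {
  if (nrow(x@smoothed) == 0L)
    stop("recording has no smoothed traces; call smoothRecording() first")
  x@smoothed
})
setMethod("recordingLayout", "MEARecording", function(x, ...) x@layout)
setMethod("activationTimes", "ActivationMap", function(x, ...) x@times)
setMethod("minGradients", "ActivationMap", function(x, ...) x@minGradient)
setMethod("silencedLabels", "SilenceMask", function(x, ...) x@silenced)
setMethod("silencedLabels", "ActivationMap", function(x, ...) x@mask@silenced)
setMethod("velocityVectorMatrix", "VelocityField", function(x, ...) x@vectors)
setMethod("speeds", "VelocityField", function(x, ...) x@speeds)
setMethod("meanSpeed", "VelocityField", function(x, ...) x@meanSpeed)
setMethod("undefinedElectrodes", "VelocityField", function(x, ...) x@undefined)

#' @describeIn accessors coefficients a..f of a fitted activation surface.
#' @export
setMethod("coef", "SurfaceFit", function(object, ...) object@coefficients)

#' @describeIn accessors residuals (ms) of a fitted activation surface.
#' @export
setMethod("residuals", "SurfaceFit", function(object, ...) object@residuals)

#' @describeIn accessors fitted activation times (ms) of a surface fit.
#' @export
setMethod("fitted", "SurfaceFit", function(object, ...) object@fitted)

setMethod("show", "ElectrodeLayout", function(object) {
  cat(sprintf("ElectrodeLayout: %d electrodes, pitch %g um\n",
              length(object@labels), object@pitch))
})

setMethod("show", "MEARecording", function(object) {
  dur <- (nrow(object@samples) - 1) * 1000 / object@samplingRate
  cat(sprintf("MEARecording: %d electrodes x %d samples (%.3f ms at %g Hz)%s\n",
              ncol(object@samples), nrow(object@samples), dur,
              object@samplingRate,
              if (nrow(object@smoothed)) ", smoothed traces attached" else ""))
})

setMethod("show", "ActivationMap", function(object) {
  n <- sum(!is.na(object@times))
  cat(sprintf("ActivationMap: %d/%d electrodes, window [%g, %g) ms, %d silenced\n",
              n, length(object@times), object@window@start,
              object@window@start + object@window@size,
              length(object@mask@silenced)))
  if (n) cat(sprintf("  activation times %.4f .. %.4f ms\n",
                     min(object@times, na.rm = TRUE),
                     max(object@times, na.rm = TRUE)))
})

setMethod("show", "SurfaceFit", function(object) {
  cat(sprintf("SurfaceFit: T(x,y) over %d electrodes, RSS %.6g ms^2, rank %d\n",
              object@nPoints, object@rss, object@rank))
  print(signif(object@coefficients, 6))
})

setMethod("show", "VelocityField", function(object) {
  nd <- sum(is.finite(object@speeds))
  cat(sprintf("VelocityField: %d defined electrodes, mean CV %.4f mm/s, %d undefined\n",
              nd, object@meanSpeed, length(object@undefined)))
})

setMethod("show", "WaveSpec", function(object) {
  descr <- switch(object@kind,
    planar = sprintf("planar, %g mm/s at %g deg", object@speed, object@direction),
    focal = sprintf("focal from (%g, %g) um at %g mm/s",
                    object@origin[1], object@origin[2], object@speed),
    quadratic = "quadratic activation surface")
  cat(sprintf("WaveSpec: %s, t0 = %g ms, noise level %g\n",
              descr, object@t0, object@noiseLevel))
})
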