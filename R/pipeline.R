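#' @include AllClasses.R io.R activation.R velocity.R viz.R serialize.R
NULL

stageLog <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' The scripted equivalent of the interactive workflow: load (or accept) a
#' recording, smooth every electrode, detect activation times within the
#' analysis window, fit the quadratic activation surface on the non-silenced
#' electrodes, derive velocity vectors, and write maps, fields and figures.
#' Silencing is configuration-driven: run once, inspect the heat map, add
#' labels to \code{silence}, rerun.
#'
#' @param input path to an ASCII recording, or an [MEARecording-class].
#' @param window an [AnalysisWindow-class], or NULL to analyse the full
#'   recording extent.
#' @param outDir output directory (created if needed); NULL writes no files.
#' @param silence character vector of electrode labels to silence.
#' @param smoothing a [SmoothingConfig-class].
#' @param beats if TRUE, also report a per-electrode beat rate over the full
#'   recording.
#' @param plots if TRUE (and \code{outDir} is set) write heat map, isoline
#'   map, vector-field and trace-grid figures.
#' @param quiet suppress per-stage log messages.
#' @return list: \code{map} ([ActivationMap-class]), \code{fit}
#'   ([SurfaceFit-class]), \code{field} ([VelocityField-class]), and
#'   \code{summary} (list: meanCV_mm_s, nElectrodesUsed, residualSD_ms,
#'   direction_deg of the mean vector, beatRate_bpm when requested, plus
#'   output file paths).
#' @export
runPipeline <- function(input, window = NULL, outDir = NULL,
                        silence = character(0),
                        smoothing = smoothingConfig(), beats = FALSE,
                        plots = TRUE, quiet = FALSE) {
  rec <- if (is(input, "MEARecording")) input
         else readAsciiRecording(input)
  stageLog(quiet, "load", "%d electrodes x %d samples at %g Hz",
           ncol(rec@samples), nrow(rec@samples), rec@samplingRate)
  rec <- smoothRecording(rec, smoothing)
  stageLog(quiet, "preprocess", "Savitzky-Golay order %d, half width %d%s",
           smoothing@order, smoothing@halfWidth,
           if (smoothing@enabled) "" else " (disabled)")
  if (is.null(window)) {
    tv <- sampleTimes(rec)
    window <- analysisWindow(tv[1], tv[length(tv)] - tv[1] + 1e-9)
  }
  mask <- if (length(silence))
    silenceElectrodes(new("SilenceMask"), silence, rec@layout)
  else new("SilenceMask")
  map <- detectActivationMap(rec, window, mask, smoothing)
  nUsed <- sum(!is.na(map@times))
  stageLog(quiet, "detect", "window [%g, %g) ms, %d electrodes, %d silenced",
           window@start, window@start + window@size, nUsed, length(silence))
  fit <- fitActivationSurface(map)
  diagn <- residualDiagnostics(fit)
  stageLog(quiet, "fit", "n = %d, RSS %.6g ms^2, residual SD %.4g ms",
           fit@nPoints, fit@rss, diagn$sd)
  field <- velocityVectors(fit, rec@layout, mask)
  mv <- colMeans(field@vectors[is.finite(field@vectors[, 1]), , drop = FALSE])
  summary <- list(meanCV_mm_s = field@meanSpeed,
                  nElectrodesUsed = nUsed,
                  residualSD_ms = diagn$sd,
                  direction_deg = atan2(mv[2], mv[1]) * 180 / pi,
                  nUndefined = length(field@undefined))
  stageLog(quiet, "velocity", "mean CV %.4f mm/s, direction %.2f deg",
           summary$meanCV_mm_s, summary$direction_deg)
  if (beats) {
    dur <- (nrow(rec@samples) - 1) * 1000 / rec@samplingRate
    active <- setdiff(rec@layout@labels, silence)
    bpm <- vapply(active, function(l)
      beatRate(detectBeats(rec@samples[, l], rec@samplingRate,
                           config = smoothing), dur), numeric(1))
    summary$beatRate_bpm <- bpm
    stageLog(quiet, "beats", "median %.1f bpm over %d electrodes",
             stats::median(bpm), length(bpm))
  }
  files <- list()
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files$map <- writeActivationMapJSON(map, file.path(outDir, "activation_map.json"))
    files$field <- writeVelocityFieldJSON(field, fit,
                                          file.path(outDir, "velocity_field.json"))
    if (plots) {
      files$heatmap <- activationHeatmap(map, file.path(outDir, "heatmap.png"))$path
      files$isolines <- isolineMap(map, file.path(outDir, "isolines.png"))$path
      files$vectors <- vectorFieldPlot(field, file.path(outDir, "vector_field.png"))$path
      files$traces <- traceGrid(rec, file.path(outDir, "traces.png"),
                                window = window)$path
    }
    sm <- summary
    sm$beatRate_bpm <- if (!is.null(sm$beatRate_bpm)) as.list(sm$beatRate_bpm)
    jsonlite::write_json(sm, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files$summary <- file.path(outDir, "summary.json")
    stageLog(quiet, "output", "wrote %d files to %s", length(files), outDir)
  }
  summary$files <- files
  list(map = map, fit = fit, field = field, summary = summary)
}
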