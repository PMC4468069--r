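#' @include AllClasses.R velocity.R
NULL

#' Serialize an activation map to JSON
#'
#' Labels map to \code{{time_ms, slope}} objects (silenced electrodes are
#' listed in the mask, not in the label map); window and mask are included so
#' a map file is self-contained.
#'
#' @param map an [ActivationMap-class].
#' @param path output JSON file.
#' @return invisibly, \code{path}.
#' @export
writeActivationMapJSON <- function(map, path) {
  pres <- names(map@times)[!is.na(map@times)]
  obj <- list(
    window = list(start = map@window@start, size = map@window@size),
    mask = as.list(map@mask@silenced),
    electrodes = stats::setNames(lapply(pres, function(l)
      list(time_ms = map@times[[l]], slope = map@minGradient[[l]])), pres))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an activation map from JSON
#'
#' @param path JSON file written by [writeActivationMapJSON()].
#' @param layout the [ElectrodeLayout-class] to attach.
#' @return an [ActivationMap-class].
#' @export
readActivationMapJSON <- function(path, layout = standardLayout()) {
  obj <- jsonlite::read_json(path)
  lab <- layout@labels
  times <- stats::setNames(rep(NA_real_, length(lab)), lab)
  slopes <- stats::setNames(rep(NA_real_, length(lab)), lab)
  for (l in names(obj$electrodes)) {
    times[l] <- obj$electrodes[[l]]$time_ms
    slopes[l] <- obj$electrodes[[l]]$slope
  }
  new("ActivationMap", times = times, minGradient = slopes,
      window = analysisWindow(obj$window$start, obj$window$size),
      mask = new("SilenceMask", silenced = as.character(unlist(obj$mask))),
      layout = layout)
}

#' Serialize a velocity field (with its fit) to JSON
#'
#' @param field a [VelocityField-class].
#' @param fit the [SurfaceFit-class] it came from.
#' @param path output JSON file.
#' @return invisibly, \code{path}.
#' @export
writeVelocityFieldJSON <- function(field, fit, path) {
  def <- names(field@speeds)[is.finite(field@speeds)]
  diag <- residualDiagnostics(fit)
  obj <- list(
    coefficients = as.list(fit@coefficients),
    mean_speed_mm_s = field@meanSpeed,
    n_points = fit@nPoints,
    undefined = as.list(field@undefined),
    diagnostics = list(residual_mean_ms = diag$mean,
                       residual_sd_ms = diag$sd,
                       shapiro_W = diag$shapiroW,
                       shapiro_p = diag$shapiroP),
    electrodes = stats::setNames(lapply(def, function(l)
      list(vx = field@vectors[l, 1], vy = field@vectors[l, 2],
           speed = field@speeds[[l]], direction_deg = field@directions[[l]],
           Tx = field@gradients[l, 1], Ty = field@gradients[l, 2])), def))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
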