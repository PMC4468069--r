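#' @include AllClasses.R activation.R velocity.R
NULL

# 8x8 grid helpers: map a standard-layout label to its (column, row) cell.
labelCol <- function(lab) as.integer(substr(lab, 1, 1))
labelRow <- function(lab) as.integer(substr(lab, 2, 2))

# Arrange per-electrode values into an 8x8 matrix (rows = grid rows, row 1 at
# the bottom); corners and absent labels stay NA.
gridMatrix <- function(values, labels) {
  m <- matrix(NA_real_, 8, 8)
  for (i in seq_along(labels))
    m[labelRow(labels[i]), labelCol(labels[i])] <- values[i]
  m
}

# Jet-like palette echoing classic activation-map figures; earliest time maps
# to the blue end.
jetColors <- function(n) {
  grDevices::colorRampPalette(c("#00007F", "blue", "#007FFF", "cyan",
                                "#7FFF7F", "yellow", "#FF7F00", "red",
                                "#7F0000"))(n)
}

openFigure <- function(path, width = 1200, height = 1200) {
  if (grepl("\\.svg$", path)) grDevices::svg(path, width = width / 150,
                                             height = height / 150)
  else grDevices::png(path, width = width, height = height, res = 150)
}

#' Trace grid figure
#'
#' Full 8x8 grid of voltage traces (corners blank), or a single electrode
#' with its activation time marked when \code{selectedLabel} is given.
#' Axis units: time in ms, voltage in uV.
#'
#' @param recording an [MEARecording-class].
#' @param path output figure file (.png or .svg).
#' @param window optional [AnalysisWindow-class] restricting the time axis.
#' @param selectedLabel optional electrode label for single-trace mode.
#' @param map optional [ActivationMap-class]; in single-trace mode its
#'   activation time is marked (green) with the smoothed trace superimposed.
#' @return (invisibly) list: \code{path}, \code{nPanels}, \code{blankCells}
#'   (corner cells), and \code{markedTime} (ms, single-trace mode).
#' @export
traceGrid <- function(recording, path, window = NULL, selectedLabel = NULL,
                      map = NULL) {
  tvec <- sampleTimes(recording)
  idx <- if (is.null(window)) seq_along(tvec) else windowIndices(tvec, window)
  if (length(idx) == 0L) stop("window contains no samples")
  lab <- recording@layout@labels
  markedTime <- NA_real_
  openFigure(path)
  on.exit(grDevices::dev.off())
  if (is.null(selectedLabel)) {
    graphics::par(mfrow = c(8, 8), mar = c(0.4, 0.4, 0.4, 0.4))
    ylim <- range(recording@samples[idx, ])
    # grid row 8 (top) drawn first; row 1 at the bottom of the page
    for (r in 8:1) for (cl in 1:8) {
      l <- sprintf("%d%d", cl, r)
      if (!l %in% lab) { graphics::plot.new(); next }
      graphics::plot(tvec[idx], recording@samples[idx, l], type = "l",
                     xaxt = "n", yaxt = "n", ylim = ylim, xlab = "", ylab = "")
      graphics::mtext(l, side = 3, line = -1.1, cex = 0.45)
    }
    n <- length(lab)
  } else {
    if (!selectedLabel %in% lab) stop("unknown electrode label: ", selectedLabel)
    graphics::plot(tvec[idx], recording@samples[idx, selectedLabel], type = "l",
                   xlab = "time [ms]", ylab = "voltage [µV]",
                   main = paste("Electrode", selectedLabel))
    if (nrow(recording@smoothed))
      graphics::lines(tvec[idx], recording@smoothed[idx, selectedLabel],
                      col = "red")
    if (!is.null(map) && is.finite(map@times[selectedLabel])) {
      markedTime <- unname(map@times[selectedLabel])
      graphics::abline(v = markedTime, col = "green3", lwd = 2)
    }
    n <- 1L
  }
  invisible(list(path = path, nPanels = n,
                 blankCells = c("11", "18", "81", "88"),
                 markedTime = markedTime))
}

#' Activation-time heat map
#'
#' 8x8 colour grid of activation times, numerically annotated; silenced and
#' missing electrodes are blank. Earliest time maps to the blue (low) end of
#' the palette. The coordinate convention (x rightward with column, y upward
#' with row, row 1 at the bottom) is stated on the axes.
#'
#' @param map an [ActivationMap-class].
#' @param path output figure file.
#' @param annotate numeric annotation per cell (default TRUE).
#' @return (invisibly) list: \code{path}, \code{grid} (8x8 matrix, ms),
#'   \code{palette}, \code{timeRange}.
#' @export
activationHeatmap <- function(map, path, annotate = TRUE) {
  times <- map@times
  if (all(is.na(times))) stop("activation map has no times")
  lab <- map@layout@labels
  g <- gridMatrix(times, lab)
  pal <- jetColors(64)
  openFigure(path)
  on.exit(grDevices::dev.off())
  graphics::image(1:8, 1:8, t(g), col = pal, xlab = "array column (x →)",
                  ylab = "array row (y ↑, row 1 bottom)",
                  main = "Activation time [ms]", axes = FALSE)
  graphics::axis(1, at = 1:8); graphics::axis(2, at = 1:8)
  if (annotate)
    for (r in 1:8) for (cl in 1:8)
      if (is.finite(g[r, cl]))
        graphics::text(cl, r, sprintf("%.2f", g[r, cl]), cex = 0.6)
  invisible(list(path = path, grid = g, palette = pal,
                 timeRange = range(times, na.rm = TRUE)))
}

#' Isochrone (isoline) map
#'
#' Contour plot of the activation-time field over the array: widely spaced
#' isolines indicate fast propagation, close isolines slow propagation.
#' Cells without a measured time (silenced/corner positions) are imputed
#' from the fitted quadratic activation surface before contouring, the same
#' surface the velocity analysis trusts.
#'
#' @param map an [ActivationMap-class] (>= 6 times).
#' @param path output figure file.
#' @param nLevels number of contour levels (>= 2; ignored when
#'   \code{levelStep} is given).
#' @param levelStep fixed isochrone interval in ms (optional); with a fixed
#'   step, isoline spacing is inversely proportional to speed.
#' @return (invisibly) list: \code{path}, \code{levels} (ms),
#'   \code{contours} (list of contour lines in um coordinates), \code{grid}.
#' @export
isolineMap <- function(map, path, nLevels = 10, levelStep = NULL) {
  times <- map@times
  if (sum(!is.na(times)) < 6L) stop("isoline map needs >= 6 activation times")
  if (is.null(levelStep) && nLevels < 2) stop("need at least 2 contour levels")
  layout <- map@layout
  fit <- fitActivationSurface(map)
  filled <- times
  missing <- names(times)[is.na(times)]
  if (length(missing)) {
    pos <- layout@positions[missing, , drop = FALSE]
    filled[missing] <- predictTime(fit, pos[, 1], pos[, 2])
  }
  g <- gridMatrix(filled, layout@labels)
  pitch <- layout@pitch
  xs <- (0:7) * pitch; ys <- (0:7) * pitch
  # corner cells are outside the layout entirely: impute from the surface too
  for (r in c(1L, 8L)) for (cl in c(1L, 8L))
    if (!sprintf("%d%d", cl, r) %in% layout@labels && is.na(g[r, cl]))
      g[r, cl] <- predictTime(fit, xs[cl], ys[r])
  rng <- range(g, na.rm = TRUE)
  levels <- if (!is.null(levelStep))
    seq(floor(rng[1] / levelStep) * levelStep, rng[2] + levelStep, by = levelStep)
  else pretty(rng, n = nLevels)
  levels <- levels[levels > rng[1] & levels < rng[2]]
  cl <- grDevices::contourLines(xs, ys, t(g), levels = levels)
  openFigure(path)
  on.exit(grDevices::dev.off())
  graphics::image(xs, ys, t(g), col = jetColors(64),
                  xlab = "x [µm] (→ column)",
                  ylab = "y [µm] (↑ row, row 1 bottom)",
                  main = "Activation isochrones [ms]")
  graphics::contour(xs, ys, t(g), levels = levels, add = TRUE, lwd = 1.5)
  invisible(list(path = path, levels = levels, contours = cl, grid = g))
}

#' Velocity vector-field plot
#'
#' One arrow per defined electrode at its position, length proportional to
#' speed, annotated with the mean conduction velocity; undefined electrodes
#' are drawn as open markers.
#'
#' @param field a [VelocityField-class].
#' @param path output figure file.
#' @param scale arrow length in um per (mm/s) (default: pitch / median speed).
#' @return (invisibly) list: \code{path}, \code{angles} (deg, per defined
#'   electrode), \code{meanSpeed} (mm/s), \code{nArrows}.
#' @export
vectorFieldPlot <- function(field, path, scale = NULL) {
  lay <- field@layout
  pos <- lay@positions
  def <- names(field@speeds)[is.finite(field@speeds)]
  if (length(def) == 0L) stop("no defined velocity vectors to plot")
  if (is.null(scale)) scale <- lay@pitch / stats::median(field@speeds[def])
  openFigure(path)
  on.exit(grDevices::dev.off())
  lim <- grDevices::extendrange(range(pos), f = 0.12)
  graphics::plot(NA, xlim = lim, ylim = lim, asp = 1,
                 xlab = "x [µm] (→ column)",
                 ylab = "y [µm] (↑ row, row 1 bottom)",
                 main = sprintf("Velocity field; mean CV %.1f mm/s",
                                field@meanSpeed))
  graphics::points(pos[, 1], pos[, 2], pch = 16, cex = 0.4, col = "grey60")
  und <- union(field@undefined,
               setdiff(lay@labels, c(def, field@undefined)))
  if (length(und))
    graphics::points(pos[und, 1], pos[und, 2], pch = 1, cex = 1.2, col = "red")
  graphics::arrows(pos[def, 1], pos[def, 2],
                   pos[def, 1] + field@vectors[def, 1] * scale,
                   pos[def, 2] + field@vectors[def, 2] * scale,
                   length = 0.06, col = "blue")
  invisible(list(path = path, angles = field@directions[def],
                 meanSpeed = field@meanSpeed, nArrows = length(def)))
}

#' 3D signal-progression frames
#'
#' One perspective-surface frame per (strided) sample of the RAW voltages
#' over the 8x8 grid, with a fixed z axis across frames, so a wavefront can
#' be watched sweeping the array. Frames are numbered PNG files; assemble
#' them into a movie with an external encoder (e.g. ffmpeg) if desired.
#'
#' @param recording an [MEARecording-class].
#' @param window an [AnalysisWindow-class].
#' @param outDir output directory for frames (created if needed).
#' @param stride keep every stride-th sample (default 20).
#' @return (invisibly) list: \code{paths}, \code{nFrames},
#'   \code{argmaxLabel} (per frame, the electrode at the voltage maximum —
#'   useful for checking wavefront progression), \code{zlim}.
#' @export
render3dFrames <- function(recording, window, outDir, stride = 20L) {
  stopifnot(stride >= 1L)
  tvec <- sampleTimes(recording)
  idx <- windowIndices(tvec, window)
  if (length(idx) == 0L) stop("window contains no samples")
  frameIdx <- idx[seq(1, length(idx), by = stride)]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  lab <- recording@layout@labels
  zlim <- range(recording@samples[idx, ])
  if (diff(zlim) == 0) zlim <- zlim + c(-1, 1)
  paths <- character(length(frameIdx))
  argmaxLabel <- character(length(frameIdx))
  for (k in seq_along(frameIdx)) {
    i <- frameIdx[k]
    v <- recording@samples[i, ]
    argmaxLabel[k] <- lab[which.max(v)]
    g <- gridMatrix(v, lab)
    g[is.na(g)] <- 0
    paths[k] <- file.path(outDir, sprintf("frame_%04d.png", k))
    grDevices::png(paths[k], width = 800, height = 800, res = 120)
    graphics::persp(1:8, 1:8, t(g), zlim = zlim, theta = 35, phi = 25,
                    xlab = "column (x)", ylab = "row (y)",
                    zlab = "voltage [uV]", col = "lightblue", shade = 0.4,
                    main = sprintf("t = %.3f ms", tvec[i]))
    grDevices::dev.off()
  }
  invisible(list(paths = paths, nFrames = length(frameIdx),
                 argmaxLabel = argmaxLabel, zlim = zlim))
}
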