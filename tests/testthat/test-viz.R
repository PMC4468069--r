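# Visual outputs are asserted through their structured metadata (times,
# levels, angles, frame order), not pixels; files only need to exist and be
# non-empty.

makeMapAndField <- function(speed = 200, direction = 0) {
  sim <- makePlanarSim(speed = speed, direction = direction)
  rec <- smoothRecording(sim$recording)
  map <- detectActivationMap(rec, fullWindow(rec))
  fit <- fitActivationSurface(map)
  list(rec = rec, map = map, fit = fit,
       field = velocityVectors(fit, recordingLayout(rec)))
}

test_that("trace grids render 60 panels and mark activation times", {
  x <- makeMapAndField()
  p <- withr::local_tempfile(fileext = ".png")
  out <- traceGrid(x$rec, p)
  expect_true(file.exists(p) && file.size(p) > 0)
  expect_equal(out$nPanels, 60)
  expect_setequal(out$blankCells, c("11", "18", "81", "88"))

  out1 <- traceGrid(x$rec, p, selectedLabel = "45", map = x$map)
  expect_equal(out1$markedTime, unname(activationTimes(x$map)["45"]))
  expect_error(traceGrid(x$rec, p, selectedLabel = "99"), "unknown")
})

test_that("heat maps put measured times in the right cells", {
  x <- makeMapAndField()
  p <- withr::local_tempfile(fileext = ".png")
  out <- activationHeatmap(x$map, p)
  expect_true(file.exists(p) && file.size(p) > 0)
  g <- out$grid
  expect_true(all(is.na(g[cbind(c(1, 8, 1, 8), c(1, 1, 8, 8))])))  # corners
  expect_equal(g[2, 1], unname(activationTimes(x$map)["12"]))       # row 2, col 1
  # silenced electrode leaves a blank cell
  lay <- recordingLayout(x$rec)
  mask <- silenceElectrodes(methods::new("SilenceMask"), "45", lay)
  map2 <- detectActivationMap(x$rec, fullWindow(x$rec), mask)
  out2 <- activationHeatmap(map2, p)
  expect_true(is.na(out2$grid[5, 4]))
  expect_error(activationHeatmap(
    methods::new("ActivationMap", times = setNames(rep(NA_real_, 60),
                                                   electrodeLabels(lay)),
                 minGradient = setNames(rep(NA_real_, 60), electrodeLabels(lay)),
                 window = x$map@window,
                 mask = silenceElectrodes(methods::new("SilenceMask"),
                                          electrodeLabels(lay), lay),
                 layout = lay), p), "no times")
})

test_that("planar isochrones are straight, parallel and evenly spaced", {
  x <- makeMapAndField(speed = 200, direction = 0)
  p <- withr::local_tempfile(fileext = ".png")
  out <- isolineMap(x$map, p, levelStep = 1)
  expect_true(file.exists(p) && file.size(p) > 0)
  # each contour of a wave along +x is a vertical line: x spread ~ 0
  xSpread <- vapply(out$contours, function(cl) diff(range(cl$x)), numeric(1))
  expect_lt(max(xSpread), 2)
  # mean x per isochrone level; spacing = distance covered per ms
  meanXByLevel <- function(cls) {
    lv <- vapply(cls, `[[`, numeric(1), "level")
    xs <- vapply(cls, function(cl) mean(cl$x), numeric(1))
    sort(as.numeric(tapply(xs, lv, mean)))
  }
  xs <- meanXByLevel(out$contours)
  expect_equal(unname(diff(xs)), rep(200, length(xs) - 1), tolerance = 0.02)

  # halving the speed halves the isoline spacing at fixed level step
  xSlow <- makeMapAndField(speed = 100, direction = 0)
  outS <- isolineMap(xSlow$map, p, levelStep = 1)
  xsS <- meanXByLevel(outS$contours)
  expect_equal(mean(diff(xsS)) / mean(diff(xs)), 0.5, tolerance = 0.02)
})

test_that("focal isochrones close around the origin", {
  spec <- shiftT0ToFit(focalWave(150, origin = c(700, 600)))
  sim <- generateRecording(spec)
  rec <- smoothRecording(sim$recording)
  map <- detectActivationMap(rec, fullWindow(rec))
  p <- withr::local_tempfile(fileext = ".png")
  out <- isolineMap(map, p, nLevels = 8)
  # at least one contour is closed (first and last vertex coincide)
  closed <- vapply(out$contours, function(cl)
    sqrt((cl$x[1] - cl$x[length(cl$x)])^2 +
         (cl$y[1] - cl$y[length(cl$y)])^2) < 1e-6, logical(1))
  expect_true(any(closed))
})

test_that("vector-field plots expose per-arrow angles", {
  x <- makeMapAndField(direction = 30)
  p <- withr::local_tempfile(fileext = ".png")
  out <- vectorFieldPlot(x$field, p)
  expect_true(file.exists(p) && file.size(p) > 0)
  expect_equal(out$nArrows, 60)
  expect_equal(out$meanSpeed, meanSpeed(x$field))
  # arrow angles equal atan2(vy, vx); planar field is parallel
  v <- velocityVectorMatrix(x$field)
  expect_equal(out$angles,
               atan2(v[, 2], v[, 1])[names(out$angles)] * 180 / pi)
  # planar field: arrows parallel up to sample-quantization of the times
  expect_lt(diff(range(out$angles)), 1)
})

test_that("3D frames stride the window and track wavefront progression", {
  x <- makeMapAndField(speed = 200, direction = 0)
  dir <- withr::local_tempdir()
  w <- analysisWindow(sampleTimes(x$rec)[1], 9)   # 9 ms at 20 kHz
  out <- render3dFrames(x$rec, w, dir, stride = 20)
  expect_equal(out$nFrames, 9)                    # 180 samples / 20
  expect_true(all(file.exists(out$paths)))
  expect_true(all(file.size(out$paths) > 0))

  # while the wavefront crosses the array, the per-frame positive-peak
  # electrode advances monotonically along the propagation axis
  tt <- activationTimes(x$map)
  wf <- analysisWindow(min(tt), diff(range(tt)) + 1e-9)
  of <- render3dFrames(x$rec, wf, dir, stride = 10)
  xs <- electrodePositions(recordingLayout(x$rec))[of$argmaxLabel, 1]
  expect_gte(cor(seq_along(xs), xs, method = "spearman"), 0.9)

  # constant recording: identical frames (same argmax, fixed z-limits)
  lay <- standardLayout()
  cst <- meaRecording(matrix(1, 100, 60), 20000, lay)
  oc <- render3dFrames(cst, analysisWindow(0, 4), dir, stride = 10)
  expect_equal(length(unique(oc$argmaxLabel)), 1)
})
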