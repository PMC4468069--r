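# Shared fixtures: everything generated in code at test time.

# A planar-wave simulation on the standard layout, shifted so the template
# fits; small enough to be regenerated freely.
makePlanarSim <- function(speed = 200, direction = 30, noiseLevel = 0,
                          seed = 1L, samplingRate = 20000, ...) {
  spec <- shiftT0ToFit(planarWave(speed, direction, noiseLevel = noiseLevel,
                                  seed = seed))
  generateRecording(spec, samplingRate = samplingRate, ...)
}

fullWindow <- function(rec) {
  tv <- sampleTimes(rec)
  analysisWindow(tv[1], tv[length(tv)] - tv[1] + 1e-9)
}

# Exactly-quadratic activation times at the standard positions.
quadTimes <- function(co = c(a = 1e-6, b = -2e-6, c = 5e-7, d = 5e-3,
                             e = -2e-3, f = 10),
                      layout = standardLayout()) {
  pos <- electrodePositions(layout)
  tt <- arrivalTime(quadraticWave(co), pos[, 1], pos[, 2])
  names(tt) <- electrodeLabels(layout)
  tt
}

# Small random recording for I/O round trips.
randomRecording <- function(n = 5, seed = 42) {
  lay <- standardLayout()
  set.seed(seed)
  meaRecording(matrix(rnorm(n * 60, sd = 100), nrow = n), 20000, lay)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-300)), tol)
}
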