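test_that("numeric gradient: central interior, one-sided ends", {
  # linear ramp: exact slope everywhere including both ends
  expect_equal(numericGradient(3 * (0:10), 1), rep(3, 11))
  # quadratic: exact at interior points
  t <- 0:20
  g <- numericGradient(t^2, 1)
  expect_equal(g[2:20], 2 * t[2:20])
  expect_equal(numericGradient(rep(1, 9), 0.5), rep(0, 9))
  expect_error(numericGradient(1, 1), "at least 2")
})

test_that("detection equals brute-force argmin of the gradient (oracle, 1000 traces)", {
  set.seed(99)
  dt <- 0.05
  for (i in 1:1000) {
    n <- sample(20:120, 1)
    tr <- rnorm(n)
    tv <- (seq_len(n) - 1) * dt
    w <- analysisWindow(0, n * dt)
    got <- detectActivationTime(tr, tv, w)
    g <- numericGradient(tr, dt)
    k <- which.min(g)
    expect_identical(got$time, tv[k])
    expect_identical(got$slope, g[k])
  }
})

test_that("ties break to the earliest sample; degenerate traces are flagged", {
  tv <- (0:99) * 0.05
  w <- analysisWindow(0.5, 2)
  # descending ramp: every gradient exactly equal -> earliest in-window sample
  got <- detectActivationTime(-(0:99), tv, w)
  expect_equal(got$time, 0.5)
  # monotonically increasing trace: slope flagged non-negative
  up <- detectActivationTime(tv^1.5, tv, w)
  expect_true(up$nonNegative)
  expect_gte(up$slope, 0)
  expect_error(detectActivationTime(-tv, tv, analysisWindow(100, 5)),
               "no samples")
})

test_that("detection recovers the template's analytic steepest descent", {
  # the biphasic template has its steepest descent exactly at tau = 0
  tpl <- fpTemplate(amplitude = 300, width = 1)
  fs <- 20000
  tv <- (0:999) / fs * 1000
  tstar <- 25.3712
  tr <- templateWaveform(tpl, tv - tstar)
  w <- analysisWindow(0, 50)
  got <- detectActivationTime(sgSmooth(tr, smoothingConfig(3, 10)), tv, w)
  expect_lt(abs(got$time - tstar), 1000 / fs + 1e-12)   # within 1 sample
  # with noise at one tenth of the trace's robust SD the error stays well
  # below the template width (the gradient extremum is locally flat, so
  # exact-sample recovery under noise is not expected; see the vignette)
  rsd <- MEAflow:::robustSD(tr)
  errs <- sapply(1:20, function(i) {
    set.seed(i)
    noisy <- tr + rnorm(length(tr), sd = rsd / 10)
    sm <- sgSmooth(noisy, smoothingConfig(3, 25))
    abs(detectActivationTime(sm, tv, w)$time - tstar)
  })
  expect_lt(max(errs), 0.25)
  expect_lt(median(errs), 0.1)
})

test_that("detected time is amplitude-equivariant and window-consistent", {
  set.seed(21)
  dt <- 0.05
  tv <- (0:399) * dt
  for (i in 1:20) {
    tr <- cumsum(rnorm(400))
    w <- analysisWindow(0, 400 * dt)
    t1 <- detectActivationTime(tr, tv, w)$time
    # scaling by c > 0 does not move the argmin
    expect_identical(detectActivationTime(3.7 * tr, tv, w)$time, t1)
    # enlarging a window that already contains the global minimum is a no-op
    g <- numericGradient(tr, dt)
    k <- which.min(g)
    small <- analysisWindow(max(0, tv[k] - 1), 2)
    expect_identical(detectActivationTime(tr, tv, small)$time, t1)
  }
})

test_that("activation maps recover planar ground truth within one sample", {
  sim <- makePlanarSim(speed = 200, direction = 30)
  rec <- smoothRecording(sim$recording)
  map <- detectActivationMap(rec, fullWindow(rec))
  err <- abs(activationTimes(map) - sim$truth$arrivalTimes)
  expect_true(all(err <= 1000 / samplingRate(rec) + 1e-12))
  expect_true(all(minGradients(map) < 0))
})

test_that("silencing excludes electrodes from the map", {
  sim <- makePlanarSim()
  rec <- smoothRecording(sim$recording)
  lay <- recordingLayout(rec)
  allBut12 <- setdiff(electrodeLabels(lay), "12")
  mask <- silenceElectrodes(new("SilenceMask"), allBut12, lay)
  map <- detectActivationMap(rec, fullWindow(rec), mask)
  expect_equal(sum(!is.na(activationTimes(map))), 1)
  expect_false(is.na(activationTimes(map)["12"]))
  mask2 <- silenceElectrodes(mask, "12", lay)
  expect_error(detectActivationMap(rec, fullWindow(rec), mask2), "silenced")
})

test_that("silence/unsilence are idempotent set operations", {
  lay <- standardLayout()
  m <- silenceElectrodes(new("SilenceMask"), "12", lay)
  expect_identical(silencedLabels(silenceElectrodes(m, "12", lay)), "12")
  m2 <- silenceElectrodes(m, "21", lay)
  expect_identical(silencedLabels(unsilenceElectrodes(m2, "12", lay)), "21")
  expect_identical(silencedLabels(unsilenceElectrodes(m2, c("12", "21"), lay)),
                   character(0))
  expect_error(silenceElectrodes(m, "99", lay), "99")
  expect_error(silenceElectrodes(m, "11", lay), "11")  # corner absent
})

test_that("identical traces yield identical activation times", {
  lay <- standardLayout()
  tpl <- fpTemplate()
  tv <- (0:599) / 20   # 20 kHz
  one <- templateWaveform(tpl, tv - 15)
  rec <- meaRecording(matrix(one, nrow = length(tv), ncol = 60), 20000, lay)
  rec <- smoothRecording(rec)
  map <- detectActivationMap(rec, fullWindow(rec))
  expect_equal(unname(diff(range(activationTimes(map)))), 0)
})

test_that("beat detection finds a seeded field-potential train", {
  fs <- 1000
  cfg <- smoothingConfig(3, 10)
  tpl <- fpTemplate(amplitude = 400, width = 4)
  tv <- (0:9999) / fs * 1000          # 10 s
  starts <- seq(250, 9750, by = 500)  # 2 Hz -> 20 beats
  tr <- rowSums(sapply(starts, function(s) templateWaveform(tpl, tv - s)))
  set.seed(8)
  tr <- tr + rnorm(length(tr), sd = 5)
  ev <- detectBeats(tr, fs, config = cfg)
  expect_length(ev, 20)
  expect_true(all(abs(ev - starts) <= 1.5))
  expect_true(all(diff(ev) >= 100))
  # amplitude invariance: relative threshold
  expect_equal(detectBeats(tr * 3, fs, config = cfg), ev)
  # doubling the stimulus rate doubles the count
  starts2 <- seq(125, 9875, by = 250)
  tr2 <- rowSums(sapply(starts2, function(s) templateWaveform(tpl, tv - s)))
  set.seed(8)
  tr2 <- tr2 + rnorm(length(tr2), sd = 5)
  expect_length(detectBeats(tr2, fs, config = cfg), 40)
})

test_that("flat noisy traces produce no beat events at k = 5", {
  set.seed(13)
  tr <- rnorm(10000, sd = 20)
  expect_length(detectBeats(tr, 1000, config = smoothingConfig(3, 10)), 0)
  expect_error(detectBeats(tr, 1000, refractoryMs = 0), "positive")
})

test_that("beat rate is events per minute", {
  expect_equal(beatRate(seq(0, 9500, by = 500), 10000), 120)
  expect_equal(beatRate(numeric(0), 10000), 0)
  expect_error(beatRate(1:3, -5), "positive")
})
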