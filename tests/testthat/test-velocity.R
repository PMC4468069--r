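test_that("exact quadratic data are interpolated to machine precision", {
  lay <- standardLayout()
  co <- c(a = 1e-6, b = -2e-6, c = 0, d = 5e-3, e = 0, f = 10)
  tt <- quadTimes(co)
  fit <- fitActivationSurface(tt, lay)
  expect_rel_equal(coef(fit)[c("a", "b", "d", "f")], co[c("a", "b", "d", "f")], 1e-9)
  expect_lt(max(abs(coef(fit)[c("c", "e")])), 1e-15)
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("a plane wave fits with zero curvature terms", {
  lay <- standardLayout()
  pos <- electrodePositions(lay)
  tt <- setNames(10 + pos[, 1] * 0.005, electrodeLabels(lay))  # 200 mm/s along x
  fit <- fitActivationSurface(tt, lay)
  co <- coef(fit)
  expect_lt(max(abs(co[c("a", "b", "c", "e")])), 1e-12)
  expect_equal(unname(co["d"]), 0.005, tolerance = 1e-9)
  expect_equal(unname(co["f"]), 10, tolerance = 1e-9)
})

test_that("six points in general position give an exact fit", {
  labs <- c("12", "34", "56", "71", "25", "87")
  lay <- standardLayout()
  set.seed(4)
  tt <- setNames(runif(6, 5, 20), labs)
  fit <- fitActivationSurface(tt, lay)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_equal(fit@rank, 6L)
})

test_that("fit preconditions and degeneracy are enforced", {
  lay <- standardLayout()
  tt <- quadTimes()
  expect_error(fitActivationSurface(tt[1:5], lay), "at least 6")
  # collinear electrodes: rank-deficient design -> warning + minimum-norm fit
  col1 <- paste0("2", 1:8)  # one grid column -> x constant
  expect_warning(fitActivationSurface(tt[col1], lay), "rank")
})

test_that("predicted time + residual reproduces observations; residuals orthogonal", {
  set.seed(17)
  lay <- standardLayout()
  tt <- quadTimes() + rnorm(60, sd = 0.3)
  fit <- fitActivationSurface(tt, lay)
  expect_lt(max(abs(fitted(fit) + residuals(fit) - tt)), 1e-9)
  expect_equal(mean(residuals(fit)), 0, tolerance = 1e-9)  # constant column
  # orthogonality to each design column, on the conditioned design
  pos <- electrodePositions(lay)
  u <- (pos[, 1] - mean(pos[, 1])); u <- u / sqrt(mean(u^2))
  v <- (pos[, 2] - mean(pos[, 2])); v <- v / sqrt(mean(v^2))
  X <- cbind(u^2, v^2, u * v, u, v, 1)
  rel <- abs(t(X) %*% residuals(fit)) / (sqrt(colSums(X^2)) * sqrt(sum(residuals(fit)^2)))
  expect_lt(max(rel), 1e-6)
})

test_that("surface prediction and gradient follow the closed forms", {
  lay <- standardLayout()
  tt <- quadTimes(c(a = 0, b = 0, c = 0, d = 0, e = 0, f = 7))
  fit <- fitActivationSurface(tt, lay)
  expect_equal(predictTime(fit, 123, -456), 7, tolerance = 1e-9)
  expect_lt(max(abs(surfaceGradient(fit, 123, -456))), 1e-12)

  co <- c(a = 2e-6, b = -1e-6, c = 4e-7, d = 3e-3, e = -2e-3, f = 5)
  fit2 <- fitActivationSurface(quadTimes(co), lay)
  g0 <- surfaceGradient(fit2, 0, 0)
  expect_equal(unname(g0[1, ]), unname(co[c("d", "e")]), tolerance = 1e-9)
  # finite-difference oracle at several points
  h <- 1
  for (p in list(c(0, 0), c(700, 600), c(-100, 1500))) {
    fd <- c((predictTime(fit2, p[1] + h, p[2]) - predictTime(fit2, p[1] - h, p[2])) / (2 * h),
            (predictTime(fit2, p[1], p[2] + h) - predictTime(fit2, p[1], p[2] - h)) / (2 * h))
    expect_rel_equal(surfaceGradient(fit2, p[1], p[2])[1, ], fd, 1e-6)
  }
})

test_that("planar velocity vectors equal speed times the unit direction", {
  lay <- standardLayout()
  pos <- electrodePositions(lay)
  th <- 30 * pi / 180
  tt <- setNames(10 + (pos[, 1] * cos(th) + pos[, 2] * sin(th)) / 200,
                 electrodeLabels(lay))
  fit <- fitActivationSurface(tt, lay)
  field <- velocityVectors(fit, lay)
  vecs <- velocityVectorMatrix(field)
  expect_equal(unname(vecs[, 1]), rep(200 * cos(th), 60), tolerance = 1e-6)
  expect_equal(unname(vecs[, 2]), rep(200 * sin(th), 60), tolerance = 1e-6)
  expect_equal(unname(vecs["45", ]), c(173.2050808, 100), tolerance = 1e-6)
  expect_equal(meanSpeed(field), 200, tolerance = 1e-9)
  expect_equal(meanConductionVelocity(field), 200, tolerance = 1e-9)

  # brute-force check of V = (Tx, Ty) / (Tx^2 + Ty^2) at every electrode
  G <- field@gradients
  V2 <- G / (G[, 1]^2 + G[, 2]^2)
  expect_equal(unname(vecs), unname(V2), tolerance = 1e-12)
})

test_that("V . grad T = 1 and |V| = 1 / |grad T| at every defined electrode", {
  set.seed(31)
  lay <- standardLayout()
  for (i in 1:10) {
    tt <- quadTimes(c(a = runif(1, -2e-6, 2e-6), b = runif(1, -2e-6, 2e-6),
                      c = runif(1, -1e-6, 1e-6), d = runif(1, 1e-3, 8e-3),
                      e = runif(1, -8e-3, 8e-3), f = runif(1, 0, 20))) +
      rnorm(60, sd = 0.05)
    fit <- fitActivationSurface(tt, lay)
    field <- velocityVectors(fit, lay)
    def <- !is.na(field@vectors[, 1])
    dotp <- rowSums(field@vectors[def, ] * field@gradients[def, ])
    expect_lt(max(abs(dotp - 1)), 1e-9)
    gn <- sqrt(rowSums(field@gradients[def, ]^2))
    expect_lt(max(abs(speeds(field)[def] - 1 / gn)), 1e-12)
  }
})

test_that("doubling activation times halves every speed", {
  lay <- standardLayout()
  tt <- quadTimes()
  f1 <- velocityVectors(fitActivationSurface(tt, lay), lay)
  f2 <- velocityVectors(fitActivationSurface(2 * tt, lay), lay)
  expect_equal(unname(speeds(f2)), unname(speeds(f1)) / 2, tolerance = 1e-9)
})

test_that("a stationary surface leaves every velocity undefined", {
  lay <- standardLayout()
  tt <- quadTimes(c(a = 0, b = 0, c = 0, d = 0, e = 0, f = 12))
  fit <- fitActivationSurface(tt, lay)
  expect_error(velocityVectors(fit, lay), "undefined at every electrode")
})

test_that("mean speed averages defined electrodes and is permutation-invariant", {
  lay <- standardLayout()
  tt <- quadTimes()
  field <- velocityVectors(fitActivationSurface(tt, lay), lay)
  s <- speeds(field)[is.finite(speeds(field))]
  expect_equal(meanConductionVelocity(field), mean(s))
  expect_equal(mean(s), mean(sample(s)))
  # single defined electrode: mean equals that speed
  mask <- silenceElectrodes(new("SilenceMask"),
                            setdiff(electrodeLabels(lay), "45"), lay)
  f1 <- velocityVectors(fitActivationSurface(tt, lay), lay, mask)
  expect_equal(meanConductionVelocity(f1), unname(speeds(f1)["45"]))
})

test_that("rotation and translation equivariance of the velocity field", {
  lay <- standardLayout()
  pos <- electrodePositions(lay)
  tt <- quadTimes() + setNames(rnorm(60, sd = 0.1), electrodeLabels(lay))
  f0 <- velocityVectors(fitActivationSurface(tt, lay), lay)

  # translation: same vectors
  posT <- pos + matrix(c(1234, -567), 60, 2, byrow = TRUE)
  layT <- electrodeLayout(electrodeLabels(lay), posT, layoutPitch(lay))
  fT <- velocityVectors(fitActivationSurface(tt, layT), layT)
  expect_equal(unname(fT@vectors), unname(f0@vectors), tolerance = 1e-6)

  # rotation by phi: vectors rotate by phi
  phi <- 40 * pi / 180
  Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  posR <- pos %*% t(Rm)
  layR <- electrodeLayout(electrodeLabels(lay), posR, layoutPitch(lay))
  fR <- velocityVectors(fitActivationSurface(tt, layR), layR)
  expect_equal(unname(fR@vectors), unname(f0@vectors %*% t(Rm)),
               tolerance = 1e-6)
})

test_that("dropping electrodes from exact quadratic data leaves coefficients fixed", {
  set.seed(23)
  lay <- standardLayout()
  tt <- quadTimes()
  full <- coef(fitActivationSurface(tt, lay))
  for (n in c(10, 30, 50, 54)) {
    keep <- sample(names(tt), 60 - n)
    sub <- coef(fitActivationSurface(tt[keep], lay))
    expect_rel_equal(sub[abs(full) > 0], full[abs(full) > 0], 1e-9)
  }
})

test_that("the OLS solution is a local minimum of the RSS", {
  set.seed(41)
  lay <- standardLayout()
  tt <- quadTimes() + rnorm(60, sd = 0.2)
  fit <- fitActivationSurface(tt, lay)
  pos <- electrodePositions(lay)
  rssOf <- function(co) {
    pred <- co["a"] * pos[, 1]^2 + co["b"] * pos[, 2]^2 +
      co["c"] * pos[, 1] * pos[, 2] + co["d"] * pos[, 1] +
      co["e"] * pos[, 2] + co["f"]
    sum((tt - pred)^2)
  }
  base <- rssOf(coef(fit))
  expect_equal(base, fit@rss, tolerance = 1e-9)
  # perturb each coefficient on its natural scale
  scalePer <- c(a = 1e-9, b = 1e-9, c = 1e-9, d = 1e-6, e = 1e-6, f = 1e-3)
  for (nm in names(scalePer)) for (sgn in c(-1, 1)) {
    co <- coef(fit)
    co[nm] <- co[nm] + sgn * scalePer[nm]
    expect_gt(rssOf(co), base)
  }
})

test_that("residual diagnostics recover the noise scale (Monte-Carlo)", {
  lay <- standardLayout()
  ttClean <- quadTimes()
  # exact data: all-zero residuals, NA normality statistic
  d0 <- residualDiagnostics(fitActivationSurface(ttClean, lay))
  expect_equal(d0$mean, 0, tolerance = 1e-12)
  expect_true(is.na(d0$shapiroW))
  expect_equal(nrow(d0$pairs), 60)

  sigma <- 0.2
  set.seed(57)
  sds <- replicate(200, {
    tt <- ttClean + rnorm(60, sd = sigma)
    residualDiagnostics(fitActivationSurface(tt, lay))$sd
  })
  # OLS residual SD underestimates sigma by sqrt((n - p) / n); 25% band
  expect_lt(abs(mean(sds) - sigma) / sigma, 0.25)
  d <- residualDiagnostics(fitActivationSurface(ttClean + rnorm(60, sd = sigma), lay))
  expect_true(is.finite(d$shapiroW) && d$shapiroW > 0 && d$shapiroW <= 1)
})
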