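#' @include AllClasses.R activation.R
NULL

# Quadratic design matrix in (already transformed) coordinates.
quadDesign <- function(x, y) cbind(x^2, y^2, x * y, x, y, 1)

#' Fit the quadratic activation surface
#'
#' Ordinary least-squares fit of T(x, y) = a x^2 + b y^2 + c x y + d x +
#' e y + f to the activation times of all non-silenced electrodes with a
#' detected time. For conditioning, coordinates are centred and scaled to
#' unit RMS before solving (raw um^2 terms are ~1e6); the minimum-norm
#' least-squares solution is obtained by SVD and coefficients are
#' back-transformed to um/ms units. A rank-deficient design (electrodes on a
#' degenerate conic set) triggers a warning and the minimum-norm fit.
#'
#' @param map an [ActivationMap-class] (or a named numeric vector of
#'   activation times in ms).
#' @param layout the [ElectrodeLayout-class]; defaults to the map's layout.
#' @return a [SurfaceFit-class].
#' @export
fitActivationSurface <- function(map, layout = NULL) {
  if (is(map, "ActivationMap")) {
    if (is.null(layout)) layout <- map@layout
    times <- map@times
  } else {
    times <- map
    if (is.null(layout)) stop("layout required when fitting raw times")
  }
  times <- times[!is.na(times)]
  lab <- names(times)
  if (!all(lab %in% layout@labels)) stop("times contain labels not in layout")
  n <- length(times)
  if (n < 6L) stop("surface fit requires at least 6 electrodes with times; got ", n)
  pos <- layout@positions[lab, , drop = FALSE]
  cx <- mean(pos[, 1]); cy <- mean(pos[, 2])
  u <- pos[, 1] - cx; v <- pos[, 2] - cy
  sx <- sqrt(mean(u^2)); sy <- sqrt(mean(v^2))
  if (sx == 0) sx <- 1
  if (sy == 0) sy <- 1
  u <- u / sx; v <- v / sy
  X <- quadDesign(u, v)
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  keep <- sv$d > tol
  rank <- sum(keep)
  if (rank < 6L)
    warning("rank-deficient design (rank ", rank, "); returning minimum-norm fit")
  beta <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% times) / sv$d[keep])
  beta <- drop(beta)
  fittedv <- drop(X %*% beta)
  res <- times - fittedv
  # back-transform: T = A u^2 + B v^2 + C u v + D u + E v + F with
  # u = (x - cx)/sx, v = (y - cy)/sy  ->  coefficients in raw x, y
  A <- beta[1]; B <- beta[2]; C <- beta[3]; D <- beta[4]; E <- beta[5]; F <- beta[6]
  a <- A / sx^2
  b <- B / sy^2
  cc <- C / (sx * sy)
  d <- -2 * A * cx / sx^2 - C * cy / (sx * sy) + D / sx
  e <- -2 * B * cy / sy^2 - C * cx / (sx * sy) + E / sy
  f <- A * cx^2 / sx^2 + B * cy^2 / sy^2 + C * cx * cy / (sx * sy) -
    D * cx / sx - E * cy / sy + F
  new("SurfaceFit",
      coefficients = c(a = a, b = b, c = cc, d = d, e = e, f = f),
      residuals = stats::setNames(res, lab),
      fitted = stats::setNames(fittedv, lab),
      rss = sum(res^2), nPoints = as.integer(n),
      transform = list(cx = cx, cy = cy, sx = sx, sy = sy),
      rank = as.integer(rank))
}

#' Evaluate the fitted activation surface
#'
#' @param fit a [SurfaceFit-class].
#' @param x,y coordinates in um (vectorized).
#' @return predicted activation time(s) in ms.
#' @export
predictTime <- function(fit, x, y) {
  co <- unname(fit@coefficients)
  co[1] * x^2 + co[2] * y^2 + co[3] * x * y + co[4] * x + co[5] * y + co[6]
}

#' Spatial gradient of the fitted surface
#'
#' Tx = dT/dx = 2 a x + c y + d and Ty = dT/dy = 2 b y + c x + e, in ms/um.
#'
#' @param fit a [SurfaceFit-class].
#' @param x,y coordinates in um (vectorized).
#' @return matrix with columns \code{Tx}, \code{Ty} (ms/um).
#' @export
surfaceGradient <- function(fit, x, y) {
  co <- unname(fit@coefficients)
  cbind(Tx = 2 * co[1] * x + co[3] * y + co[4],
        Ty = 2 * co[2] * y + co[3] * x + co[5], deparse.level = 0)
}

#' Velocity vectors from a fitted activation surface
#'
#' At each non-silenced electrode position the velocity vector is
#' V = (Tx, Ty) / (Tx^2 + Ty^2), the gradient direction scaled so that
#' V . grad T = 1: speed is 1 / |grad T|. With coordinates in um and times in
#' ms, speeds come out in um/ms, numerically equal to mm/s. Electrodes where
#' |grad T| < \code{tol} (stationary surface) are flagged undefined, reported
#' and excluded from the mean speed.
#'
#' @param fit a [SurfaceFit-class].
#' @param layout an [ElectrodeLayout-class].
#' @param mask a [SilenceMask-class].
#' @param tol gradient-degeneracy tolerance in ms/um (default 1e-12).
#' @return a [VelocityField-class].
#' @export
velocityVectors <- function(fit, layout = standardLayout(),
                            mask = new("SilenceMask"), tol = 1e-12) {
  lab <- layout@labels
  active <- setdiff(lab, mask@silenced)
  pos <- layout@positions
  G <- surfaceGradient(fit, pos[, 1], pos[, 2])
  rownames(G) <- lab
  g2 <- G[, 1]^2 + G[, 2]^2
  gnorm <- sqrt(g2)
  vec <- matrix(NA_real_, nrow = length(lab), ncol = 2,
                dimnames = list(lab, c("vx", "vy")))
  speedsV <- stats::setNames(rep(NA_real_, length(lab)), lab)
  dirs <- stats::setNames(rep(NA_real_, length(lab)), lab)
  undef <- character(0)
  for (el in active) {
    if (gnorm[el] < tol) {
      undef <- c(undef, el)
      next
    }
    vec[el, ] <- G[el, ] / g2[el]
    speedsV[el] <- 1 / gnorm[el]
    dirs[el] <- atan2(vec[el, 2], vec[el, 1]) * 180 / pi
  }
  defined <- speedsV[!is.na(speedsV)]
  if (length(defined) == 0L)
    stop("velocity undefined at every electrode (stationary activation surface)")
  new("VelocityField", vectors = vec, speeds = speedsV, directions = dirs,
      gradients = G, meanSpeed = mean(defined), undefined = undef,
      layout = layout)
}

#' Mean local conduction velocity
#'
#' Arithmetic mean of the per-electrode speeds over the electrodes where the
#' velocity vector is defined.
#'
#' @param field a [VelocityField-class].
#' @return mean conduction velocity in mm/s.
#' @export
meanConductionVelocity <- function(field) {
  s <- field@speeds[is.finite(field@speeds)]
  if (length(s) == 0L) stop("no defined electrodes")
  mean(s)
}

#' Residual diagnostics of a surface fit
#'
#' Goodness-of-fit summary for assessing the quality of the velocity
#' estimates: a good fit has residuals approximately normally distributed
#' around zero and unstructured against predicted activation time. The
#' normality statistic is the Shapiro-Wilk W (with p value); it is NA when
#' residuals are numerically constant (exact fits), where the test is
#' undefined.
#'
#' @param fit a [SurfaceFit-class].
#' @return list with \code{mean}, \code{sd}, \code{pairs} (data.frame of
#'   predicted and residual, ms, for plotting), \code{shapiroW},
#'   \code{shapiroP}.
#' @export
residualDiagnostics <- function(fit) {
  r <- fit@residuals
  prs <- data.frame(label = names(r), predicted = fit@fitted, residual = r,
                    row.names = NULL)
  W <- NA_real_; P <- NA_real_
  if (length(r) >= 3 && diff(range(r)) > 1e-12 * max(1, max(abs(r)))) {
    sw <- stats::shapiro.test(r)
    W <- unname(sw$statistic); P <- sw$p.value
  }
  list(mean = mean(r), sd = stats::sd(r), pairs = prs, shapiroW = W, shapiroP = P)
}
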