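#' @include AllClasses.R io.R velocity.R
NULL

#' Field-potential template constructor
#'
#' @param amplitude peak absolute amplitude in uV (default 500, typical of
#'   neonatal cardiomyocyte monolayer field potentials).
#' @param width lobe half-width in ms (default 1).
#' @return an [FPTemplate-class].
#' @export
fpTemplate <- function(amplitude = 500, width = 1)
  new("FPTemplate", amplitude = amplitude, width = width)

# Template waveform and its support half-length (the waveform decays as a
# Gaussian; beyond 6 widths it is below 1e-7 of peak and treated as zero).
templateSupport <- function(template) 6 * template@width

#' Evaluate the biphasic template
#'
#' g(tau) = -A (tau/w) exp((1 - (tau/w)^2) / 2): positive lobe at tau = -w,
#' dominant downstroke crossing zero at tau = 0 where the derivative attains
#' its unique minimum -A e^(1/2) / w (steepest descent exactly at tau = 0).
#'
#' @param template an [FPTemplate-class].
#' @param tau time offsets from the activation time, in ms (vectorized).
#' @return waveform values in uV.
#' @export
templateWaveform <- function(template, tau) {
  s <- tau / template@width
  -template@amplitude * s * exp((1 - s^2) / 2)
}

#' Wavefront specifications
#'
#' Construct a [WaveSpec-class] for the simulator: \code{planarWave}
#' propagates a straight wavefront at constant speed along a direction;
#' \code{focalWave} spreads isotropically from an origin point (the
#' corner-initiation pattern seen in cultured monolayers paced by an edge
#' pacemaker); \code{quadraticWave} draws activation times directly from a
#' quadratic surface so the fitting model is exactly correct.
#'
#' @param speed wavefront speed in mm/s (= um/ms).
#' @param direction propagation direction in degrees (planar).
#' @param origin numeric (x, y) origin in um (focal).
#' @param coefficients named numeric a..f (quadratic; ms, um units).
#' @param t0 activation-time offset in ms.
#' @param template an [FPTemplate-class].
#' @param noiseLevel additive white Gaussian noise level in robust-SD
#'   multiples of each clean trace (0 = noise-free).
#' @param seed integer seed for the noise draw.
#' @return a [WaveSpec-class].
#' @name waveSpecs
NULL

#' @rdname waveSpecs
#' @export
planarWave <- function(speed, direction, t0 = 8, template = fpTemplate(),
                       noiseLevel = 0, seed = 1L) {
  new("WaveSpec", kind = "planar", speed = speed, direction = direction,
      t0 = t0, template = template, noiseLevel = noiseLevel,
      seed = as.integer(seed))
}

#' @rdname waveSpecs
#' @export
focalWave <- function(speed, origin, t0 = 8, template = fpTemplate(),
                      noiseLevel = 0, seed = 1L) {
  new("WaveSpec", kind = "focal", speed = speed, origin = as.numeric(origin),
      t0 = t0, template = template, noiseLevel = noiseLevel,
      seed = as.integer(seed))
}

#' @rdname waveSpecs
#' @export
quadraticWave <- function(coefficients, t0 = 0, template = fpTemplate(),
                          noiseLevel = 0, seed = 1L) {
  co <- coefficients[c("a", "b", "c", "d", "e", "f")]
  new("WaveSpec", kind = "quadratic", coefficients = co, t0 = t0,
      template = template, noiseLevel = noiseLevel, seed = as.integer(seed))
}

#' Ground-truth arrival time of a wavefront at a point
#'
#' Planar: t0 + (x cos theta + y sin theta) / speed. Focal: t0 + distance to
#' origin / speed. Quadratic: the surface value plus t0. Speeds in mm/s equal
#' um/ms, so um coordinates divide directly.
#'
#' @param spec a [WaveSpec-class].
#' @param x,y coordinates in um (vectorized).
#' @return arrival time(s) in ms.
#' @export
arrivalTime <- function(spec, x, y) {
  switch(spec@kind,
    planar = {
      th <- spec@direction * pi / 180
      spec@t0 + (x * cos(th) + y * sin(th)) / spec@speed
    },
    focal = spec@t0 + sqrt((x - spec@origin[1])^2 + (y - spec@origin[2])^2) / spec@speed,
    quadratic = {
      co <- unname(spec@coefficients)
      spec@t0 + co[1] * x^2 + co[2] * y^2 + co[3] * x * y +
        co[4] * x + co[5] * y + co[6]
    })
}

#' Ground-truth velocity vectors of a wavefront
#'
#' Planar: the constant vector speed (cos theta, sin theta). Focal: speed
#' times the unit radial vector from the origin (undefined at the origin
#' itself). Quadratic: the closed form V = (Tx, Ty) / (Tx^2 + Ty^2) of the
#' exact surface gradient.
#'
#' @param spec a [WaveSpec-class].
#' @param positions n x 2 matrix of (x, y) in um.
#' @return n x 2 matrix of (vx, vy) in mm/s.
#' @export
groundTruthVelocity <- function(spec, positions) {
  x <- positions[, 1]; y <- positions[, 2]
  out <- switch(spec@kind,
    planar = {
      th <- spec@direction * pi / 180
      cbind(vx = rep(spec@speed * cos(th), length(x)),
            vy = rep(spec@speed * sin(th), length(x)))
    },
    focal = {
      dx <- x - spec@origin[1]; dy <- y - spec@origin[2]
      r <- sqrt(dx^2 + dy^2)
      if (any(r == 0)) stop("focal ground-truth velocity undefined at the origin")
      cbind(vx = spec@speed * dx / r, vy = spec@speed * dy / r)
    },
    quadratic = {
      co <- unname(spec@coefficients)
      Tx <- 2 * co[1] * x + co[3] * y + co[4]
      Ty <- 2 * co[2] * y + co[3] * x + co[5]
      g2 <- Tx^2 + Ty^2
      cbind(vx = Tx / g2, vy = Ty / g2)
    })
  rownames(out) <- rownames(positions)
  out
}

# Run expr with a temporarily-seeded RNG, restoring global RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic MEA recording with known ground truth
#'
#' Each electrode trace is the sum over beats of the biphasic template
#' shifted to the electrode's ground-truth arrival time, plus (optionally)
#' seeded white Gaussian noise scaled to the clean trace's robust SD. The
#' returned ground truth carries the exact first-beat arrival times and the
#' closed-form velocity vector per electrode, so the whole pipeline can be
#' checked end to end.
#'
#' @param spec a [WaveSpec-class].
#' @param layout an [ElectrodeLayout-class] (default [standardLayout()]).
#' @param samplingRate sampling rate in Hz (default 20000).
#' @param duration recording length in ms; NULL (default) picks the shortest
#'   duration covering every arrival plus the template support.
#' @param beats number of beats (default 1).
#' @param beatPeriod inter-beat interval in ms (default 500).
#' @return list with \code{recording} (an [MEARecording-class]) and
#'   \code{truth} (list: \code{arrivalTimes} named vector, ms, first beat;
#'   \code{velocity} n x 2 matrix, mm/s; \code{spec}).
#' @export
generateRecording <- function(spec, layout = standardLayout(),
                              samplingRate = 20000, duration = NULL,
                              beats = 1L, beatPeriod = 500) {
  stopifnot(is(spec, "WaveSpec"))
  validObject(spec)
  pos <- layout@positions
  arr <- arrivalTime(spec, pos[, 1], pos[, 2])
  names(arr) <- layout@labels
  sup <- templateSupport(spec@template)
  if (any(arr - sup < -1e-9))
    stop("template extends before t = 0; increase spec t0 (need t0 >= ",
         format(sup + spec@t0 - min(arr)), " ms)")
  need <- max(arr) + (beats - 1) * beatPeriod + sup
  if (is.null(duration)) duration <- need + 2 / samplingRate * 1000
  if (duration < need)
    stop("duration ", duration, " ms too short: template extends past the ",
         "recording end (need >= ", format(need), " ms)")
  n <- floor(duration * samplingRate / 1000) + 1L
  tvec <- (seq_len(n) - 1) * 1000 / samplingRate
  samples <- matrix(0, nrow = n, ncol = length(arr),
                    dimnames = list(NULL, layout@labels))
  for (j in seq_along(arr)) {
    v <- numeric(n)
    for (b in seq_len(beats)) {
      tau <- tvec - arr[j] - (b - 1) * beatPeriod
      inSup <- abs(tau) <= sup
      v[inSup] <- v[inSup] + templateWaveform(spec@template, tau[inSup])
    }
    samples[, j] <- v
  }
  if (spec@noiseLevel > 0) {
    sds <- apply(samples, 2, robustSD) * spec@noiseLevel
    noise <- withSeed(spec@seed,
      matrix(stats::rnorm(length(samples)), nrow = n) %*% diag(sds))
    samples <- samples + noise
  }
  rec <- new("MEARecording", samples = samples, samplingRate = samplingRate,
             layout = layout)
  vel <- groundTruthVelocity(spec, pos)
  list(recording = rec,
       truth = list(arrivalTimes = arr, velocity = vel, spec = spec))
}

#' Shift a wave's t0 so the whole template fits in the recording
#'
#' Increases \code{t0} by the smallest amount that keeps every electrode's
#' template (arrival time minus the template support) at or after t = 0.
#' Useful for waves travelling toward the origin, whose earliest arrivals are
#' negative relative to t0.
#'
#' @param spec a [WaveSpec-class].
#' @param layout the [ElectrodeLayout-class] the wave will be sampled on.
#' @return the spec with adjusted \code{t0}.
#' @export
shiftT0ToFit <- function(spec, layout = standardLayout()) {
  pos <- layout@positions
  arr <- arrivalTime(spec, pos[, 1], pos[, 2])
  shortfall <- templateSupport(spec@template) - min(arr)
  if (shortfall > 0) spec@t0 <- spec@t0 + shortfall
  spec
}

#' Serialize ground truth to JSON
#'
#' Writes the simulator's ground truth (arrival times and velocity vectors)
#' next to a recording so command-line runs need no shared state.
#'
#' @param truth the \code{truth} element of [generateRecording()].
#' @param path output JSON file.
#' @return invisibly, \code{path}.
#' @export
writeGroundTruthJSON <- function(truth, path) {
  obj <- list(
    kind = truth$spec@kind,
    t0 = truth$spec@t0,
    noiseLevel = truth$spec@noiseLevel,
    arrivalTimes = as.list(truth$arrivalTimes),
    velocity = apply(truth$velocity, 1, function(v) list(vx = v[1], vy = v[2]),
                     simplify = FALSE))
  if (truth$spec@kind == "planar") {
    obj$speed <- truth$spec@speed
    obj$direction <- truth$spec@direction
  }
  if (truth$spec@kind == "focal") {
    obj$speed <- truth$spec@speed
    obj$origin <- truth$spec@origin
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
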