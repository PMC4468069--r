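#' @include AllClasses.R velocity.R synth.R
NULL

#' Electrode-dropout robustness curve
#'
#' For each requested number of silenced electrodes, repeatedly silences a
#' uniformly random subset (without replacement within a replicate,
#' independent across replicates, seeded), refits the activation surface on
#' the remainder and recomputes the mean conduction velocity. Each estimate
#' is expressed as a percentage of the best estimate, the one using the
#' maximum number of available electrodes (n silenced = 0). Optional
#' activation-time noise (\code{timeNoiseSD}) is added per replicate before
#' fitting, to probe how sparser fits amplify timing error.
#'
#' @param map an [ActivationMap-class] (or named numeric vector of times, ms).
#' @param layout an [ElectrodeLayout-class]; defaults to the map's layout.
#' @param nList numbers of electrodes to silence (default 0, 5, ..., 50).
#' @param reps replicates per n (default 100).
#' @param seed integer RNG seed.
#' @param timeNoiseSD SD (ms) of Gaussian noise added to activation times per
#'   replicate (default 0: noise-free dropout).
#' @return data.frame with columns \code{nSilenced}, \code{rep},
#'   \code{meanCV} (mm/s) and \code{percentOfBest}; attributes \code{seed},
#'   \code{reps} and \code{bestEstimate} (mm/s).
#' @export
dropoutCurve <- function(map, layout = NULL, nList = seq(0, 50, by = 5),
                         reps = 100L, seed = 1L, timeNoiseSD = 0) {
  if (is(map, "ActivationMap")) {
    if (is.null(layout)) layout <- map@layout
    times <- map@times
  } else {
    times <- map
    if (is.null(layout)) stop("layout required when using raw times")
  }
  times <- times[!is.na(times)]
  nAvail <- length(times)
  if (max(nList) > nAvail - 6L)
    stop("cannot silence ", max(nList), " of ", nAvail,
         " electrodes: at least 6 must remain")
  if (reps < 1L) stop("reps must be >= 1")
  best <- meanConductionVelocity(
    velocityVectors(fitActivationSurface(times, layout), layout))
  out <- withSeed(seed, {
    rows <- vector("list", length(nList) * reps)
    k <- 0L
    for (n in nList) {
      for (r in seq_len(reps)) {
        tt <- times
        if (timeNoiseSD > 0) tt <- tt + stats::rnorm(nAvail, sd = timeNoiseSD)
        drop <- if (n > 0) sample(names(tt), n) else character(0)
        keep <- tt[setdiff(names(tt), drop)]
        cv <- meanConductionVelocity(
          velocityVectors(fitActivationSurface(keep, layout), layout))
        bestRep <- if (timeNoiseSD > 0)
          meanConductionVelocity(
            velocityVectors(fitActivationSurface(tt, layout), layout))
        else best
        k <- k + 1L
        rows[[k]] <- data.frame(nSilenced = n, rep = r, meanCV = cv,
                                percentOfBest = 100 * cv / bestRep)
      }
    }
    do.call(rbind, rows)
  })
  attr(out, "seed") <- seed
  attr(out, "reps") <- reps
  attr(out, "bestEstimate") <- best
  out
}

#' Add seeded white Gaussian noise to a recording
#'
#' Noise SD per electrode is \code{level} times the robust SD (1.4826 x
#' median absolute deviation, plain SD for flat-baseline traces) of that
#' electrode's clean trace, so the level is a scale-free multiplier. Level 0
#' returns the recording unchanged. Any previously attached smoothed traces
#' are dropped (they no longer describe the samples).
#'
#' @param recording an [MEARecording-class].
#' @param level noise level in robust-SD multiples (>= 0).
#' @param seed integer RNG seed; the same seed reproduces the same noise.
#' @return a noisy [MEARecording-class].
#' @export
addWhiteNoise <- function(recording, level, seed = 1L) {
  stopifnot(is(recording, "MEARecording"))
  if (!is.finite(level) || level < 0) stop("noise level must be >= 0")
  if (level == 0) return(recording)
  sds <- apply(recording@samples, 2, robustSD) * level
  noise <- withSeed(seed,
    matrix(stats::rnorm(length(recording@samples)),
           nrow = nrow(recording@samples)) %*% diag(sds))
  recording@samples <- recording@samples + noise
  recording@smoothed <- matrix(numeric(0), 0, 0)
  recording
}

#' White-noise robustness curve
#'
#' For each noise level and replicate: add seeded white noise, re-smooth,
#' re-detect activation times, refit the surface, and record the mean
#' absolute change in activation times and the absolute change in mean
#' conduction velocity relative to the clean (level 0) analysis. Per-level
#' mean and SEM (SD / sqrt(reps)) are aggregated.
#'
#' @param recording a clean [MEARecording-class].
#' @param levels noise levels in robust-SD multiples; must include 0.
#' @param window the [AnalysisWindow-class] used for detection.
#' @param reps replicates per level (default 5).
#' @param seed integer RNG seed.
#' @param config [SmoothingConfig-class] for re-smoothing.
#' @param mask a [SilenceMask-class].
#' @return list with \code{perRep} (data.frame: level, rep, timeErrMs,
#'   cvErrMmS) and \code{summary} (data.frame: level, meanTimeErr,
#'   semTimeErr, meanCVErr, semCVErr); attribute \code{seed}.
#' @export
noiseCurve <- function(recording, levels = c(0, 0.5, 1, 2, 4), window,
                       reps = 5L, seed = 1L, config = smoothingConfig(),
                       mask = new("SilenceMask")) {
  if (!0 %in% levels) stop("levels must include 0 (the clean reference)")
  stopifnot(is(window, "AnalysisWindow"))
  layout <- recording@layout
  cleanMap <- detectActivationMap(recording, window, mask, config)
  cleanTimes <- activationTimes(cleanMap)
  cleanCV <- meanConductionVelocity(
    velocityVectors(fitActivationSurface(cleanMap), layout, mask))
  rows <- vector("list", length(levels) * reps)
  k <- 0L
  for (li in seq_along(levels)) {
    lv <- levels[li]
    for (r in seq_len(reps)) {
      repSeed <- seed + 1000L * li + r
      noisy <- addWhiteNoise(recording, lv, repSeed)
      m <- detectActivationMap(noisy, window, mask, config)
      tErr <- mean(abs(activationTimes(m) - cleanTimes), na.rm = TRUE)
      cv <- meanConductionVelocity(
        velocityVectors(fitActivationSurface(m), layout, mask))
      k <- k + 1L
      rows[[k]] <- data.frame(level = lv, rep = r, timeErrMs = tErr,
                              cvErrMmS = abs(cv - cleanCV))
    }
  }
  perRep <- do.call(rbind, rows)
  agg <- lapply(split(perRep, perRep$level), function(d)
    data.frame(level = d$level[1],
               meanTimeErr = mean(d$timeErrMs),
               semTimeErr = stats::sd(d$timeErrMs) / sqrt(nrow(d)),
               meanCVErr = mean(d$cvErrMmS),
               semCVErr = stats::sd(d$cvErrMmS) / sqrt(nrow(d))))
  summary <- do.call(rbind, agg[order(as.numeric(names(agg)))])
  rownames(summary) <- NULL
  out <- list(perRep = perRep, summary = summary)
  attr(out, "seed") <- seed
  out
}
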