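#' @include trace-onset.R
NULL

#' Construct a synthetic-trace generator specification
#'
#' Describes a population of synthetic single-cell degradation traces
#' emulating time-lapse GFP data: each cell shows a flat plateau until its
#' onset (the population onset plus Gaussian per-cell jitter), then either an
#' exponential decline or the rescaled total-substrate curve of a simulated
#' \linkS4class{TimeCourse}; i.i.d. Gaussian noise (standard deviation
#' \code{noiseSd * plateau}) is added to every sample.  Defaults mirror a
#' one-hour imaging session sampled every 30 s.
#'
#' @param plateau pre-onset level, arbitrary units
#' @param onset population onset time, s
#' @param declineShape \code{"exponential"} or \code{"model"}
#' @param declineRate exponential decline rate, /s
#' @param model a \linkS4class{TimeCourse} (required for
#'   \code{declineShape = "model"})
#' @param noiseSd noise standard deviation as a fraction of the plateau
#' @param samplingInterval sampling interval, s
#' @param duration trace duration, s
#' @param nCells number of cells in the population
#' @param onsetJitterSd per-cell onset jitter standard deviation, s
#' @param seed integer master seed; every trace is a deterministic function
#'   of (seed, cell index)
#' @return a validated \linkS4class{TraceSpec}
#' @export
TraceSpec <- function(plateau = 1000, onset = 600,
                      declineShape = c("exponential", "model"),
                      declineRate = 0.005, model = NULL, noiseSd = 0.02,
                      samplingInterval = 30, duration = 3600, nCells = 30L,
                      onsetJitterSd = 30, seed = 1L) {
  new("TraceSpec", plateau = plateau, onset = onset,
      declineShape = match.arg(declineShape), declineRate = declineRate,
      model = model, noiseSd = noiseSd, samplingInterval = samplingInterval,
      duration = duration, nCells = as.integer(nCells),
      onsetJitterSd = onsetJitterSd, seed = as.integer(seed))
}

setMethod("show", "TraceSpec", function(object) {
  cat(sprintf("TraceSpec: %d cells, plateau %g a.u., onset %g +/- %g s\n",
              object@nCells, object@plateau, object@onset,
              object@onsetJitterSd))
  cat(sprintf("  decline: %s%s; noise sd %g x plateau; %g s sampling over %g s; seed %d\n",
              object@declineShape,
              if (object@declineShape == "exponential")
                sprintf(" (rate %g /s)", object@declineRate) else "",
              object@noiseSd, object@samplingInterval, object@duration,
              object@seed))
})

## per-cell RNG stream: deterministic in (seed, cellIndex), independent of
## the order in which cells are generated
.cellSeed <- function(seed, cellIndex) {
  (as.integer(seed) * 20011L + as.integer(cellIndex) * 613L) %% 2147483629L
}

.declineValue <- function(spec, tAfter) {
  ## normalized decline curve, value 1 at tAfter = 0
  if (spec@declineShape == "exponential") {
    exp(-spec@declineRate * tAfter)
  } else {
    tc <- spec@model
    tot <- totalSubstrate(tc)
    stats::approx(tc@times, tot / tot[1], xout = pmin(tAfter, max(tc@times)),
                  rule = 2)$y
  }
}

#' Generate one synthetic fluorescence trace
#'
#' @param spec a \linkS4class{TraceSpec}
#' @param cellIndex positive integer; together with \code{spec@seed} it
#'   determines the trace completely
#' @return a \linkS4class{FluorescenceTrace} carrying its true onset
#' @examples
#' tr <- generateTrace(TraceSpec(seed = 7), 1)
#' tr
#' @export
generateTrace <- function(spec, cellIndex) {
  stopifnot(is(spec, "TraceSpec"), cellIndex >= 1)
  times <- seq(0, spec@duration, by = spec@samplingInterval)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.cellSeed(spec@seed, cellIndex))
  onset <- spec@onset +
    if (spec@onsetJitterSd > 0) stats::rnorm(1, 0, spec@onsetJitterSd) else 0
  onset <- max(onset, 0)
  clean <- ifelse(times < onset, 1, .declineValue(spec, pmax(times - onset, 0)))
  noise <- if (spec@noiseSd > 0)
    stats::rnorm(length(times), 0, spec@noiseSd) else 0
  intensities <- pmax(spec@plateau * (clean + noise), 0)
  FluorescenceTrace(times, intensities,
                    cellId = sprintf("cell_%03d", cellIndex),
                    trueOnset = onset)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic trace population
#'
#' @param spec a \linkS4class{TraceSpec}
#' @return list of \code{spec@nCells} \linkS4class{FluorescenceTrace}
#' @export
generateTraces <- function(spec) {
  lapply(seq_len(spec@nCells), function(i) generateTrace(spec, i))
}

#' Generate traces from a simulated model time course
#'
#' End-to-end bridge between the kinetic model and the trace pipeline: the
#' total-substrate curve of a model run is rescaled to the plateau level,
#' resampled on the imaging grid and degraded with additive noise, so one can
#' simulate, add measurement noise, detect onsets and compare the calls with
#' the model's own timing metrics.  The model curve is used from t = 0 (its
#' plateau is part of the curve), so \code{spec@onset} and the jitter are
#' ignored; the recorded \code{trueOnset} is the model's 95%-crossing time
#' (T95), \code{NA} if the model never crosses.
#'
#' @param params a \linkS4class{RateParams}
#' @param spec a \linkS4class{TraceSpec} providing plateau, noise, sampling
#'   and population size
#' @param horizon model horizon, s (default the trace duration)
#' @return list of \linkS4class{FluorescenceTrace}
#' @export
generateModelPopulation <- function(params, spec,
                                    horizon = spec@duration) {
  stopifnot(is(params, "RateParams"), is(spec, "TraceSpec"))
  tc <- simulateDegradation(params, horizon = horizon)
  tot <- totalSubstrate(tc)
  t95 <- crossingTime(tc@times, tot, 0.95)
  times <- seq(0, spec@duration, by = spec@samplingInterval)
  clean <- stats::approx(tc@times, tot / tot[1],
                         xout = pmin(times, max(tc@times)), rule = 2)$y
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  lapply(seq_len(spec@nCells), function(i) {
    set.seed(.cellSeed(spec@seed, i))
    noise <- if (spec@noiseSd > 0)
      stats::rnorm(length(times), 0, spec@noiseSd) else 0
    FluorescenceTrace(times, pmax(spec@plateau * (clean + noise), 0),
                      cellId = sprintf("cell_%03d", i),
                      trueOnset = if (is.na(t95)) NA_real_ else t95)
  })
}
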