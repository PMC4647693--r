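#' @import methods
NULL

.APC_MODES <- c("linear", "constant")
.DEUB_VARIANTS <- c("none", "all", "free_only", "bound_only", "mono_only")
.SCENARIOS <- c("affinity", "catalytic", "custom")
.MAX_UB <- 4L

.checkNonNegScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    return(sprintf("'%s' must be a single finite non-negative number", name))
  NULL
}

#' One-substrate kinetic parameters
#'
#' Rate constants and initial conditions for the one-substrate multi-step
#' ubiquitination model.  A substrate S binds free APC/C-Cdc20 (A) with rate
#' constant \code{ka} (per nM per second), dissociates with \code{kd} (per
#' second) and, while bound, gains one ubiquitin at a time with rate constant
#' \code{kc} (per second).  Once a substrate carries \code{maxUb} (four)
#' ubiquitins it is degraded by the proteasome with rate constant \code{e},
#' whether bound or free.  APC/C-Cdc20 either accumulates linearly at
#' \code{pA} nM/s from zero (\code{apcMode = "linear"}) or is present at a
#' constant level \code{Aconst} nM (\code{apcMode = "constant"}).
#' Deubiquitination, when enabled, removes one ubiquitin at rate \code{kdub}
#' from the species selected by \code{deubVariant}.
#'
#' @slot ka association rate constant, /(nM s)
#' @slot kd dissociation rate constant, /s
#' @slot kc ubiquitin-transfer rate constant, /s
#' @slot e proteasomal degradation rate constant, /s
#' @slot pA APC/C-Cdc20 accumulation rate, nM/s (linear mode)
#' @slot Aconst constant APC/C-Cdc20 level, nM (constant mode)
#' @slot S0 initial free unmodified substrate, nM
#' @slot apcMode \code{"linear"} or \code{"constant"}
#' @slot deubVariant one of \code{"none"}, \code{"all"}, \code{"free_only"},
#'   \code{"bound_only"}, \code{"mono_only"}
#' @slot kdub deubiquitination rate constant, /s (ignored when
#'   \code{deubVariant = "none"})
#' @slot maxUb maximum ubiquitin count, fixed at 4
#' @seealso [RateParams()], [simulateDegradation()]
#' @name RateParams-class
#' @aliases RateParams-class
#' @exportClass RateParams
setClass("RateParams",
  representation(
    ka = "numeric", kd = "numeric", kc = "numeric", e = "numeric",
    pA = "numeric", Aconst = "numeric", S0 = "numeric",
    apcMode = "character", deubVariant = "character", kdub = "numeric",
    maxUb = "integer"
  ),
  prototype(
    ka = 0.01, kd = 1, kc = 1, e = 1000, pA = 0.06, Aconst = 100,
    S0 = 200, apcMode = "linear", deubVariant = "none", kdub = 0,
    maxUb = .MAX_UB
  )
)

setValidity("RateParams", function(object) {
  msgs <- c(
    .checkNonNegScalar(object@ka, "ka"), .checkNonNegScalar(object@kd, "kd"),
    .checkNonNegScalar(object@kc, "kc"), .checkNonNegScalar(object@e, "e"),
    .checkNonNegScalar(object@pA, "pA"),
    .checkNonNegScalar(object@Aconst, "Aconst"),
    .checkNonNegScalar(object@S0, "S0"),
    .checkNonNegScalar(object@kdub, "kdub")
  )
  if (!object@apcMode %in% .APC_MODES)
    msgs <- c(msgs, sprintf("apcMode must be one of: %s",
                            paste(.APC_MODES, collapse = ", ")))
  if (!object@deubVariant %in% .DEUB_VARIANTS)
    msgs <- c(msgs, sprintf("deubVariant must be one of: %s",
                            paste(.DEUB_VARIANTS, collapse = ", ")))
  if (!identical(object@maxUb, .MAX_UB))
    msgs <- c(msgs, "maxUb is fixed at 4")
  if (length(msgs)) msgs else TRUE
})

#' Two-substrate kinetic parameters
#'
#' Parameters for the two-substrate model in which substrates S and C compete
#' for a single pool of APC/C-Cdc20.  Both substrates bind with the shared
#' \code{ka} and are degraded with the shared \code{e}; each has its own
#' dissociation and catalysis rate constants.  The named scenarios encode the
#' two ways C can be the better substrate: \code{"affinity"} sets
#' \code{kdC = kdS / 10} (ten-fold tighter binding), \code{"catalytic"} sets
#' \code{kcC = 10 * kcS} (ten-fold faster ubiquitin transfer); all other
#' parameters are identical between the substrates.
#'
#' @slot ka shared association rate constant, /(nM s)
#' @slot e shared proteasomal degradation rate constant, /s
#' @slot pA APC/C-Cdc20 accumulation rate, nM/s
#' @slot Aconst constant APC/C-Cdc20 level, nM
#' @slot apcMode \code{"linear"} or \code{"constant"}
#' @slot kdS,kcS,S0 dissociation rate, catalysis rate and initial amount of S
#' @slot kdC,kcC,C0 dissociation rate, catalysis rate and initial amount of C
#' @slot scenario \code{"affinity"}, \code{"catalytic"} or \code{"custom"}
#' @seealso [TwoSubstrateParams()], [runCompetition()]
#' @name TwoSubstrateParams-class
#' @aliases TwoSubstrateParams-class
#' @exportClass TwoSubstrateParams
setClass("TwoSubstrateParams",
  representation(
    ka = "numeric", e = "numeric", pA = "numeric", Aconst = "numeric",
    apcMode = "character",
    kdS = "numeric", kcS = "numeric", S0 = "numeric",
    kdC = "numeric", kcC = "numeric", C0 = "numeric",
    scenario = "character"
  ),
  prototype(
    ka = 0.01, e = 1000, pA = 0.06, Aconst = 100, apcMode = "linear",
    kdS = 1, kcS = 1, S0 = 200, kdC = 0.1, kcC = 1, C0 = 200,
    scenario = "affinity"
  )
)

setValidity("TwoSubstrateParams", function(object) {
  msgs <- c(
    .checkNonNegScalar(object@ka, "ka"), .checkNonNegScalar(object@e, "e"),
    .checkNonNegScalar(object@pA, "pA"),
    .checkNonNegScalar(object@Aconst, "Aconst"),
    .checkNonNegScalar(object@kdS, "kdS"), .checkNonNegScalar(object@kcS, "kcS"),
    .checkNonNegScalar(object@S0, "S0"),
    .checkNonNegScalar(object@kdC, "kdC"), .checkNonNegScalar(object@kcC, "kcC"),
    .checkNonNegScalar(object@C0, "C0")
  )
  if (!object@apcMode %in% .APC_MODES)
    msgs <- c(msgs, "apcMode must be 'linear' or 'constant'")
  if (!object@scenario %in% .SCENARIOS)
    msgs <- c(msgs, sprintf("scenario must be one of: %s",
                            paste(.SCENARIOS, collapse = ", ")))
  tol <- 1e-12
  if (object@scenario == "affinity" &&
      (abs(object@kdC - object@kdS / 10) > tol * max(1, object@kdS) ||
       abs(object@kcC - object@kcS) > tol * max(1, object@kcS)))
    msgs <- c(msgs, "affinity scenario requires kdC = kdS/10 and kcC = kcS")
  if (object@scenario == "catalytic" &&
      (abs(object@kcC - 10 * object@kcS) > tol * max(1, object@kcS) ||
       abs(object@kdC - object@kdS) > tol * max(1, object@kdS)))
    msgs <- c(msgs, "catalytic scenario requires kcC = 10*kcS and kdC = kdS")
  if (length(msgs)) msgs else TRUE
})

#' Simulated concentration time course
#'
#' Concentrations (nM) of every molecular species on a uniform output time
#' grid, together with the parameter object that produced them.  For the
#' one-substrate model the species are \code{A}, \code{S0..S4} (free
#' substrate with 0--4 ubiquitins) and \code{AS0..AS4} (APC/C-bound
#' substrate); the two-substrate model adds \code{C0..C4} and \code{AC0..AC4}.
#'
#' @slot times seconds, strictly increasing, starting at 0
#' @slot conc numeric matrix, one row per time point, one named column per
#'   species
#' @slot params the \linkS4class{RateParams} or
#'   \linkS4class{TwoSubstrateParams} used
#' @slot solver character, integration method used
#' @seealso [simulateDegradation()], [totalSubstrate()], [timingMetrics()]
#' @name TimeCourse-class
#' @aliases TimeCourse-class
#' @exportClass TimeCourse
setClass("TimeCourse",
  representation(times = "numeric", conc = "matrix", params = "ANY",
                 solver = "character"),
  prototype(times = numeric(0),
            conc = matrix(numeric(0), 0, 0), solver = "lsoda")
)

setValidity("TimeCourse", function(object) {
  msgs <- character(0)
  if (length(object@times) != nrow(object@conc))
    msgs <- c(msgs, "length(times) must equal nrow(conc)")
  if (length(object@times)) {
    if (object@times[1] != 0)
      msgs <- c(msgs, "times must start at 0")
    if (any(diff(object@times) <= 0))
      msgs <- c(msgs, "times must be strictly increasing")
  }
  if (is.null(colnames(object@conc)))
    msgs <- c(msgs, "conc must have species column names")
  if (length(object@conc) && min(object@conc) < -1e-9)
    msgs <- c(msgs, "concentrations must be non-negative (beyond clip tolerance)")
  if (length(msgs)) msgs else TRUE
})

#' Degradation-timing metrics
#'
#' Summary of one substrate's degradation curve: \code{T95} and \code{T50}
#' are the times (s) at which total substrate first falls to 95% and 50% of
#' its initial amount, located by linear interpolation between output samples;
#' \code{Td = T50 - T95} measures the degradation rate (the smaller, the
#' faster).  A crossing that does not occur within the simulated horizon is
#' censored: its value is \code{NA} and the corresponding flag in
#' \code{censored} is \code{TRUE}.  \code{maxOccupancy} is the maximum over
#' time of the fraction of total APC/C-Cdc20 bound to this substrate.
#'
#' @slot t95,t50,td seconds, \code{NA} when censored
#' @slot maxOccupancy fraction in [0, 1], \code{NA} if no APC/C ever present
#' @slot censored named logical vector with elements \code{t95}, \code{t50},
#'   \code{td}
#' @slot substrate label of the substrate summarised ("S" or "C")
#' @seealso [timingMetrics()]
#' @name TimingMetrics-class
#' @aliases TimingMetrics-class
#' @exportClass TimingMetrics
setClass("TimingMetrics",
  representation(t95 = "numeric", t50 = "numeric", td = "numeric",
                 maxOccupancy = "numeric", censored = "logical",
                 substrate = "character"),
  prototype(t95 = NA_real_, t50 = NA_real_, td = NA_real_,
            maxOccupancy = NA_real_,
            censored = c(t95 = TRUE, t50 = TRUE, td = TRUE),
            substrate = "S")
)

setValidity("TimingMetrics", function(object) {
  msgs <- character(0)
  if (!all(c("t95", "t50", "td") %in% names(object@censored)))
    msgs <- c(msgs, "censored must have elements t95, t50, td")
  if (!is.na(object@t95) && !is.na(object@t50)) {
    if (object@t50 <= object@t95)
      msgs <- c(msgs, "t50 must exceed t95 when both are defined")
  }
  if (!is.na(object@maxOccupancy) &&
      (object@maxOccupancy < 0 || object@maxOccupancy > 1 + 1e-9))
    msgs <- c(msgs, "maxOccupancy must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Log-spaced parameter grid
#'
#' The default grid places 25 values of both \code{kc} and \code{kd}
#' log-spaced on [1e-3, 1e3] /s (neighbour ratio 10^(1/4), about 1.8) and 6
#' values of \code{ka} log-spaced on [1e-4, 10] /(nM s) (neighbour ratio 10).
#'
#' @slot kc,kd,ka numeric vectors of grid values
#' @seealso [buildLogGrid()], [scanGrid()]
#' @name LogGrid-class
#' @aliases LogGrid-class
#' @exportClass LogGrid
setClass("LogGrid",
  representation(kc = "numeric", kd = "numeric", ka = "numeric"))

setValidity("LogGrid", function(object) {
  msgs <- character(0)
  for (nm in c("kc", "kd", "ka")) {
    v <- slot(object, nm)
    if (!length(v) || any(!is.finite(v)) || any(v <= 0) ||
        any(diff(v) <= 0))
      msgs <- c(msgs, sprintf("%s values must be positive and increasing", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' Parameter-scan result
#'
#' One record per grid cell with the timing metrics (and, for two-substrate
#' scans, the competition metrics) evaluated there, plus the fixed parameters
#' and solver settings used, for provenance.
#'
#' @slot grid the \linkS4class{LogGrid} scanned
#' @slot table data.frame, one row per grid cell
#' @slot fixed named list of fixed parameters (ka, pA/Aconst, S0, e, mode, ...)
#' @slot scanType "one_substrate" or "two_substrate"
#' @seealso [scanGrid()], [competitionScan()], [overlapMask()]
#' @name ScanResult-class
#' @aliases ScanResult-class
#' @exportClass ScanResult
setClass("ScanResult",
  representation(grid = "LogGrid", table = "data.frame", fixed = "list",
                 scanType = "character"),
  prototype(scanType = "one_substrate"))

setValidity("ScanResult", function(object) {
  msgs <- character(0)
  if (!all(c("kc", "kd") %in% names(object@table)))
    msgs <- c(msgs, "table must contain kc and kd columns")
  if (nrow(object@table) &&
      nrow(object@table) != length(object@grid@kc) * length(object@grid@kd))
    msgs <- c(msgs, "table must have one row per (kc, kd) grid cell")
  if (length(msgs)) msgs else TRUE
})

#' Processivity-model result
#'
#' Outcome of the single-binding-event model: starting from substrate-bound
#' enzyme with no ubiquitins (AS0) as the sole species, each complex either
#' gains one ubiquitin (rate \code{kc}) or dissociates (rate \code{kd});
#' substrates with four ubiquitins can only dissociate.  At steady state all
#' substrate has dissociated and \code{fractions[i + 1]} is the fraction of
#' substrate that ended with \code{i} ubiquitins (i = 0..4);
#' \code{average} is the mean number of ubiquitins per substrate molecule.
#'
#' @slot fractions numeric length 5, terminal fractions for 0..4 ubiquitins
#' @slot average mean ubiquitins per substrate, in [0, 4]
#' @slot kc,kd the rate constants used (/s)
#' @slot note character; flags the degenerate kd = 0 case where substrate
#'   never dissociates
#' @seealso [simulateProcessivity()], [processivityClosedForm()]
#' @name ProcessivityResult-class
#' @aliases ProcessivityResult-class
#' @exportClass ProcessivityResult
setClass("ProcessivityResult",
  representation(fractions = "numeric", average = "numeric",
                 kc = "numeric", kd = "numeric", note = "character"),
  prototype(note = ""))

setValidity("ProcessivityResult", function(object) {
  msgs <- character(0)
  if (length(object@fractions) != 5L)
    msgs <- c(msgs, "fractions must have length 5 (0..4 ubiquitins)")
  else if (abs(sum(object@fractions) - 1) > 1e-6)
    msgs <- c(msgs, "terminal fractions must sum to 1 within 1e-6")
  if (object@average < -1e-9 || object@average > 4 + 1e-9)
    msgs <- c(msgs, "average ubiquitins must lie in [0, 4]")
  if (length(msgs)) msgs else TRUE
})

#' Single-cell fluorescence trace
#'
#' A uniformly sampled intensity time series for one cell, as produced by
#' time-lapse imaging of a GFP-tagged substrate (default 30 s sampling over
#' about one hour).  Synthetic traces carry their ground-truth onset time in
#' \code{trueOnset} so detector accuracy can be scored.
#'
#' @slot cellId character identifier
#' @slot times seconds, uniformly spaced within 1%
#' @slot intensities arbitrary units, non-negative
#' @slot trueOnset seconds, \code{NA} for real traces
#' @seealso [generateTrace()], [detectOnset()]
#' @name FluorescenceTrace-class
#' @aliases FluorescenceTrace-class
#' @exportClass FluorescenceTrace
setClass("FluorescenceTrace",
  representation(cellId = "character", times = "numeric",
                 intensities = "numeric", trueOnset = "numeric"),
  prototype(cellId = "cell", trueOnset = NA_real_))

setValidity("FluorescenceTrace", function(object) {
  msgs <- character(0)
  n <- length(object@times)
  if (n < 10L)
    msgs <- c(msgs, "a trace needs at least 10 samples")
  if (length(object@intensities) != n)
    msgs <- c(msgs, "times and intensities must have the same length")
  if (any(!is.finite(object@intensities)))
    msgs <- c(msgs, "intensities must be finite")
  if (n >= 2L) {
    dt <- diff(object@times)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 0.01 * mean(dt))
      msgs <- c(msgs, "times must be uniformly spaced within 1%")
  }
  if (length(msgs)) msgs else TRUE
})

#' Degradation-onset call
#'
#' Result of onset detection on one trace.  \code{argminTime} is the time of
#' the most negative smoothed first derivative (the fastest-declining point);
#' \code{onsetTime} is the latest earlier time at which the derivative was
#' still close to zero (within \code{threshold} of the minimum's magnitude).
#' When the trace never declines, \code{found} is \code{FALSE}; when the
#' decline starts at the first sample so no near-zero point precedes the
#' minimum, the onset is reported at the first sample with
#' \code{flagged = TRUE}.
#'
#' @slot cellId character
#' @slot onsetTime seconds, \code{NA} when not found
#' @slot argminTime seconds, \code{NA} when not found
#' @slot threshold the zero-fraction used
#' @slot found,flagged logicals
#' @seealso [detectOnset()]
#' @name OnsetCall-class
#' @aliases OnsetCall-class
#' @exportClass OnsetCall
setClass("OnsetCall",
  representation(cellId = "character", onsetTime = "numeric",
                 argminTime = "numeric", threshold = "numeric",
                 found = "logical", flagged = "logical"),
  prototype(cellId = "cell", onsetTime = NA_real_, argminTime = NA_real_,
            threshold = 0.1, found = FALSE, flagged = FALSE))

setValidity("OnsetCall", function(object) {
  if (isTRUE(object@found) && !is.na(object@onsetTime) &&
      !is.na(object@argminTime) && object@onsetTime > object@argminTime)
    return("onsetTime must not exceed argminTime")
  TRUE
})

#' Synthetic-trace generator specification
#'
#' Describes a population of synthetic single-cell degradation traces: a flat
#' plateau until a per-cell onset time (population onset plus Gaussian
#' jitter), then either an exponential decline or the rescaled
#' total-substrate curve of a model \linkS4class{TimeCourse}, with additive
#' i.i.d. Gaussian noise, sampled every \code{samplingInterval} seconds.
#'
#' @slot plateau pre-onset level, arbitrary units
#' @slot onset population onset time, s
#' @slot declineShape "exponential" or "model"
#' @slot declineRate exponential decline rate, /s (exponential shape)
#' @slot model \linkS4class{TimeCourse} or \code{NULL} (model shape)
#' @slot noiseSd noise standard deviation as a fraction of the plateau
#' @slot samplingInterval s (default 30)
#' @slot duration s (default 3600)
#' @slot nCells number of cells
#' @slot onsetJitterSd per-cell onset jitter standard deviation, s
#' @slot seed integer master seed; all randomness derives from it
#' @seealso [TraceSpec()], [generateTrace()], [generateModelPopulation()]
#' @name TraceSpec-class
#' @aliases TraceSpec-class
#' @exportClass TraceSpec
setClass("TraceSpec",
  representation(plateau = "numeric", onset = "numeric",
                 declineShape = "character", declineRate = "numeric",
                 model = "ANY", noiseSd = "numeric",
                 samplingInterval = "numeric", duration = "numeric",
                 nCells = "integer", onsetJitterSd = "numeric",
                 seed = "integer"),
  prototype(plateau = 1000, onset = 600, declineShape = "exponential",
            declineRate = 0.005, model = NULL, noiseSd = 0.02,
            samplingInterval = 30, duration = 3600, nCells = 30L,
            onsetJitterSd = 30, seed = 1L))

setValidity("TraceSpec", function(object) {
  msgs <- c(
    .checkNonNegScalar(object@plateau, "plateau"),
    .checkNonNegScalar(object@onset, "onset"),
    .checkNonNegScalar(object@noiseSd, "noiseSd"),
    .checkNonNegScalar(object@onsetJitterSd, "onsetJitterSd")
  )
  if (!object@declineShape %in% c("exponential", "model"))
    msgs <- c(msgs, "declineShape must be 'exponential' or 'model'")
  if (object@declineShape == "exponential" &&
      (!is.finite(object@declineRate) || object@declineRate <= 0))
    msgs <- c(msgs, "declineRate must be positive")
  if (object@declineShape == "model" && !is(object@model, "TimeCourse"))
    msgs <- c(msgs, "model decline requires a TimeCourse in @model")
  if (object@samplingInterval <= 0 || object@duration <= 0)
    msgs <- c(msgs, "samplingInterval and duration must be positive")
  if (object@onset + 5 * object@samplingInterval >= object@duration)
    msgs <- c(msgs, "onset + 5 samples must precede the end of the trace")
  if (object@nCells < 1L)
    msgs <- c(msgs, "nCells must be at least 1")
  if (length(msgs)) msgs else TRUE
})
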