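#' @include timing-metrics.R
NULL

#' Construct two-substrate kinetic parameters
#'
#' Builds parameters for two substrates, S and C, competing for one
#' APC/C-Cdc20 pool.  In the \code{"affinity"} scenario C binds ten-fold more
#' tightly (\code{kdC = kdS/10}, \code{kcC = kcS}); in the \code{"catalytic"}
#' scenario C is ubiquitinated ten-fold faster (\code{kcC = 10*kcS},
#' \code{kdC = kdS}).  With \code{scenario = "custom"} the C parameters are
#' taken as given.  Both substrates start at the same concentration
#' (200 nM each by default) with no production.
#'
#' @param kdS,kcS dissociation and catalysis rate constants of S, /s
#' @param scenario \code{"affinity"}, \code{"catalytic"} or \code{"custom"}
#' @param ka shared association rate constant, /(nM s)
#' @param e shared proteasomal degradation rate constant, /s
#' @param pA APC/C accumulation rate, nM/s (linear mode)
#' @param Aconst constant APC/C level, nM (constant mode)
#' @param apcMode \code{"linear"} or \code{"constant"}
#' @param S0,C0 initial substrate amounts, nM
#' @param kdC,kcC C rate constants; ignored unless \code{scenario = "custom"}
#' @return a validated \linkS4class{TwoSubstrateParams}
#' @examples
#' TwoSubstrateParams(kdS = 1, kcS = 0.1, scenario = "catalytic")
#' @export
TwoSubstrateParams <- function(kdS = 1, kcS = 1,
                               scenario = c("affinity", "catalytic", "custom"),
                               ka = 0.01, e = 1000, pA = 0.06, Aconst = 100,
                               apcMode = c("linear", "constant"),
                               S0 = 200, C0 = 200,
                               kdC = kdS, kcC = kcS) {
  scenario <- match.arg(scenario)
  if (scenario == "affinity") { kdC <- kdS / 10; kcC <- kcS }
  if (scenario == "catalytic") { kcC <- 10 * kcS; kdC <- kdS }
  new("TwoSubstrateParams", ka = ka, e = e, pA = pA, Aconst = Aconst,
      apcMode = match.arg(apcMode), kdS = kdS, kcS = kcS, S0 = S0,
      kdC = kdC, kcC = kcC, C0 = C0, scenario = scenario)
}

setMethod("show", "TwoSubstrateParams", function(object) {
  cat(sprintf("TwoSubstrateParams (%s scenario)\n", object@scenario))
  cat(sprintf("  shared: ka = %g /(nM s), e = %g /s, APC/C input: %s\n",
              object@ka, object@e,
              if (object@apcMode == "linear")
                sprintf("linear at %g nM/s", object@pA)
              else sprintf("constant %g nM", object@Aconst)))
  cat(sprintf("  S: kd = %g /s, kc = %g /s, S0 = %g nM\n",
              object@kdS, object@kcS, object@S0))
  cat(sprintf("  C: kd = %g /s, kc = %g /s, C0 = %g nM\n",
              object@kdC, object@kcC, object@C0))
})

#' One-substrate reduction of a two-substrate parameter set
#'
#' The S-only model with the same shared parameters and the kinetics of S,
#' used as the baseline when quantifying the effect of competition.
#'
#' @param params a \linkS4class{TwoSubstrateParams}
#' @return a \linkS4class{RateParams} for substrate S alone
#' @export
soloParams <- function(params) {
  stopifnot(is(params, "TwoSubstrateParams"))
  RateParams(ka = params@ka, kd = params@kdS, kc = params@kcS, e = params@e,
             pA = params@pA, Aconst = params@Aconst, S0 = params@S0,
             apcMode = params@apcMode)
}

.ratioOrNA <- function(num, den) {
  if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
}

#' Run a two-substrate competition experiment
#'
#' Simulates the two-substrate system, the matching one-substrate (S alone)
#' baseline, and summarises the competition:
#' \describe{
#'   \item{relOnsetDifference}{(T95_S - T95_C) / T95_C, the relative
#'     difference in degradation onset between the later substrate S and the
#'     better substrate C.}
#'   \item{tdRatio}{Td_C / Td_S; values below 1 mean C degrades faster.}
#'   \item{competitionEffect}{(T95_S in the two-substrate system - T95_S
#'     alone) / T95_S alone: the relative onset delay that adding C imposes
#'     on S.  Non-negative: a competitor can only withdraw APC/C from S.}
#' }
#' All denominators are the C (or S-alone) baseline values.  Any metric whose
#' ingredients are censored is itself \code{NA}, never fabricated.
#'
#' @param params a \linkS4class{TwoSubstrateParams}
#' @param horizon simulated time, s
#' @param outputGrid output sampling interval, s
#' @return a list with elements \code{timeCourse} (two-substrate
#'   \linkS4class{TimeCourse}), \code{soloTimeCourse},
#'   \code{metricsS}, \code{metricsC} (\linkS4class{TimingMetrics}), and
#'   \code{competition} (named numeric vector of the scalar metrics)
#' @examples
#' res <- runCompetition(TwoSubstrateParams(kdS = 10, kcS = 0.1,
#'                                          scenario = "affinity"))
#' res$competition
#' @export
runCompetition <- function(params, horizon = 3000, outputGrid = 1) {
  stopifnot(is(params, "TwoSubstrateParams"))
  tc <- simulateDegradation(params, horizon = horizon,
                            outputGrid = outputGrid)
  solo <- simulateDegradation(soloParams(params), horizon = horizon,
                              outputGrid = outputGrid)
  mS <- timingMetrics(tc, "S")
  mC <- timingMetrics(tc, "C")
  mSolo <- timingMetrics(solo, "S")
  comp <- c(
    relOnsetDifference = .ratioOrNA(mS@t95 - mC@t95, mC@t95),
    tdRatio = .ratioOrNA(mC@td, mS@td),
    competitionEffect = .ratioOrNA(mS@t95 - mSolo@t95, mSolo@t95),
    maxOccupancyS = mS@maxOccupancy,
    maxOccupancyC = mC@maxOccupancy,
    t95SoloS = mSolo@t95
  )
  list(timeCourse = tc, soloTimeCourse = solo, metricsS = mS, metricsC = mC,
       soloMetricsS = mSolo, competition = comp)
}
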