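#' @include AllGenerics.R
NULL

.ONE_SPECIES <- c("A", paste0("S", 0:4), paste0("AS", 0:4))
.TWO_SPECIES <- c(.ONE_SPECIES, paste0("C", 0:4), paste0("AC", 0:4))

#' Construct one-substrate kinetic parameters
#'
#' Defaults follow the reference parameterisation of the model: substrate at
#' 200 nM (the estimated cellular concentration of the cyclin Clb5), APC/C
#' accumulating linearly at 0.06 nM/s from zero, and proteasomal degradation
#' at 1000/s so that substrate is destroyed essentially as soon as it carries
#' four ubiquitins.  \code{ka}, \code{kd} and \code{kc} are the parameters
#' normally scanned.
#'
#' @param ka association rate constant, /(nM s)
#' @param kd dissociation rate constant, /s
#' @param kc ubiquitin-transfer rate constant, /s
#' @param e proteasomal degradation rate constant, /s
#' @param pA APC/C-Cdc20 accumulation rate, nM/s (linear mode)
#' @param Aconst constant APC/C-Cdc20 level, nM (constant mode only)
#' @param S0 initial free unmodified substrate, nM
#' @param apcMode \code{"linear"} (A grows as pA*t from 0) or
#'   \code{"constant"} (A starts and stays at \code{Aconst} minus whatever is
#'   substrate-bound)
#' @param deubVariant which species deubiquitination acts on; \code{"none"}
#'   disables it
#' @param kdub deubiquitination rate constant, /s
#' @return a validated \linkS4class{RateParams}
#' @examples
#' p <- RateParams(kc = 0.1, kd = 10)
#' tc <- simulateDegradation(p, horizon = 300)
#' timingMetrics(tc)
#' @export
RateParams <- function(ka = 0.01, kd = 1, kc = 1, e = 1000, pA = 0.06,
                       Aconst = 100, S0 = 200,
                       apcMode = c("linear", "constant"),
                       deubVariant = c("none", "all", "free_only",
                                       "bound_only", "mono_only"),
                       kdub = 0) {
  new("RateParams", ka = ka, kd = kd, kc = kc, e = e, pA = pA,
      Aconst = Aconst, S0 = S0, apcMode = match.arg(apcMode),
      deubVariant = match.arg(deubVariant), kdub = kdub, maxUb = .MAX_UB)
}

setMethod("show", "RateParams", function(object) {
  cat("RateParams (one-substrate multi-step ubiquitination model)\n")
  cat(sprintf("  ka = %g /(nM s), kd = %g /s, kc = %g /s, e = %g /s\n",
              object@ka, object@kd, object@kc, object@e))
  if (object@apcMode == "linear")
    cat(sprintf("  APC/C input: linear, pA = %g nM/s from A(0) = 0\n",
                object@pA))
  else
    cat(sprintf("  APC/C input: constant, A_total = %g nM\n", object@Aconst))
  cat(sprintf("  S0 = %g nM; deubiquitination: %s", object@S0,
              object@deubVariant))
  if (object@deubVariant != "none")
    cat(sprintf(" (kdub = %g /s)", object@kdub))
  cat("\n")
})

## deubiquitination flows: species with i ubiquitins (i in idx) lose one at
## rate kdub; returns the signed contribution for a 5-vector (counts 0..4)
.deubFlow <- function(x, kdub, idx) {
  d <- numeric(5)
  if (kdub > 0 && length(idx)) {
    f <- kdub * x[idx + 1L]
    d[idx + 1L] <- d[idx + 1L] - f
    d[idx] <- d[idx] + f
  }
  d
}

.deubIdx <- function(variant, side) {
  switch(variant,
    none = integer(0),
    all = 1:4,
    free_only = if (side == "free") 1:4 else integer(0),
    bound_only = if (side == "bound") 1:4 else integer(0),
    mono_only = 1L)
}

## core mass-action rates; y named as .ONE_SPECIES
.ratesOne <- function(y, p) {
  A <- y[1L]
  S <- y[2:6]
  AS <- y[7:11]
  bind <- p@ka * A * S
  diss <- p@kd * AS
  catOut <- c(p@kc * AS[1:4], 0)          # AS4 has no further catalysis
  catIn <- c(0, p@kc * AS[1:4])
  dS <- -bind + diss + .deubFlow(S, p@kdub, .deubIdx(p@deubVariant, "free"))
  dS[5] <- dS[5] - p@e * S[5]
  dAS <- bind - diss - catOut + catIn +
    .deubFlow(AS, p@kdub, .deubIdx(p@deubVariant, "bound"))
  dAS[5] <- dAS[5] - p@e * AS[5]
  pATerm <- if (p@apcMode == "linear") p@pA else 0
  dA <- pATerm - sum(bind) + sum(diss) + p@e * AS[5]
  c(dA, dS, dAS)
}

.ratesTwo <- function(y, p) {
  A <- y[1L]
  S <- y[2:6];  AS <- y[7:11]
  C <- y[12:16]; AC <- y[17:21]
  bindS <- p@ka * A * S;  dissS <- p@kdS * AS
  bindC <- p@ka * A * C;  dissC <- p@kdC * AC
  dS <- -bindS + dissS; dS[5] <- dS[5] - p@e * S[5]
  dAS <- bindS - dissS - c(p@kcS * AS[1:4], 0) + c(0, p@kcS * AS[1:4])
  dAS[5] <- dAS[5] - p@e * AS[5]
  dC <- -bindC + dissC; dC[5] <- dC[5] - p@e * C[5]
  dAC <- bindC - dissC - c(p@kcC * AC[1:4], 0) + c(0, p@kcC * AC[1:4])
  dAC[5] <- dAC[5] - p@e * AC[5]
  pATerm <- if (p@apcMode == "linear") p@pA else 0
  dA <- pATerm - sum(bindS) - sum(bindC) + sum(dissS) + sum(dissC) +
    p@e * (AS[5] + AC[5])
  c(dA, dS, dAS, dC, dAC)
}

#' Instantaneous rates of change for every species
#'
#' Evaluates the mass-action right-hand side of the model at a given state:
#' binding (\code{ka*A*S_i}), dissociation (\code{kd*AS_i}), stepwise
#' ubiquitin transfer (\code{kc*AS_i} for i < 4), proteasomal degradation of
#' the four-ubiquitin forms (\code{e*S4}, \code{e*AS4}, the latter releasing
#' free APC/C), linear APC/C production, and the configured
#' deubiquitination flows.
#'
#' @param state named numeric vector of concentrations (nM); names must be
#'   \code{A}, \code{S0..S4}, \code{AS0..AS4} (plus \code{C0..C4},
#'   \code{AC0..AC4} for two-substrate parameters)
#' @param params a \linkS4class{RateParams} or
#'   \linkS4class{TwoSubstrateParams}
#' @return named numeric vector of d(concentration)/dt in nM/s
#' @examples
#' st <- initialState(RateParams())
#' degradationRates(st, RateParams())
#' @export
degradationRates <- function(state, params) {
  nm <- if (is(params, "TwoSubstrateParams")) .TWO_SPECIES else .ONE_SPECIES
  stopifnot(is.numeric(state), !is.null(names(state)))
  if (!setequal(names(state), nm))
    stop("state must have exactly the species names: ",
         paste(nm, collapse = ", "))
  y <- state[nm]
  r <- if (is(params, "TwoSubstrateParams")) .ratesTwo(y, params)
       else .ratesOne(y, params)
  names(r) <- nm
  r
}

#' Initial state for a model run
#'
#' All species start at zero except free unmodified substrate (\code{S0},
#' and \code{C0} for two-substrate runs) and, in constant-APC/C mode, free
#' APC/C at \code{Aconst}.  In linear mode A(0) = 0.
#'
#' @param params a \linkS4class{RateParams} or
#'   \linkS4class{TwoSubstrateParams}
#' @return named numeric vector of concentrations (nM)
#' @export
initialState <- function(params) {
  two <- is(params, "TwoSubstrateParams")
  nm <- if (two) .TWO_SPECIES else .ONE_SPECIES
  y0 <- setNames(numeric(length(nm)), nm)
  y0["A"] <- if (params@apcMode == "constant") params@Aconst else 0
  y0["S0"] <- params@S0
  if (two) y0["C0"] <- params@C0
  y0
}

.describeParams <- function(p) {
  if (is(p, "TwoSubstrateParams"))
    sprintf("ka=%g, kdS=%g, kcS=%g, kdC=%g, kcC=%g, e=%g, mode=%s",
            p@ka, p@kdS, p@kcS, p@kdC, p@kcC, p@e, p@apcMode)
  else
    sprintf("ka=%g, kd=%g, kc=%g, e=%g, mode=%s, deub=%s",
            p@ka, p@kd, p@kc, p@e, p@apcMode, p@deubVariant)
}

.CLIP_TOL <- 1e-6   # nM; larger negatives indicate solver failure
.REPORT_CLIP <- 1e-9

.integrate <- function(params, horizon, outputGrid, method, dt,
                       rtol = 1e-8, atol = 1e-10) {
  y0 <- initialState(params)
  times <- seq(0, horizon, by = outputGrid)
  rhs <- if (is(params, "TwoSubstrateParams")) .ratesTwo else .ratesOne
  if (method == "lsoda") {
    fn <- function(t, y, parms) list(rhs(y, parms))
    solveWith <- function(m)
      try(suppressWarnings(
        deSolve::ode(y = y0, times = times, func = fn, parms = params,
                     method = m, rtol = rtol, atol = atol,
                     maxsteps = 50000)), silent = TRUE)
    bad <- function(out)
      inherits(out, "try-error") ||
        (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0) ||
        nrow(out) < length(times) || anyNA(out)
    out <- solveWith("lsoda")
    ## lsoda's dense-output interpolation can fail once the substrate pool
    ## underflows; the plain BDF solver handles those runs, deterministically
    if (bad(out)) out <- solveWith("vode")
    if (bad(out))
      stop("integration failed for parameter set (", .describeParams(params),
           ")", call. = FALSE)
    conc <- unname(out[, -1, drop = FALSE])
  } else {
    ## explicit fixed-step Euler; only stable for dt < 2/max rate
    nSteps <- round(horizon / dt)
    y <- y0
    conc <- matrix(NA_real_, length(times), length(y0))
    conc[1, ] <- y
    nextOut <- 2L
    outEvery <- round(outputGrid / dt)
    for (stp in seq_len(nSteps)) {
      y <- y + dt * rhs(y, params)
      if (stp %% outEvery == 0L && nextOut <= length(times)) {
        conc[nextOut, ] <- y
        nextOut <- nextOut + 1L
      }
    }
    if (anyNA(conc) || any(!is.finite(conc)))
      stop("integration failed for parameter set (", .describeParams(params),
           "): fixed-step scheme diverged (decrease dt)", call. = FALSE)
  }
  if (min(conc) < -.CLIP_TOL)
    stop("integration failed for parameter set (", .describeParams(params),
         "): concentrations fell below -", .CLIP_TOL, " nM", call. = FALSE)
  conc[conc < .REPORT_CLIP & conc < 0] <- 0
  conc[conc < 0] <- 0
  colnames(conc) <- names(y0)
  new("TimeCourse", times = times, conc = conc, params = params,
      solver = if (method == "lsoda") "lsoda" else sprintf("euler(dt=%g)", dt))
}

#' Simulate a degradation time course
#'
#' Integrates the mass-action system from its initial condition over
#' \code{[0, horizon]} seconds and returns concentrations on a uniform output
#' grid.  The default integrator is the adaptive, stiffness-switching
#' \code{lsoda} (rtol 1e-8, atol 1e-10 nM) because the fast proteasomal step
#' (e = 1000/s) makes the system stiff; an explicit fixed-step Euler mode is
#' available for replication studies but requires \code{dt} below the
#' stability limit 2/(largest rate constant).
#'
#' @param params a \linkS4class{RateParams} or
#'   \linkS4class{TwoSubstrateParams}
#' @param horizon total simulated time, s (default 3000)
#' @param outputGrid output sampling interval, s (default 1)
#' @param method \code{"lsoda"} (default) or \code{"euler"}
#' @param dt fixed Euler step, s (\code{method = "euler"} only)
#' @return a \linkS4class{TimeCourse}
#' @examples
#' tc <- simulateDegradation(RateParams(kc = 0.1, kd = 10), horizon = 500)
#' plot(modelTimes(tc), totalSubstrate(tc), type = "l",
#'      xlab = "time (s)", ylab = "total substrate (nM)")
#' @export
setGeneric("simulateDegradation",
  function(params, horizon = 3000, outputGrid = 1,
           method = c("lsoda", "euler"), dt = 1)
    standardGeneric("simulateDegradation"))

#' @rdname simulateDegradation
#' @export
setMethod("simulateDegradation", "RateParams",
  function(params, horizon = 3000, outputGrid = 1,
           method = c("lsoda", "euler"), dt = 1) {
    stopifnot(horizon > 0, outputGrid > 0)
    .integrate(params, horizon, outputGrid, match.arg(method), dt)
  })

#' @rdname simulateDegradation
#' @export
setMethod("simulateDegradation", "TwoSubstrateParams",
  function(params, horizon = 3000, outputGrid = 1,
           method = c("lsoda", "euler"), dt = 1) {
    stopifnot(horizon > 0, outputGrid > 0)
    .integrate(params, horizon, outputGrid, match.arg(method), dt)
  })

#' @rdname TimeCourse-class
#' @export
setMethod("modelTimes", "TimeCourse", function(x) x@times)

#' @rdname TimeCourse-class
#' @export
setMethod("concentrations", "TimeCourse", function(x) x@conc)

#' @rdname TimeCourse-class
#' @export
setMethod("modelParams", "TimeCourse", function(x) x@params)

setMethod("show", "TimeCourse", function(object) {
  cat(sprintf("TimeCourse: %d species x %d time points over [0, %g] s (%s)\n",
              ncol(object@conc), length(object@times),
              if (length(object@times)) max(object@times) else 0,
              object@solver))
  cat("  species:", paste(colnames(object@conc), collapse = " "), "\n")
  cat("  parameters:", .describeParams(object@params), "\n")
})
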