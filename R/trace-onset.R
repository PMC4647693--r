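#' @include processivity.R
NULL

#' Construct a fluorescence trace
#'
#' @param times sample times, s (uniform spacing, default 30 s intervals)
#' @param intensities intensities, arbitrary units
#' @param cellId identifier
#' @param trueOnset ground-truth onset for synthetic traces (s), or \code{NA}
#' @return a validated \linkS4class{FluorescenceTrace}
#' @export
FluorescenceTrace <- function(times, intensities, cellId = "cell",
                              trueOnset = NA_real_) {
  new("FluorescenceTrace", cellId = as.character(cellId), times = times,
      intensities = intensities, trueOnset = trueOnset)
}

setMethod("show", "FluorescenceTrace", function(object) {
  dt <- if (length(object@times) > 1) diff(object@times)[1] else NA
  cat(sprintf("FluorescenceTrace '%s': %d samples every %g s over [%g, %g] s\n",
              object@cellId, length(object@times), dt,
              min(object@times), max(object@times)))
  if (!is.na(object@trueOnset))
    cat(sprintf("  true onset (synthetic): %g s\n", object@trueOnset))
})

## centered moving average with shrinking (partial) windows at the edges
.movingAverage <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth and normalize a trace
#'
#' Applies a centered moving average (partial windows at the edges) and
#' divides by the maximum of the smoothed curve, so the result lies in
#' (0, 1] for a non-negative trace.  \code{window = 1} is the identity
#' smoother.
#'
#' @param trace a \linkS4class{FluorescenceTrace}
#' @param window odd window length in samples (default 5, i.e. 2.5 min at
#'   30-s sampling)
#' @return a \linkS4class{FluorescenceTrace} with smoothed, normalized
#'   intensities
#' @export
smoothNormalize <- function(trace, window = 5L) {
  stopifnot(is(trace, "FluorescenceTrace"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1")
  if (length(trace@intensities) < window)
    stop("trace is shorter than the smoothing window")
  sm <- .movingAverage(trace@intensities, window)
  mx <- max(sm)
  if (mx <= 0)
    stop("smoothed trace has non-positive maximum; cannot normalize")
  FluorescenceTrace(trace@times, sm / mx, cellId = trace@cellId,
                    trueOnset = trace@trueOnset)
}

## first derivative by central differences (one-sided at the ends), per second
.firstDerivative <- function(times, y) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (times[2] - times[1])
  d[n] <- (y[n] - y[n - 1]) / (times[n] - times[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (times[i + 1] - times[i - 1])
  }
  d
}

#' Detect degradation onset on a single trace
#'
#' Implements the derivative-based onset caller: smooth and normalize the
#' trace, take its first derivative (central differences), locate the
#' derivative minimum (the fastest-declining point, which must be negative
#' for a decline to exist), then scan backwards in time from that point for
#' the latest earlier sample at which the derivative is still close to zero
#' -- operationally, at least \code{zeroFraction} times the (negative)
#' minimum, i.e. not materially declining.  That sample is the onset call.
#'
#' A centered moving average of half-width h = (window - 1)/2 smears a
#' corner over [onset - h, onset + h] samples, and the central difference
#' reaches one sample further, so the latest near-zero derivative sample
#' sits exactly h + 1 samples before the true corner.  The reported onset
#' compensates this known group delay by h + 1 samples (never beyond the
#' derivative minimum), which makes the call exact for a noise-free
#' plateau-then-decline trace at any window length.
#'
#' If the trace never declines (minimum derivative >= 0) no onset is found.
#' If the decline is already underway at the first sample, the onset is
#' reported at the first sample and flagged.
#'
#' @param trace a \linkS4class{FluorescenceTrace}
#' @param zeroFraction "close to zero" threshold as a fraction of the
#'   derivative minimum's magnitude (default 0.1)
#' @param window smoothing window passed to \code{\link{smoothNormalize}}
#' @param minDrop minimum fractional loss of the normalized trace required
#'   to call a decline at all (default 0.05); guards against reporting an
#'   onset on an essentially flat trace whose derivative minimum is only
#'   numerical ripple
#' @return an \linkS4class{OnsetCall}
#' @examples
#' tr <- generateTrace(TraceSpec(noiseSd = 0, onsetJitterSd = 0), 1)
#' detectOnset(tr)
#' @export
detectOnset <- function(trace, zeroFraction = 0.1, window = 5L,
                        minDrop = 0.05) {
  stopifnot(is(trace, "FluorescenceTrace"), zeroFraction > 0,
            zeroFraction < 1, minDrop >= 0)
  sm <- smoothNormalize(trace, window = window)
  d <- .firstDerivative(sm@times, sm@intensities)
  iMin <- which.min(d)
  m <- d[iMin]
  if (m >= 0 || min(sm@intensities) > 1 - minDrop)
    return(new("OnsetCall", cellId = trace@cellId, onsetTime = NA_real_,
               argminTime = NA_real_, threshold = zeroFraction,
               found = FALSE, flagged = FALSE))
  flagged <- FALSE
  onsetIdx <- NA_integer_
  if (iMin > 1L) {
    before <- seq_len(iMin - 1L)
    ok <- before[d[before] >= zeroFraction * m]
    if (length(ok)) onsetIdx <- max(ok)
  }
  if (is.na(onsetIdx)) {          # decline under way from the very start
    onsetIdx <- 1L
    flagged <- TRUE
  } else {
    ## compensate the smoothing + differencing group delay (h + 1 samples)
    h <- (as.integer(window) - 1L) %/% 2L
    onsetIdx <- min(onsetIdx + h + 1L, iMin)
  }
  new("OnsetCall", cellId = trace@cellId,
      onsetTime = sm@times[onsetIdx], argminTime = sm@times[iMin],
      threshold = zeroFraction, found = TRUE, flagged = flagged)
}

#' @rdname OnsetCall-class
#' @export
setMethod("onsetTime", "OnsetCall", function(x) x@onsetTime)

setMethod("show", "OnsetCall", function(object) {
  cat(sprintf("OnsetCall '%s': ", object@cellId))
  if (!object@found) {
    cat("no decline detected\n")
  } else {
    cat(sprintf("onset %g s (derivative minimum at %g s, threshold %g)%s\n",
                object@onsetTime, object@argminTime, object@threshold,
                if (object@flagged) " [flagged: decline from first sample]"
                else ""))
  }
})

#' Detect onsets for a list of traces
#'
#' @param traces list of \linkS4class{FluorescenceTrace}
#' @param ... passed to \code{\link{detectOnset}}
#' @return data.frame with columns \code{cellId, onset, argmin, found,
#'   flagged, trueOnset}
#' @export
detectOnsets <- function(traces, ...) {
  rows <- lapply(traces, function(tr) {
    oc <- detectOnset(tr, ...)
    data.frame(cellId = tr@cellId, onset = oc@onsetTime,
               argmin = oc@argminTime, found = oc@found,
               flagged = oc@flagged, trueOnset = tr@trueOnset)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare onset times between two cell populations
#'
#' Two-sample t test (Welch by default, pooled-variance on request) on the
#' detected onset times of two groups of cells, as used to compare the onset
#' timing of different APC/C-Cdc20 substrates.
#'
#' @param groupA,groupB numeric vectors of onset times, s (each n >= 2)
#' @param pooled use the pooled-variance (classical Student) test instead of
#'   Welch
#' @return list with \code{meanDifference} (mean(A) - mean(B)),
#'   \code{statistic}, \code{pValue}, \code{meanA}, \code{meanB}, \code{sdA},
#'   \code{sdB}, \code{nA}, \code{nB}, \code{method}
#' @export
onsetStatistics <- function(groupA, groupB, pooled = FALSE) {
  groupA <- groupA[!is.na(groupA)]
  groupB <- groupB[!is.na(groupB)]
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  if (sd(groupA) == 0 && sd(groupB) == 0 && mean(groupA) == mean(groupB)) {
    ## degenerate but well-defined: identical constant groups
    tt <- list(statistic = c(t = 0), p.value = 1,
               method = if (pooled) "Two Sample t-test" else "Welch")
  } else {
    tt <- stats::t.test(groupA, groupB, var.equal = pooled)
  }
  list(meanDifference = mean(groupA) - mean(groupB),
       statistic = unname(tt$statistic), pValue = tt$p.value,
       meanA = mean(groupA), meanB = mean(groupB),
       sdA = sd(groupA), sdB = sd(groupB),
       nA = length(groupA), nB = length(groupB),
       method = if (pooled) "pooled" else "welch")
}
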