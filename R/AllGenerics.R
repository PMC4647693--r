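#' @include AllClasses.R
NULL

#' Total substrate over time
#'
#' Sum of free and APC/C-bound species of one substrate at each output time,
#' in nM.  This is the "total amount of substrate" curve from which the
#' timing metrics are read.
#'
#' @param x a \linkS4class{TimeCourse}
#' @param substrate \code{"S"} (default) or \code{"C"} (two-substrate runs)
#' @return numeric vector, one value per time point
#' @export
setGeneric("totalSubstrate", function(x, substrate = "S")
  standardGeneric("totalSubstrate"))

#' Compute degradation-timing metrics
#'
#' T95 and T50 are the first times the total-substrate curve falls to 95%
#' and 50% of its initial value (linear interpolation between output
#' samples); Td = T50 - T95.  Crossings that do not occur within the horizon
#' are censored.  Also reports the maximum fraction of APC/C-Cdc20 occupied
#' by the substrate.
#'
#' @param x a \linkS4class{TimeCourse}
#' @param substrate \code{"S"} or \code{"C"}
#' @return a \linkS4class{TimingMetrics}
#' @export
setGeneric("timingMetrics", function(x, substrate = "S")
  standardGeneric("timingMetrics"))

#' Maximum APC/C occupancy by a substrate
#'
#' Maximum over time of (substrate-bound APC/C) / (total APC/C), skipping
#' time points where no APC/C is yet present.  Returns \code{NA} when the
#' APC/C trajectory is identically zero.
#'
#' @param x a \linkS4class{TimeCourse}
#' @param substrate \code{"S"} or \code{"C"}
#' @return a fraction in [0, 1], or \code{NA}
#' @export
setGeneric("maxOccupancy", function(x, substrate = "S")
  standardGeneric("maxOccupancy"))

#' @describeIn TimeCourse-class output time grid (s)
#' @param x,object a \code{TimeCourse}
#' @export
setGeneric("modelTimes", function(x) standardGeneric("modelTimes"))

#' @describeIn TimeCourse-class concentration matrix (time x species, nM)
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @describeIn TimeCourse-class the parameter object used
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @describeIn TimingMetrics-class onset-delay metric T95 (s; NA if censored)
#' @param x,object a \code{TimingMetrics}
#' @export
setGeneric("T95", function(x) standardGeneric("T95"))

#' @describeIn TimingMetrics-class half-degradation time T50 (s; NA if censored)
#' @export
setGeneric("T50", function(x) standardGeneric("T50"))

#' @describeIn TimingMetrics-class degradation-rate metric Td = T50 - T95 (s)
#' @export
setGeneric("Td", function(x) standardGeneric("Td"))

#' @describeIn TimingMetrics-class named logical censoring flags
#' @export
setGeneric("isCensored", function(x) standardGeneric("isCensored"))

#' @describeIn ScanResult-class per-cell metric table as a data.frame
#' @param x,object a \code{ScanResult}
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @describeIn ProcessivityResult-class average ubiquitins per substrate
#' @param x,object a \code{ProcessivityResult}
#' @export
setGeneric("avgUbiquitins", function(x) standardGeneric("avgUbiquitins"))

#' @describeIn OnsetCall-class detected onset time (s; NA when not found)
#' @param x,object an \code{OnsetCall}
#' @export
setGeneric("onsetTime", function(x) standardGeneric("onsetTime"))
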