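#' @include model-core.R
NULL

.substrateCols <- function(tc, substrate) {
  substrate <- match.arg(substrate, c("S", "C"))
  free <- paste0(substrate, 0:4)
  bound <- paste0("A", substrate, 0:4)
  cols <- c(free, bound)
  if (!all(cols %in% colnames(tc@conc)))
    stop("time course has no substrate '", substrate, "'")
  cols
}

#' @rdname totalSubstrate
#' @export
setMethod("totalSubstrate", "TimeCourse", function(x, substrate = "S") {
  cols <- .substrateCols(x, substrate)
  rowSums(x@conc[, cols, drop = FALSE])
})

#' First crossing time of a fraction of the initial value
#'
#' Finds the first time at which a sampled series falls to
#' \code{fraction * series[1]}, locating the crossing by linear interpolation
#' between adjacent samples.  Returns \code{NA} (censored) when the series
#' never reaches the threshold within the sampled window.
#'
#' @param times sample times, s, strictly increasing
#' @param series sampled values; \code{series[1]} must be positive (it is the
#'   baseline)
#' @param fraction target fraction of the initial value, in (0, 1)
#' @return crossing time in seconds, or \code{NA_real_} if censored
#' @examples
#' t <- 0:3000
#' crossingTime(t, 200 * exp(-0.01 * t), 0.5)  # ~ log(2)/0.01
#' @export
crossingTime <- function(times, series, fraction) {
  stopifnot(length(times) == length(series), fraction > 0, fraction < 1)
  if (!is.finite(series[1]) || series[1] <= 0)
    stop("undefined baseline: series must start at a positive value")
  target <- fraction * series[1]
  below <- which(series <= target)
  if (!length(below))
    return(NA_real_)
  j <- below[1]
  if (j == 1L)
    return(times[1])
  ## interpolate on the bracketing interval [j-1, j]
  t0 <- times[j - 1L]; t1 <- times[j]
  y0 <- series[j - 1L]; y1 <- series[j]
  if (y0 == y1) return(t1)
  t0 + (y0 - target) / (y0 - y1) * (t1 - t0)
}

#' @rdname maxOccupancy
#' @export
setMethod("maxOccupancy", "TimeCourse", function(x, substrate = "S") {
  substrate <- match.arg(substrate, c("S", "C"))
  boundCols <- grep("^A[SC][0-4]$", colnames(x@conc), value = TRUE)
  own <- boundCols[substr(boundCols, 2, 2) == substrate]
  if (!length(own))
    stop("time course has no substrate '", substrate, "'")
  totalBound <- rowSums(x@conc[, boundCols, drop = FALSE])
  totalA <- x@conc[, "A"] + totalBound
  ok <- totalA > 0
  if (!any(ok))
    return(NA_real_)
  ownBound <- rowSums(x@conc[, own, drop = FALSE])
  max(ownBound[ok] / totalA[ok])
})

#' @rdname timingMetrics
#' @export
setMethod("timingMetrics", "TimeCourse", function(x, substrate = "S") {
  tot <- totalSubstrate(x, substrate)
  t95 <- crossingTime(x@times, tot, 0.95)
  t50 <- crossingTime(x@times, tot, 0.50)
  td <- if (!is.na(t95) && !is.na(t50)) t50 - t95 else NA_real_
  occ <- maxOccupancy(x, substrate)
  new("TimingMetrics", t95 = t95, t50 = t50, td = td, maxOccupancy = occ,
      censored = c(t95 = is.na(t95), t50 = is.na(t50), td = is.na(td)),
      substrate = substrate)
})

#' @rdname TimingMetrics-class
#' @export
setMethod("T95", "TimingMetrics", function(x) x@t95)

#' @rdname TimingMetrics-class
#' @export
setMethod("T50", "TimingMetrics", function(x) x@t50)

#' @rdname TimingMetrics-class
#' @export
setMethod("Td", "TimingMetrics", function(x) x@td)

#' @rdname TimingMetrics-class
#' @export
setMethod("isCensored", "TimingMetrics", function(x) x@censored)

#' @rdname TimingMetrics-class
#' @export
setMethod("maxOccupancy", "TimingMetrics", function(x, substrate = "S")
  x@maxOccupancy)

setMethod("show", "TimingMetrics", function(object) {
  fmt <- function(v, cens) if (cens) "censored" else sprintf("%.2f s", v)
  cat(sprintf("TimingMetrics for substrate %s\n", object@substrate))
  cat("  T95 (onset delay):  ", fmt(object@t95, object@censored["t95"]), "\n")
  cat("  T50 (half-life pt): ", fmt(object@t50, object@censored["t50"]), "\n")
  cat("  Td  (T50 - T95):    ", fmt(object@td, object@censored["td"]), "\n")
  if (!is.na(object@maxOccupancy))
    cat(sprintf("  max APC/C occupancy: %.4f\n", object@maxOccupancy))
  else
    cat("  max APC/C occupancy: undefined (no APC/C present)\n")
})
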