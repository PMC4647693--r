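#' @include competition.R
NULL

#' Build the log-spaced parameter grid
#'
#' By default: 25 values of \code{kc} and of \code{kd} equally spaced on a
#' log scale over [1e-3, 1e3] /s, so that each value differs from its
#' neighbour by the factor 10^(1/4) (about 1.8), and 6 values of \code{ka}
#' over [1e-4, 10] /(nM s) spaced by factors of 10.  Endpoints are included
#' exactly.
#'
#' @param kcRange,kdRange length-2 numeric ranges, /s
#' @param kaRange length-2 numeric range, /(nM s)
#' @param nKc,nKd,nKa numbers of grid points
#' @return a \linkS4class{LogGrid}
#' @examples
#' g <- buildLogGrid()
#' range(g@kc); g@kc[2] / g@kc[1]   # 10^0.25
#' @export
buildLogGrid <- function(kcRange = c(1e-3, 1e3), kdRange = c(1e-3, 1e3),
                         kaRange = c(1e-4, 10), nKc = 25L, nKd = 25L,
                         nKa = 6L) {
  logSeq <- function(r, n) {
    stopifnot(length(r) == 2L, all(r > 0), r[2] > r[1], n >= 2L)
    10^seq(log10(r[1]), log10(r[2]), length.out = n)
  }
  new("LogGrid", kc = logSeq(kcRange, nKc), kd = logSeq(kdRange, nKd),
      ka = logSeq(kaRange, nKa))
}

setMethod("show", "LogGrid", function(object) {
  cat(sprintf("LogGrid: %d kc x %d kd cells (x %d ka values)\n",
              length(object@kc), length(object@kd), length(object@ka)))
  cat(sprintf("  kc in [%g, %g] /s, kd in [%g, %g] /s, ka in [%g, %g] /(nM s)\n",
              min(object@kc), max(object@kc), min(object@kd), max(object@kd),
              min(object@ka), max(object@ka)))
})

.metricsRow <- function(m) {
  c(t95 = m@t95, t50 = m@t50, td = m@td, maxOccupancy = m@maxOccupancy)
}

#' Scan the one-substrate model over a (kc, kd) grid
#'
#' Runs \code{\link{simulateDegradation}} at every (kc, kd) cell of the grid
#' with all other parameters fixed, and records T95, T50, Td, the maximum
#' APC/C occupancy and censoring flags per cell.  A solver failure in one
#' cell is recorded (\code{failed = TRUE}) and never aborts the scan.
#'
#' @param grid a \linkS4class{LogGrid} (only \code{kc} and \code{kd} are
#'   scanned; fix \code{ka} via \code{baseParams})
#' @param baseParams a \linkS4class{RateParams} supplying every parameter
#'   except \code{kc} and \code{kd}
#' @param horizon simulated time per cell, s
#' @param outputGrid output sampling interval, s
#' @return a \linkS4class{ScanResult} whose table has one row per (kc, kd)
#'   cell with columns \code{kc, kd, t95, t50, td, maxOccupancy,
#'   censoredT95, censoredT50, censoredTd, failed}
#' @examples
#' g <- buildLogGrid(nKc = 3, nKd = 3)
#' sc <- scanGrid(g, RateParams(), horizon = 500)
#' head(scanTable(sc))
#' @export
scanGrid <- function(grid, baseParams = RateParams(), horizon = 3000,
                     outputGrid = 1) {
  stopifnot(is(grid, "LogGrid"), is(baseParams, "RateParams"))
  cells <- expand.grid(kc = grid@kc, kd = grid@kd,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- baseParams
    p@kc <- cells$kc[i]
    p@kd <- cells$kd[i]
    res <- try({
      tc <- simulateDegradation(p, horizon = horizon,
                                outputGrid = outputGrid)
      timingMetrics(tc, "S")
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      rows[[i]] <- data.frame(kc = cells$kc[i], kd = cells$kd[i],
                              t95 = NA_real_, t50 = NA_real_, td = NA_real_,
                              maxOccupancy = NA_real_, censoredT95 = TRUE,
                              censoredT50 = TRUE, censoredTd = TRUE,
                              failed = TRUE)
    } else {
      rows[[i]] <- data.frame(kc = cells$kc[i], kd = cells$kd[i],
                              t95 = res@t95, t50 = res@t50, td = res@td,
                              maxOccupancy = res@maxOccupancy,
                              censoredT95 = res@censored[["t95"]],
                              censoredT50 = res@censored[["t50"]],
                              censoredTd = res@censored[["td"]],
                              failed = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  fixed <- list(ka = baseParams@ka, e = baseParams@e,
                apcMode = baseParams@apcMode, pA = baseParams@pA,
                Aconst = baseParams@Aconst, S0 = baseParams@S0,
                deubVariant = baseParams@deubVariant, kdub = baseParams@kdub,
                horizon = horizon, outputGrid = outputGrid,
                solver = "lsoda(rtol=1e-8,atol=1e-10)")
  new("ScanResult", grid = grid, table = tab, fixed = fixed,
      scanType = "one_substrate")
}

#' Scan a two-substrate competition scenario over the (kc,S, kd,S) grid
#'
#' For every grid cell, runs the two-substrate system (C's parameters derived
#' from the scenario rule) together with the one-substrate baseline of S, and
#' records the timing metrics of both substrates plus the competition
#' metrics of \code{\link{runCompetition}}.  The grid indexes the parameters
#' of S; C's follow the scenario.
#'
#' @param grid a \linkS4class{LogGrid}
#' @param scenario \code{"affinity"} or \code{"catalytic"}
#' @param baseParams a \linkS4class{RateParams} carrying the shared
#'   parameters (ka, e, APC/C input, initial amounts taken as S0 for both)
#' @param horizon,outputGrid as in \code{\link{scanGrid}}
#' @param cells optional two-column data.frame (kc, kd) restricting the scan
#'   to a subset of grid cells; metrics for the remaining cells are
#'   \code{NA} with \code{skipped = TRUE}
#' @return a \linkS4class{ScanResult} with \code{scanType =
#'   "two_substrate"}; table columns include per-substrate metrics
#'   (\code{t95S, tdS, t95C, tdC, ...}) and \code{relOnsetDifference,
#'   tdRatio, competitionEffect}
#' @export
competitionScan <- function(grid, scenario = c("affinity", "catalytic"),
                            baseParams = RateParams(), horizon = 3000,
                            outputGrid = 1, cells = NULL) {
  stopifnot(is(grid, "LogGrid"))
  scenario <- match.arg(scenario)
  all_cells <- expand.grid(kc = grid@kc, kd = grid@kd,
                           KEEP.OUT.ATTRS = FALSE)
  if (is.null(cells)) {
    todo <- rep(TRUE, nrow(all_cells))
  } else {
    key <- paste(signif(all_cells$kc, 12), signif(all_cells$kd, 12))
    want <- paste(signif(cells$kc, 12), signif(cells$kd, 12))
    todo <- key %in% want
  }
  emptyRow <- function(kc, kd, failed = FALSE, skipped = FALSE)
    data.frame(kc = kc, kd = kd, t95S = NA_real_, t50S = NA_real_,
               tdS = NA_real_, maxOccupancyS = NA_real_, t95C = NA_real_,
               t50C = NA_real_, tdC = NA_real_, maxOccupancyC = NA_real_,
               t95SoloS = NA_real_, relOnsetDifference = NA_real_,
               tdRatio = NA_real_, competitionEffect = NA_real_,
               failed = failed, skipped = skipped)
  rows <- vector("list", nrow(all_cells))
  for (i in seq_len(nrow(all_cells))) {
    kc <- all_cells$kc[i]; kd <- all_cells$kd[i]
    if (!todo[i]) { rows[[i]] <- emptyRow(kc, kd, skipped = TRUE); next }
    res <- try({
      p <- TwoSubstrateParams(kdS = kd, kcS = kc, scenario = scenario,
                              ka = baseParams@ka, e = baseParams@e,
                              pA = baseParams@pA, Aconst = baseParams@Aconst,
                              apcMode = baseParams@apcMode,
                              S0 = baseParams@S0, C0 = baseParams@S0)
      runCompetition(p, horizon = horizon, outputGrid = outputGrid)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      rows[[i]] <- emptyRow(kc, kd, failed = TRUE)
    } else {
      mS <- res$metricsS; mC <- res$metricsC
      rows[[i]] <- data.frame(
        kc = kc, kd = kd,
        t95S = mS@t95, t50S = mS@t50, tdS = mS@td,
        maxOccupancyS = mS@maxOccupancy,
        t95C = mC@t95, t50C = mC@t50, tdC = mC@td,
        maxOccupancyC = mC@maxOccupancy,
        t95SoloS = res$competition[["t95SoloS"]],
        relOnsetDifference = res$competition[["relOnsetDifference"]],
        tdRatio = res$competition[["tdRatio"]],
        competitionEffect = res$competition[["competitionEffect"]],
        failed = FALSE, skipped = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  fixed <- list(ka = baseParams@ka, e = baseParams@e,
                apcMode = baseParams@apcMode, pA = baseParams@pA,
                Aconst = baseParams@Aconst, S0 = baseParams@S0,
                scenario = scenario, horizon = horizon,
                outputGrid = outputGrid,
                solver = "lsoda(rtol=1e-8,atol=1e-10)")
  new("ScanResult", grid = grid, table = tab, fixed = fixed,
      scanType = "two_substrate")
}

#' @rdname ScanResult-class
#' @export
setMethod("scanTable", "ScanResult", function(x) x@table)

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult (%s): %d cells\n", object@scanType,
              nrow(object@table)))
  cat(sprintf("  fixed: ka = %g /(nM s), e = %g /s, mode = %s\n",
              object@fixed$ka, object@fixed$e, object@fixed$apcMode))
  if (object@scanType == "one_substrate") {
    m <- overlapMask(object)
    cat(sprintf("  overlap zone (T95 > 200 s & Td < 600 s): %d cells\n",
                sum(m, na.rm = TRUE)))
  }
})

#' Timing-criteria masks over a scan
#'
#' The two in-vivo-motivated criteria are a delayed onset, T95 > 200 s, and
#' a fast degradation, Td < 600 s.  \code{delayMask} and \code{rateMask}
#' return the single-criterion masks; \code{overlapMask} their elementwise
#' AND (the overlap zone).  Censored T95 cells (substrate never reached 95%)
#' satisfy the delay criterion trivially but can never satisfy the rate
#' criterion; censored Td cells fail the rate criterion.
#'
#' @param scan a one-substrate \linkS4class{ScanResult} (for two-substrate
#'   scans the masks refer to substrate S's solo-equivalent columns
#'   \code{t95S}, \code{tdS})
#' @param t95Min onset-delay threshold, s (default 200)
#' @param tdMax degradation-rate threshold, s (default 600)
#' @return logical vector aligned with \code{scanTable(scan)} rows
#' @export
overlapMask <- function(scan, t95Min = 200, tdMax = 600) {
  delayMask(scan, t95Min) & rateMask(scan, tdMax)
}

#' @rdname overlapMask
#' @export
delayMask <- function(scan, t95Min = 200) {
  tab <- scan@table
  t95 <- if ("t95" %in% names(tab)) tab$t95 else tab$t95S
  cens <- if ("censoredT95" %in% names(tab)) tab$censoredT95 else is.na(t95)
  ifelse(cens, TRUE, t95 > t95Min) & !tab$failed
}

#' @rdname overlapMask
#' @export
rateMask <- function(scan, tdMax = 600) {
  tab <- scan@table
  td <- if ("td" %in% names(tab)) tab$td else tab$tdS
  ifelse(is.na(td), FALSE, td < tdMax) & !tab$failed
}

#' T95 sensitivity to a small perturbation of kc or kd
#'
#' Recomputes the model after multiplying \code{kc} by the grid-spacing
#' factor 10^(1/4) (about 1.8; \code{which = "kc_up"}) or dividing \code{kd}
#' by the same factor (\code{which = "kd_down"}), and returns the relative
#' decrease of T95, (T95_base - T95_perturbed) / T95_base.  The perturbed run
#' is a fresh simulation, so the sensitivity is defined off-grid too.
#' Censored baselines or perturbed runs yield \code{NA}.
#'
#' @param params a \linkS4class{RateParams} at the baseline cell
#' @param which \code{"kc_up"} or \code{"kd_down"}
#' @param factor perturbation factor; default the exact grid ratio 10^0.25
#' @param horizon,outputGrid as in \code{\link{simulateDegradation}}
#' @return list with \code{sensitivity} (relative T95 decrease),
#'   \code{t95Base}, \code{t95Perturbed}
#' @examples
#' sensitivityT95(RateParams(kc = 0.1, kd = 10), "kc_up", horizon = 1000)
#' @export
sensitivityT95 <- function(params, which = c("kc_up", "kd_down"),
                           factor = 10^0.25, horizon = 3000,
                           outputGrid = 1) {
  which <- match.arg(which)
  stopifnot(is(params, "RateParams"), factor > 1)
  pert <- params
  if (which == "kc_up") pert@kc <- params@kc * factor
  else pert@kd <- params@kd / factor
  base <- timingMetrics(simulateDegradation(params, horizon = horizon,
                                            outputGrid = outputGrid))
  perturbed <- timingMetrics(simulateDegradation(pert, horizon = horizon,
                                                 outputGrid = outputGrid))
  sens <- if (is.na(base@t95) || is.na(perturbed@t95)) NA_real_
          else (base@t95 - perturbed@t95) / base@t95
  list(sensitivity = sens, t95Base = base@t95, t95Perturbed = perturbed@t95)
}
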