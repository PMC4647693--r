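#' @include synthetic-data.R
NULL

.pkgVersion <- function()
  as.character(utils::packageVersion("apcdeg"))

## provenance header written at the top of every CSV artifact
.provenanceLines <- function(extra = character(0)) {
  c(sprintf("# apcdeg %s", .pkgVersion()),
    sprintf("# %s", extra))
}

.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

## full-precision CSV writer with '#' provenance header
.writeCSV <- function(df, path, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceLines(extra), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  })
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.readCSV <- function(path, required) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a model configuration file
#'
#' Reads a YAML or JSON mapping of the kinetic-parameter field names
#' (\code{k_a}, \code{k_d}, \code{k_c}, \code{e}, \code{p_A},
#' \code{A_const}, \code{S0_init}, \code{apc_mode}, \code{deub_variant},
#' \code{k_dub}; units as in \linkS4class{RateParams}) and returns the
#' corresponding parameter object.  Unknown keys are an error, so configs
#' round-trip losslessly.
#'
#' @param path file path; format chosen by extension (.yaml/.yml/.json)
#' @return a \linkS4class{RateParams}
#' @export
readRateConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    stop("unsupported config extension '", ext, "' (use .yaml or .json)"))
  known <- c(k_a = "ka", k_d = "kd", k_c = "kc", e = "e", p_A = "pA",
             A_const = "Aconst", S0_init = "S0", apc_mode = "apcMode",
             deub_variant = "deubVariant", k_dub = "kdub")
  bad <- setdiff(names(cfg), names(known))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- stats::setNames(cfg, known[names(cfg)])
  do.call(RateParams, args)
}

#' Write a model configuration file
#'
#' Inverse of \code{\link{readRateConfig}}; the written file reads back to
#' an identical parameter object.
#'
#' @param params a \linkS4class{RateParams}
#' @param path output path (.yaml/.yml or .json)
#' @return the path, invisibly
#' @export
writeRateConfig <- function(params, path) {
  stopifnot(is(params, "RateParams"))
  cfg <- list(k_a = params@ka, k_d = params@kd, k_c = params@kc,
              e = params@e, p_A = params@pA, A_const = params@Aconst,
              S0_init = params@S0, apc_mode = params@apcMode,
              deub_variant = params@deubVariant, k_dub = params@kdub)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(cfg, path),
    json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config extension '", ext, "'"))
  invisible(path)
}

#' Write / read a time course as tidy CSV
#'
#' Long layout with columns \code{time_s}, \code{species},
#' \code{concentration_nM}; numbers are written with 17 significant digits so
#' a write-then-read round trip reproduces the values exactly.  A provenance
#' header (package version, parameter hash) precedes the data as
#' \code{#}-comment lines.
#'
#' @param tc a \linkS4class{TimeCourse}
#' @param path file path
#' @return \code{writeTimeCourseCSV}: the path, invisibly;
#'   \code{readTimeCourseCSV}: a \linkS4class{TimeCourse} (without the
#'   originating parameter object)
#' @export
writeTimeCourseCSV <- function(tc, path) {
  stopifnot(is(tc, "TimeCourse"))
  species <- colnames(tc@conc)
  df <- data.frame(
    time_s = rep(tc@times, times = length(species)),
    species = rep(species, each = length(tc@times)),
    concentration_nM = as.vector(tc@conc))
  .writeCSV(df, path,
            extra = sprintf("params_hash: %s; solver: %s",
                            .hashObject(tc@params), tc@solver))
}

#' @rdname writeTimeCourseCSV
#' @export
readTimeCourseCSV <- function(path) {
  df <- .readCSV(path, c("time_s", "species", "concentration_nM"))
  df$time_s <- as.numeric(df$time_s)
  df$concentration_nM <- as.numeric(df$concentration_nM)
  species <- unique(df$species)
  times <- sort(unique(df$time_s))
  conc <- matrix(NA_real_, length(times), length(species),
                 dimnames = list(NULL, species))
  for (sp in species) {
    sub <- df[df$species == sp, ]
    conc[, sp] <- sub$concentration_nM[order(sub$time_s)]
  }
  new("TimeCourse", times = times, conc = conc, params = NULL,
      solver = "file")
}

#' Write / read fluorescence traces as CSV
#'
#' Columns \code{cell_id}, \code{time_s}, \code{intensity}, plus
#' \code{true_onset_s} when any trace carries a ground-truth onset.
#'
#' @param traces list of \linkS4class{FluorescenceTrace}
#' @param path file path
#' @return \code{writeTraceCSV}: the path, invisibly; \code{readTraceCSV}: a
#'   list of \linkS4class{FluorescenceTrace}
#' @export
writeTraceCSV <- function(traces, path) {
  if (is(traces, "FluorescenceTrace")) traces <- list(traces)
  withTruth <- any(vapply(traces, function(tr) !is.na(tr@trueOnset),
                          logical(1)))
  df <- do.call(rbind, lapply(traces, function(tr) {
    out <- data.frame(cell_id = tr@cellId, time_s = tr@times,
                      intensity = tr@intensities)
    if (withTruth) out$true_onset_s <- tr@trueOnset
    out
  }))
  .writeCSV(df, path, extra = sprintf("n_cells: %d", length(traces)))
}

#' @rdname writeTraceCSV
#' @export
readTraceCSV <- function(path) {
  df <- .readCSV(path, c("cell_id", "time_s", "intensity"))
  df$time_s <- as.numeric(df$time_s)
  df$intensity <- as.numeric(df$intensity)
  lapply(split(df, factor(df$cell_id, levels = unique(df$cell_id))),
         function(sub) {
           ord <- order(sub$time_s)
           FluorescenceTrace(sub$time_s[ord], sub$intensity[ord],
                             cellId = sub$cell_id[1],
                             trueOnset = if ("true_onset_s" %in% names(sub))
                               sub$true_onset_s[1] else NA_real_)
         })
}

#' Write a scan result as tidy CSV
#'
#' One row per grid cell per metric: columns \code{ka}, \code{kc},
#' \code{kd}, \code{metric}, \code{value}, \code{censored}.  Deterministic:
#' identical scans yield byte-identical files.
#'
#' @param scan a \linkS4class{ScanResult}
#' @param path file path
#' @return the path, invisibly
#' @export
writeScanCSV <- function(scan, path) {
  stopifnot(is(scan, "ScanResult"))
  tab <- scan@table
  metricCols <- setdiff(names(tab),
                        c("kc", "kd", "failed", "skipped",
                          grep("^censored", names(tab), value = TRUE)))
  censorFor <- function(metric) {
    flag <- paste0("censored", toupper(substring(metric, 1, 1)),
                   substring(metric, 2))
    if (flag %in% names(tab)) tab[[flag]] else is.na(tab[[metric]])
  }
  long <- do.call(rbind, lapply(metricCols, function(m)
    data.frame(ka = scan@fixed$ka, kc = tab$kc, kd = tab$kd, metric = m,
               value = tab[[m]], censored = censorFor(m))))
  long <- long[order(long$metric, long$kd, long$kc), ]
  rownames(long) <- NULL
  .writeCSV(long, path,
            extra = sprintf("scan: %s; fixed_hash: %s", scan@scanType,
                            .hashObject(scan@fixed)))
}

#' Write scalar metrics as a JSON sidecar
#'
#' @param metrics a \linkS4class{TimingMetrics}, or a named list of scalars
#' @param path file path
#' @return the path, invisibly
#' @export
writeMetricsJSON <- function(metrics, path) {
  if (is(metrics, "TimingMetrics"))
    metrics <- list(substrate = metrics@substrate, t95_s = metrics@t95,
                    t50_s = metrics@t50, td_s = metrics@td,
                    max_occupancy = metrics@maxOccupancy,
                    censored = as.list(metrics@censored))
  jsonlite::write_json(c(list(package = paste("apcdeg", .pkgVersion())),
                         metrics),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
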