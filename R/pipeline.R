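#' Inoculum carryover concentration
#'
#' Concentration of a stock component (e.g. the glycerol used as
#' cryoprotectant) carried into a culture well with the inoculum:
#' \deqn{c = \frac{c_{stock}}{d} \cdot \frac{v_{inoc}}{v_{inoc} + v_{medium}}}
#' with \eqn{d} the predilution factor. Cryostock glycerol supports
#' background growth in no-added-carbon control wells, so this number
#' decides whether growth on poor substrates can be interpreted at all.
#' With the standard protocol (200 g/L glycerol stock, 30-fold predilution,
#' 10 uL inoculum into 290 uL medium) the carryover is 0.22 g/L.
#'
#' @param cStock Stock concentration (g/L), > 0.
#' @param predilutionFactor Fold dilution before inoculation, >= 1.
#' @param vInoc Inoculum volume (uL), > 0.
#' @param vMedium Medium volume (uL), >= 0.
#' @return Concentration in the well (g/L).
#' @examples
#' carryoverConcentration(200, 30, 10, 290)  # 0.222 -> displays as 0.22 g/L
#' @export
carryoverConcentration <- function(cStock, predilutionFactor, vInoc, vMedium) {
  if (cStock <= 0 || vInoc <= 0 || vMedium < 0)
    stopParam("cStock and vInoc must be positive, vMedium non-negative")
  if (predilutionFactor < 1)
    stopParam("predilutionFactor must be >= 1")
  cStock / predilutionFactor * vInoc / (vInoc + vMedium)
}

#' Run the full plate-analysis pipeline
#'
#' Orchestrates ingest, per-well kinetics, group statistics and table
#' emission. The input is either a measured plate (\code{timeseries} CSV +
#' \code{layout} YAML) or a simulation \code{scenario}; exactly one must be
#' given. Outputs written under \code{out}: \code{wells.csv} (per-well
#' kinetics), \code{table_max_od.csv}/\code{.md} and
#' \code{table_mu.csv}/\code{.md} (strain x substrate summary tables with
#' letters and cross-system marks), \code{run.log}, and for simulations
#' \code{plate.csv} and \code{truth.csv}. Wells whose kinetics fail are
#' logged and excluded from the statistics; only hard errors (unreadable
#' input, inconsistent layout) abort the run.
#'
#' @param timeseries Path to a time-series CSV (with \code{layout}).
#' @param layout Path to a layout YAML.
#' @param scenario Scenario list or YAML path (instead of
#'   \code{timeseries}/\code{layout}); a list of scenarios (e.g. one per
#'   cultivation system) simulates one plate each and pools the results, so
#'   cross-system comparisons appear in the tables.
#' @param dialect CSV dialect for [readTimeseriesCsv()].
#' @param smoothing Smoothing policy: a single factor, or a named vector
#'   keyed by substrate (e.g. \code{c(glucose = 0.3, no_carbon = 0.7)}) for
#'   the usual rule of 0.3 for good growth and 0.7 for poor or no growth.
#' @param alpha Significance level (default 0.05).
#' @param out Output directory (created if needed), or \code{NULL} to skip
#'   writing.
#' @param seed Seed for simulation scenarios.
#' @param format \code{"csv"}, \code{"markdown"} or both.
#' @return (Invisibly) list with \code{results} (per-well), \code{tableMu},
#'   \code{tableMaxOd}, \code{plates}, \code{truth} (simulations only), and
#'   \code{log} (character vector).
#' @export
runPipeline <- function(timeseries = NULL, layout = NULL, scenario = NULL,
                        dialect = "generic", smoothing = 0.3, alpha = 0.05,
                        out = NULL, seed = 1L,
                        format = c("csv", "markdown")) {
  format <- match.arg(format, several.ok = TRUE)
  hasFiles <- !is.null(timeseries) || !is.null(layout)
  if (hasFiles == !is.null(scenario))
    stopConfig("give either timeseries+layout or a scenario, not both")
  log <- c(sprintf("plateKinetics run %s", format(Sys.time(), "%Y-%m-%d")),
           sprintf("alpha = %g, seed = %d", alpha, as.integer(seed)))

  truth <- NULL
  plates <- NULL
  if (!is.null(scenario)) {
    # one scenario, or a list of scenarios (e.g. one per cultivation system,
    # each a physically separate plate) pooled into one analysis
    scen <- if (!is.null(scenario$groups)) list(scenario) else scenario
    sims <- lapply(seq_along(scen), function(i)
      simulatePlate(scen[[i]], seed = as.integer(seed) + (i - 1L)))
    plates <- lapply(sims, `[[`, "plate")
    plate <- plates[[1]]
    truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
    log <- c(log, sprintf("simulated %d plate(s): %d wells total",
                          length(plates),
                          sum(vapply(plates, nWells, 0L))))
  } else {
    if (is.null(timeseries) || is.null(layout))
      stopConfig("both timeseries and layout are required")
    plate <- readTimeseriesCsv(timeseries, dialect = dialect)
    ann <- readLayout(layout)
    orphans <- setdiff(wellIds(plate), ann$well)
    if (length(orphans))
      stopConfig(sprintf("layout does not cover well(s): %s",
                         paste(orphans, collapse = ", ")))
    extra <- setdiff(ann$well, wellIds(plate))
    if (length(extra))
      stopConfig(sprintf("layout lists well(s) absent from the time series: %s",
                         paste(extra, collapse = ", ")))
    wellAnnotations(plate) <- ann
    log <- c(log, sprintf("read plate: %d wells, %d time points",
                          nWells(plate), length(plateTime(plate))))
  }

  if (is.null(plates)) plates <- list(plate)
  sPolicy <- if (!is.null(names(smoothing))) {
    subs <- unique(unlist(lapply(plates, function(p) wellAnnotations(p)$substrate)))
    miss <- setdiff(subs, names(smoothing))
    if (length(miss))
      stopConfig(sprintf("smoothing map lacks substrate(s): %s",
                         paste(miss, collapse = ", ")))
    function(row) unname(smoothing[[row$substrate]])
  } else as.numeric(smoothing)
  log <- c(log, sprintf("smoothing policy: %s",
                        paste(format(smoothing, digits = 3), collapse = ", ")))

  results <- do.call(rbind, lapply(plates, analyzePlate, smoothing = sPolicy))
  failed <- results[!results$ok, , drop = FALSE]
  if (nrow(failed))
    log <- c(log, sprintf("excluded well %s: %s", failed$well, failed$reason))
  flagged <- results[results$ok & nzchar(results$qc_flags), , drop = FALSE]
  if (nrow(flagged))
    log <- c(log, sprintf("flags for well %s: %s", flagged$well, flagged$qc_flags))
  log <- c(log, sprintf("%d/%d wells analyzed", sum(results$ok), nrow(results)))

  tableMu <- groupTables(results, metric = "mu_max", alpha = alpha)
  tableMaxOd <- groupTables(results, metric = "max_od", alpha = alpha)

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    writeKineticsCsv(results, file.path(out, "wells.csv"))
    if ("csv" %in% format) {
      writeGroupTable(tableMu, file.path(out, "table_mu.csv"), "csv")
      writeGroupTable(tableMaxOd, file.path(out, "table_max_od.csv"), "csv")
    }
    if ("markdown" %in% format) {
      writeGroupTable(tableMu, file.path(out, "table_mu.md"), "markdown")
      writeGroupTable(tableMaxOd, file.path(out, "table_max_od.md"), "markdown")
    }
    if (!is.null(truth)) {
      for (i in seq_along(plates)) {
        nm <- if (length(plates) == 1) "plate.csv" else sprintf("plate_%d.csv", i)
        writeTimeseriesCsv(plates[[i]], file.path(out, nm))
      }
      writeGroundTruthCsv(truth, file.path(out, "truth.csv"))
    }
    writeLines(log, file.path(out, "run.log"))
  }
  invisible(list(results = results, tableMu = tableMu,
                 tableMaxOd = tableMaxOd, plates = plates, truth = truth,
                 log = log))
}
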