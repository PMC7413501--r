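#' Read a plate-reader time-series CSV
#'
#' Reads delimited text with one header row, time in the first column and one
#' column of OD readings per well, the layout produced by common
#' turbidometric readers' CSV exports. Two dialects are supported:
#' \code{"generic"} expects decimal hours in the time column;
#' \code{"bioscreen"} additionally accepts clock strings \code{hh:mm:ss},
#' converted to hours. Cells that do not parse as numbers become missing
#' readings (\code{NA}). The delimiter is the comma with a decimal point;
#' semicolon-delimited exports are rejected with an explicit message rather
#' than auto-detected.
#'
#' @param source Path to a CSV file, or a connection.
#' @param dialect \code{"generic"} or \code{"bioscreen"}.
#' @return A [PlateTimeSeries-class] with wells in header order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time,W1,W2", "0,0.1,0.1", "1,0.11,0.12"), f)
#' readTimeseriesCsv(f)
#' @export
readTimeseriesCsv <- function(source, dialect = c("generic", "bioscreen")) {
  dialect <- match.arg(dialect)
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    stopFormat("empty file: no header row found")
  if (!grepl(",", lines[1]) && grepl(";", lines[1]))
    stopFormat(paste("semicolon-delimited input detected; this reader accepts",
                     "comma-delimited files with decimal points only"))
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (length(header) < 2)
    stopFormat("header must name a time column and at least one well")
  wells <- header[-1]
  if (anyDuplicated(wells))
    stopFormat(sprintf("duplicate well header '%s'", wells[duplicated(wells)][1]))
  if (length(lines) == 1)
    stopFormat("header-only file: no data rows")

  body <- strsplit(lines[-1], ",", fixed = TRUE)
  nc <- length(header)
  tm <- numeric(length(body))
  od <- matrix(NA_real_, nrow = length(body), ncol = length(wells),
               dimnames = list(NULL, wells))
  for (i in seq_along(body)) {
    row <- trimws(body[[i]])
    length(row) <- nc  # short rows padded with NA
    tm[i] <- parseTimeCell(row[1], dialect, i + 1)
    od[i, ] <- suppressWarnings(as.numeric(row[-1]))
  }
  bad <- which(diff(tm) <= 0)
  if (length(bad))
    stopFormat(sprintf("time not strictly increasing at line %d (t = %g)",
                       bad[1] + 2, tm[bad[1] + 1]))
  PlateTimeSeries(time = tm, od = od)
}

parseTimeCell <- function(cell, dialect, rowNum) {
  if (is.na(cell) || !nzchar(cell))
    stopFormat(sprintf("missing time value at data row %d", rowNum))
  if (dialect == "bioscreen" && grepl(":", cell, fixed = TRUE)) {
    parts <- suppressWarnings(as.numeric(strsplit(cell, ":", fixed = TRUE)[[1]]))
    if (length(parts) != 3 || anyNA(parts))
      stopFormat(sprintf("cannot parse clock time '%s' at data row %d", cell, rowNum))
    return(parts[1] + parts[2] / 60 + parts[3] / 3600)
  }
  val <- suppressWarnings(as.numeric(cell))
  if (is.na(val))
    stopFormat(sprintf("cannot parse time value '%s' at data row %d", cell, rowNum))
  val
}

#' Write a plate time series as generic-dialect CSV
#'
#' Emits the generic dialect: one header row \code{time,<well1>,...}, time in
#' decimal hours in the first column, missing readings as empty cells.
#' Written files round-trip through [readTimeseriesCsv()].
#'
#' @param plate A [PlateTimeSeries-class].
#' @param sink Output path or connection.
#' @return Invisibly, \code{sink}.
#' @export
writeTimeseriesCsv <- function(plate, sink) {
  stopifnot(methods::is(plate, "PlateTimeSeries"))
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.15g", x))
  header <- paste(c("time", wellIds(plate)), collapse = ",")
  rows <- apply(cbind(plateTime(plate), plateOD(plate)), 1L,
                function(r) paste(fmt(r), collapse = ","))
  writeLines(c(header, rows), con = sink)
  invisible(sink)
}

#' Read a plate-layout configuration
#'
#' Reads a YAML layout mapping wells to their experimental annotation. The
#' file holds a \code{wells:} sequence (or a bare sequence) of entries with
#' keys \code{well}, \code{strain}, \code{substrate}, \code{system},
#' \code{replicate} and optionally \code{edge_well}, \code{lid_removed},
#' \code{wavelength_nm}. Substrate and system must come from the closed
#' vocabularies in [substrateLevels()] and [systemLevels()]. Well labels are
#' opaque strings; both \code{"Well 111"} (100-well honeycomb) and
#' \code{"A1"} (96-well) styles pass through unmodified.
#'
#' @param source Path to a YAML file, or a YAML string.
#' @return Annotation \code{data.frame}, one row per well.
#' @export
readLayout <- function(source) {
  cfg <- if (is.character(source) && length(source) == 1 && file.exists(source))
    yaml::read_yaml(source)
  else yaml::yaml.load(paste(source, collapse = "\n"))
  if (!is.null(cfg$wells)) cfg <- cfg$wells
  if (is.null(cfg) || length(cfg) == 0) return(emptyAnnotations())
  if (!is.list(cfg[[1]]))
    stopConfig("layout must be a sequence of well entries")
  rows <- lapply(seq_along(cfg), function(i) {
    e <- cfg[[i]]
    for (key in c("well", "strain", "substrate", "system", "replicate"))
      if (is.null(e[[key]]))
        stopConfig(sprintf("layout entry %d: missing key '%s'", i, key))
    if (!e$substrate %in% substrateLevels())
      stopConfig(sprintf("unknown substrate token '%s' (well %s)", e$substrate, e$well))
    if (!e$system %in% systemLevels())
      stopConfig(sprintf("unknown system token '%s' (well %s)", e$system, e$well))
    rep <- as.integer(e$replicate)
    if (is.na(rep) || rep < 1)
      stopConfig(sprintf("replicate must be a positive integer (well %s)", e$well))
    data.frame(
      well = as.character(e$well), strain = as.character(e$strain),
      substrate = e$substrate, system = e$system, replicate = rep,
      edge_well = isTRUE(e$edge_well), lid_removed = isTRUE(e$lid_removed),
      wavelength_nm = if (is.null(e$wavelength_nm)) NA_real_ else as.numeric(e$wavelength_nm),
      stringsAsFactors = FALSE
    )
  })
  ann <- do.call(rbind, rows)
  if (anyDuplicated(ann$well))
    stopConfig(sprintf("well '%s' listed twice in layout",
                       ann$well[duplicated(ann$well)][1]))
  ann
}
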