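emptyAnnotations <- function() {
  data.frame(
    well = character(0), strain = character(0), substrate = character(0),
    system = character(0), replicate = integer(0), edge_well = logical(0),
    lid_removed = logical(0), wavelength_nm = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' PlateTimeSeries: a plate of optical-density time courses
#'
#' Container for plate-reader output: a shared, strictly increasing time
#' vector (hours) and a matrix of OD readings with one column per well.
#' Missing readings are \code{NA}. Negative readings are retained (instrument
#' blanks can dip below zero); downstream log transforms floor them and flag
#' the well. Optional per-well annotations carry strain, substrate,
#' cultivation system, replicate number, and edge-well / lid-removal flags.
#'
#' @slot time Numeric vector of sampling times in hours, strictly increasing.
#' @slot od Numeric matrix, \code{length(time)} rows, one named column per
#'   well; \code{NA} marks missing readings.
#' @slot annotations A \code{data.frame} with one row per annotated well and
#'   columns \code{well}, \code{strain}, \code{substrate}, \code{system},
#'   \code{replicate}, \code{edge_well}, \code{lid_removed},
#'   \code{wavelength_nm}; may have zero rows.
#'
#' @seealso [readTimeseriesCsv()], [simulatePlate()], [analyzePlate()]
#' @export
setClass("PlateTimeSeries",
  slots = c(time = "numeric", od = "matrix", annotations = "data.frame"),
  prototype = prototype(
    time = numeric(0),
    od = matrix(numeric(0), nrow = 0, ncol = 0),
    annotations = emptyAnnotations()
  )
)

setValidity("PlateTimeSeries", function(object) {
  msg <- character(0)
  tm <- object@time
  od <- object@od
  if (length(tm) != nrow(od))
    msg <- c(msg, "length(time) must equal nrow(od)")
  if (length(tm) && any(!is.finite(tm)))
    msg <- c(msg, "time must be finite")
  if (length(tm) > 1 && any(diff(tm) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (ncol(od) > 0) {
    ids <- colnames(od)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
      msg <- c(msg, "every well needs a non-empty label (colnames(od))")
    else if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate well label '%s'", ids[duplicated(ids)][1]))
  }
  if (any(!is.finite(od) & !is.na(od)))
    msg <- c(msg, "non-missing od values must be finite")
  ann <- object@annotations
  need <- c("well", "strain", "substrate", "system", "replicate",
            "edge_well", "lid_removed", "wavelength_nm")
  if (!all(need %in% names(ann)))
    msg <- c(msg, paste("annotations must have columns:", paste(need, collapse = ", ")))
  else if (nrow(ann)) {
    if (anyDuplicated(ann$well))
      msg <- c(msg, "annotations: duplicated well")
    bad <- setdiff(ann$substrate, substrateLevels())
    if (length(bad))
      msg <- c(msg, sprintf("unknown substrate '%s'", bad[1]))
    bad <- setdiff(ann$system, systemLevels())
    if (length(bad))
      msg <- c(msg, sprintf("unknown system '%s'", bad[1]))
  }
  if (length(msg)) msg else TRUE
})

#' SmoothedCurve: a fitted penalized cubic smoothing spline
#'
#' A cubic smoothing spline (or, at smoothing factor 0, its natural-cubic
#' interpolation limit) fitted to one well's series, evaluable with first and
#' second derivatives on the observation interval only; evaluation outside
#' \code{[tMin, tMax]} is an error (no extrapolation).
#'
#' @slot fit The underlying \code{smooth.spline} fit.
#' @slot smoothingFactor Smoothing factor on the 0--1 scale.
#' @slot scale Either \code{"log"} (fitted to log OD ratios) or \code{"od"}.
#' @slot tMin,tMax Observation interval bounds (hours).
#'
#' @seealso [fitSmoothingSpline()], [evalCurve()]
#' @export
setClass("SmoothedCurve",
  slots = c(fit = "ANY", smoothingFactor = "numeric", scale = "character",
            tMin = "numeric", tMax = "numeric")
)

setValidity("SmoothedCurve", function(object) {
  msg <- character(0)
  s <- object@smoothingFactor
  if (length(s) != 1 || is.na(s) || s < 0 || s > 1)
    msg <- c(msg, "smoothingFactor must be a single number in [0, 1]")
  if (!object@scale %in% c("log", "od"))
    msg <- c(msg, "scale must be 'log' or 'od'")
  if (object@tMin >= object@tMax)
    msg <- c(msg, "tMin must be < tMax")
  if (length(msg)) msg else TRUE
})

#' GrowthComparison: ANOVA plus protected Fisher-LSD letter display
#'
#' Result of comparing a growth metric (specific growth rate or maximum OD)
#' across substrate groups within one strain and cultivation system: group
#' summaries (n, mean, SEM, letters), the one-way ANOVA, and the pairwise
#' LSD significance matrix. Two groups share a letter if and only if their
#' pairwise comparison is not significant.
#'
#' @slot groups \code{data.frame} with columns \code{group}, \code{n},
#'   \code{mean}, \code{sem}, \code{letters}.
#' @slot anovaF,anovaP One-way ANOVA F statistic and p value.
#' @slot mse Pooled within-group (error) mean square.
#' @slot dfError Error degrees of freedom.
#' @slot alpha Significance level used for the LSD tests.
#' @slot pairwise Logical matrix of pairwise significance (TRUE = the two
#'   groups differ), symmetric with a FALSE diagonal.
#'
#' @seealso [fisherLsdLetters()]
#' @export
setClass("GrowthComparison",
  slots = c(groups = "data.frame", anovaF = "numeric", anovaP = "numeric",
            mse = "numeric", dfError = "numeric", alpha = "numeric",
            pairwise = "matrix")
)

setValidity("GrowthComparison", function(object) {
  msg <- character(0)
  pw <- object@pairwise
  if (nrow(pw) != ncol(pw) || !isTRUE(all(pw == t(pw))))
    msg <- c(msg, "pairwise must be a symmetric matrix")
  else if (nrow(pw) && any(diag(pw)))
    msg <- c(msg, "pairwise diagonal must be FALSE")
  if (nrow(object@groups) != nrow(pw))
    msg <- c(msg, "groups rows must match pairwise dimension")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})
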