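#' Construct a PlateTimeSeries
#'
#' @param time Numeric vector of sampling times in hours, strictly increasing.
#' @param od Numeric matrix of OD readings with \code{length(time)} rows; if
#'   it has no column names, \code{wellIds} must be supplied.
#' @param wellIds Optional character vector of well labels, one per column of
#'   \code{od}; overrides existing column names.
#' @param annotations Optional annotation \code{data.frame} as described in
#'   [PlateTimeSeries-class]; rows are matched to wells by the \code{well}
#'   column. Defaults to no annotations.
#'
#' @return A validated [PlateTimeSeries-class] object.
#' @examples
#' p <- PlateTimeSeries(time = c(0, 1, 2),
#'                      od = cbind(W1 = c(0.1, 0.12, 0.2)))
#' plateTime(p)
#' @export
PlateTimeSeries <- function(time, od, wellIds = NULL, annotations = NULL) {
  od <- as.matrix(od)
  storage.mode(od) <- "double"
  if (!is.null(wellIds)) colnames(od) <- as.character(wellIds)
  if (is.null(annotations)) annotations <- emptyAnnotations()
  methods::new("PlateTimeSeries", time = as.numeric(time), od = od,
               annotations = annotations)
}

#' @rdname plateKinetics-accessors
setMethod("plateTime", "PlateTimeSeries", function(x) x@time)

#' @rdname plateKinetics-accessors
setMethod("plateOD", "PlateTimeSeries", function(x) x@od)

#' @rdname plateKinetics-accessors
setMethod("wellIds", "PlateTimeSeries", function(x) colnames(x@od))

#' @rdname plateKinetics-accessors
setMethod("nWells", "PlateTimeSeries", function(x) ncol(x@od))

#' @rdname plateKinetics-accessors
setMethod("wellAnnotations", "PlateTimeSeries", function(x) x@annotations)

#' @rdname plateKinetics-accessors
setMethod("wellAnnotations<-", "PlateTimeSeries", function(x, value) {
  x@annotations <- value
  methods::validObject(x)
  x
})

setMethod("show", "PlateTimeSeries", function(object) {
  tm <- object@time
  cat(sprintf("PlateTimeSeries: %d wells x %d time points\n",
              ncol(object@od), length(tm)))
  if (length(tm))
    cat(sprintf("  time: %.3g .. %.3g h\n", tm[1], tm[length(tm)]))
  nMiss <- sum(is.na(object@od))
  if (nMiss) cat(sprintf("  missing readings: %d\n", nMiss))
  if (nrow(object@annotations))
    cat(sprintf("  annotated wells: %d\n", nrow(object@annotations)))
  invisible(NULL)
})

#' Subset a plate by wells
#'
#' @param x A [PlateTimeSeries-class].
#' @param i Well labels or column indices.
#' @param j,...,drop Ignored.
#' @return A [PlateTimeSeries-class] with the selected wells (annotations
#'   restricted to them).
#' @export
setMethod("[", "PlateTimeSeries", function(x, i, j, ..., drop = FALSE) {
  od <- x@od[, i, drop = FALSE]
  ann <- x@annotations
  ann <- ann[ann$well %in% colnames(od), , drop = FALSE]
  rownames(ann) <- NULL
  methods::new("PlateTimeSeries", time = x@time, od = od, annotations = ann)
})

# Per-well series with missing readings dropped.
wellSeries <- function(plate, well) {
  od <- plate@od[, well]
  keep <- !is.na(od)
  list(time = plate@time[keep], od = unname(od[keep]))
}
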