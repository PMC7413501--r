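# Classed conditions so callers (and tests) can distinguish failure modes
# without matching on message text.

pkError <- function(class, msg, ...) {
  structure(
    class = c(class, "pkError", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
}

stopFormat <- function(msg, ...) stop(pkError("pkFormatError", msg, ...))
stopConfig <- function(msg, ...) stop(pkError("pkConfigError", msg, ...))
stopParam  <- function(msg, ...) stop(pkError("pkParamError", msg, ...))
stopData   <- function(msg, ...) stop(pkError("pkDataError", msg, ...))
stopInsufficient <- function(msg, ...) stop(pkError("pkInsufficientDataError", msg, ...))
stopDegenerate   <- function(msg, ...) stop(pkError("pkDegenerateVarianceError", msg, ...))

#' Closed vocabularies for well annotations
#'
#' Substrates and cultivation systems form closed vocabularies: the four
#' carbon sources used in the plate assays plus the no-added-carbon control,
#' and the two cultivation systems (BSC, a 100-well honeycomb-plate
#' turbidometric reader; Cph, 96-well plates in an automated plate hotel).
#'
#' @return Character vector of allowed tokens.
#' @export
substrateLevels <- function() c("glucose", "xylose", "galactose", "glycerol", "no_carbon")

#' @rdname substrateLevels
#' @export
systemLevels <- function() c("BSC", "Cph")

# Run an expression with a private, seeded RNG stream; the caller's RNG state
# is untouched.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
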