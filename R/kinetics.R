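# Evaluation grid for extrema: a regular grid over the observation interval
# plus the spline knots, so narrow features at knots are not missed.
curveGrid <- function(curve, nGrid = 2001L) {
  f <- curve@fit$fit
  knots <- f$knot * f$range + f$min
  g <- c(seq(curve@tMin, curve@tMax, length.out = nGrid),
         pmin(pmax(knots, curve@tMin), curve@tMax))
  sort(unique(g))
}

#' Maximum specific growth rate from a log-scale smoothed curve
#'
#' The maximum specific growth rate is the maximum of the first derivative
#' of the smoothing spline fitted to log-transformed OD, taken over the
#' entire observation interval (a regular grid of \code{nGrid} points plus
#' the spline knots) — no subjective choice of an exponential window. Ties
#' (a flat derivative, e.g. pure exponential growth) are broken by the
#' earliest time.
#'
#' @param curve A [SmoothedCurve-class] on the log scale.
#' @param nGrid Grid resolution (default 2001).
#' @return List with \code{mu} (h^-1) and \code{tMu} (h).
#' @examples
#' tm <- seq(0, 100, 0.5)
#' crv <- fitSmoothingSpline(tm, 0.05 * tm, s = 0.3, scale = "log")
#' muMax(crv)  # mu = 0.05 at tMu = 0
#' @export
muMax <- function(curve, nGrid = 2001L) {
  if (curve@scale != "log")
    stopParam("muMax requires a curve fitted on the log scale")
  g <- curveGrid(curve, nGrid)
  d <- evalCurve(curve, g, deriv = 1L)
  top <- max(d)
  tol <- 1e-8 * max(abs(top), 1e-8)
  i <- which(d >= top - tol)[1]  # earliest-time tie-break
  list(mu = d[i], tMu = g[i])
}

#' Lag time by the tangent method
#'
#' The lag phase ends where the tangent to the log-OD curve at the point of
#' maximum slope crosses the baseline level \eqn{z = 0}:
#' \eqn{lag = t_\mu - f(t_\mu)/\mu}, clamped to \code{[0, tMu]}. When growth
#' is below \code{muFloor} the tangent is ill-defined and the lag is
#' reported absent (\code{NA}).
#'
#' @param curve A [SmoothedCurve-class] on the log scale.
#' @param mu,tMu Maximum specific growth rate and its time, from [muMax()].
#' @param muFloor Minimum rate (h^-1) for which a lag is reported
#'   (default 0.005).
#' @return Lag in hours, or \code{NA} when \code{mu < muFloor}.
#' @export
lagTime <- function(curve, mu, tMu, muFloor = 0.005) {
  if (is.na(mu) || mu < muFloor) return(NA_real_)
  lag <- tMu - evalCurve(curve, tMu) / mu
  min(max(lag, 0), tMu)
}

#' Maximum OD from a smoothed raw-OD curve
#'
#' Maximum of the smoothing spline fitted to the raw OD series over the full
#' observation interval. Evaporation-inflated tails are deliberately not
#' trimmed; edge-well annotation travels with the results so such wells can
#' be judged downstream.
#'
#' @param time,od Numeric vectors (hours, OD).
#' @param s Smoothing factor in \code{[0, 1]}.
#' @param nGrid Grid resolution (default 2001).
#' @return Maximum fitted OD.
#' @export
maxOD <- function(time, od, s, nGrid = 2001L) {
  keep <- !is.na(od)
  crv <- fitSmoothingSpline(time[keep], od[keep], s = s, scale = "od")
  max(evalCurve(crv, curveGrid(crv, nGrid)))
}

#' Default per-well analysis options
#'
#' @param baselineK Initial readings averaged into the log-transform baseline.
#' @param floorEps Relative floor for non-positive OD before the log.
#' @param muFloor Minimum rate (h^-1) below which lag is absent and the well
#'   is flagged \code{nonpositive_growth}.
#' @param gapFactor A gap is flagged when an inter-sample interval exceeds
#'   \code{gapFactor} times the median interval (default 5; a power outage of
#'   tens of hours against a 0.5 h cadence is ~100x).
#' @param despike Remove isolated positive spikes (rolling-median detector,
#'   [detectSpikes()]) before fitting (default TRUE).
#' @param despikeWindow,despikeK Detector parameters.
#' @param fewPointsMin Wells with fewer retained readings are flagged
#'   \code{few_points}.
#' @return Named list of options.
#' @export
kineticsOptions <- function(baselineK = 3L, floorEps = 1e-6, muFloor = 0.005,
                            gapFactor = 5, despike = TRUE, despikeWindow = 5L,
                            despikeK = 6, fewPointsMin = 10L) {
  list(baselineK = baselineK, floorEps = floorEps, muFloor = muFloor,
       gapFactor = gapFactor, despike = despike, despikeWindow = despikeWindow,
       despikeK = despikeK, fewPointsMin = fewPointsMin)
}

#' Analyze one well: growth rate, lag, maximum OD
#'
#' Runs the per-well estimation chain: drop missing readings, flag sampling
#' gaps, log-transform against the initial baseline, remove isolated
#' positive spikes, fit the smoothing spline, locate the maximum specific
#' growth rate over the whole record, derive the tangent-method lag, and fit
#' the raw-OD spline for the maximum OD. Estimation failures (too few
#' points, non-positive baseline) yield a failure record rather than an
#' error, so one bad well never aborts a plate.
#'
#' @param time,od Numeric vectors (hours, OD); \code{od} may contain
#'   \code{NA}.
#' @param s Smoothing factor in \code{[0, 1]}; the field practice is 0.3 for
#'   clean, well-growing wells and 0.7 for noisy or poorly growing wells.
#' @param options See [kineticsOptions()].
#' @param well Optional well label carried into the result.
#' @return One-row \code{data.frame} with columns \code{well},
#'   \code{mu_max}, \code{t_mu}, \code{lag}, \code{max_od},
#'   \code{smoothing_factor}, \code{n_points}, \code{n_spikes},
#'   \code{qc_flags} (semicolon-joined), \code{ok}, \code{reason}.
#' @examples
#' tm <- seq(0, 240, 0.5)
#' od <- 0.1 * exp(gompertzLogCurve(2, 0.05, 50, tm))
#' analyzeWell(tm, od, s = 0.3)
#' @export
analyzeWell <- function(time, od, s, options = kineticsOptions(), well = NA_character_) {
  res <- data.frame(well = well, mu_max = NA_real_, t_mu = NA_real_,
                    lag = NA_real_, max_od = NA_real_, smoothing_factor = s,
                    n_points = NA_integer_, n_spikes = 0L, qc_flags = "",
                    ok = FALSE, reason = "", stringsAsFactors = FALSE)
  keep <- !is.na(od)
  tm <- time[keep]; y <- od[keep]
  res$n_points <- length(y)
  flags <- character(0)
  if (length(tm) > 2) {
    dt <- diff(tm)
    if (any(dt > options$gapFactor * stats::median(dt)))
      flags <- c(flags, "gap_detected")
  }
  if (length(y) < options$fewPointsMin) flags <- c(flags, "few_points")

  out <- tryCatch({
    lt <- logTransform(tm, y, baselineK = options$baselineK,
                       floorEps = options$floorEps)
    if (lt$floored) flags <- c(flags, "negative_od_floored")
    z <- lt$z
    drop <- if (isTRUE(options$despike))
      detectSpikes(z, window = options$despikeWindow, k = options$despikeK)
    else integer(0)
    res$n_spikes <- length(drop)
    if (length(drop)) { tm2 <- tm[-drop]; z2 <- z[-drop]; y2 <- y[-drop] }
    else { tm2 <- tm; z2 <- z; y2 <- y }
    zc <- fitSmoothingSpline(tm2, z2, s = s, scale = "log")
    mm <- muMax(zc)
    res$mu_max <- mm$mu
    res$t_mu <- mm$tMu
    if (mm$mu < options$muFloor) flags <- c(flags, "nonpositive_growth")
    res$lag <- lagTime(zc, mm$mu, mm$tMu, muFloor = options$muFloor)
    res$max_od <- maxOD(tm2, y2, s = s)
    res$ok <- TRUE
    res
  }, pkError = function(e) {
    res$reason <- conditionMessage(e)
    res
  })
  out$qc_flags <- paste(flags, collapse = ";")
  out
}

#' Analyze every well of a plate
#'
#' Applies [analyzeWell()] to each well, using a per-well smoothing factor
#' resolved from \code{smoothing}: a single number, a named vector keyed by
#' well, or a function of the well's annotation row returning a factor (the
#' conventional policy is 0.7 for poorly growing or noisy wells and 0.3 for
#' clean, well-growing ones). Annotations, when present, are merged into the
#' result.
#'
#' @param plate A [PlateTimeSeries-class].
#' @param smoothing Smoothing policy (default 0.3).
#' @param options See [kineticsOptions()].
#' @return \code{data.frame} with one row per well (kinetics columns plus
#'   any annotation columns).
#' @export
analyzePlate <- function(plate, smoothing = 0.3, options = kineticsOptions()) {
  stopifnot(methods::is(plate, "PlateTimeSeries"))
  ann <- wellAnnotations(plate)
  sFor <- function(w) {
    if (is.function(smoothing)) {
      row <- ann[match(w, ann$well), , drop = FALSE]
      smoothing(row)
    } else if (!is.null(names(smoothing))) {
      if (!w %in% names(smoothing))
        stopConfig(sprintf("no smoothing factor given for well '%s'", w))
      unname(smoothing[[w]])
    } else as.numeric(smoothing)
  }
  rows <- lapply(wellIds(plate), function(w) {
    od <- plateOD(plate)[, w]
    analyzeWell(plateTime(plate), od, s = sFor(w), options = options, well = w)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (nrow(ann)) {
    res <- merge(res, ann, by = "well", all.x = TRUE, sort = FALSE)
    res <- res[match(wellIds(plate), res$well), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Write per-well kinetics results as CSV
#'
#' @param results Output of [analyzePlate()].
#' @param sink Path or connection.
#' @return Invisibly, \code{sink}.
#' @export
writeKineticsCsv <- function(results, sink) {
  utils::write.csv(results, sink, row.names = FALSE, na = "")
  invisible(sink)
}
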