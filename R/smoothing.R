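#' Log-transform an OD series against its initial baseline
#'
#' Computes \eqn{z_i = \ln(\max(y_i, \epsilon y_0) / y_0)} where \eqn{y_0} is
#' the mean of the first \code{baselineK} non-missing readings. The specific
#' growth rate is the slope of log biomass, so all rate estimation happens on
#' this scale. Non-positive readings (possible after blank subtraction or
#' from instrument noise) are floored at \code{floorEps * y0} and flagged
#' rather than silently edited.
#'
#' @param time Numeric vector of sampling times (hours); only its length is
#'   checked here, evaluation is element-wise on \code{od}.
#' @param od Numeric OD vector, no missing values.
#' @param baselineK Number of initial readings averaged into the baseline
#'   \eqn{y_0} (default 3).
#' @param floorEps Relative floor applied before taking logs (default 1e-6).
#' @return List with \code{z} (the transformed series), \code{y0}, and
#'   \code{floored} (TRUE if any reading was floored).
#' @examples
#' tm <- 0:10
#' logTransform(tm, 0.1 * exp(0.05 * tm))$z  # equals 0.05 * tm (approx)
#' @export
logTransform <- function(time, od, baselineK = 3L, floorEps = 1e-6) {
  if (floorEps <= 0) stopParam("floorEps must be positive")
  if (length(od) < baselineK)
    stopInsufficient(sprintf("need at least %d readings, got %d", baselineK, length(od)))
  if (anyNA(od)) stopData("od must not contain missing values (drop them first)")
  y0 <- mean(od[seq_len(baselineK)])
  if (y0 <= 0) stopData("baseline OD (mean of initial readings) must be positive")
  floorVal <- floorEps * y0
  floored <- any(od < floorVal)
  list(z = log(pmax(od, floorVal) / y0), y0 = y0, floored = floored)
}

#' Detect isolated positive spikes with a rolling median
#'
#' Pellets of mycelium drifting through the light path produce isolated
#' positive spikes in OD traces. This detector compares each reading with the
#' median of its centred window: for a monotone (or any locally median-
#' preserving) series the deviation is exactly zero, so clean noiseless
#' curves are untouched; an isolated spike deviates by roughly its own
#' height. Readings whose deviation exceeds
#' \code{k * 1.4826 * median(|deviation|)} (one-sided, positive only, with a
#' small absolute floor for numerically clean data) are flagged.
#'
#' @param values Numeric series (typically log-scale OD).
#' @param window Odd window width for the rolling median (default 5).
#' @param k Threshold in robust standard deviations (default 6).
#' @param floorAbs Absolute deviation floor (default 1e-6), so that exact
#'   curves yield no detections.
#' @return Integer vector of spike indices (possibly empty).
#' @export
detectSpikes <- function(values, window = 5L, k = 6, floorAbs = 1e-6) {
  n <- length(values)
  if (n < window) return(integer(0))
  h <- window %/% 2L
  med <- vapply(seq_len(n), function(i)
    stats::median(values[max(1L, i - h):min(n, i + h)]), numeric(1))
  dev <- values - med
  sig <- 1.4826 * stats::median(abs(dev))
  which(dev > max(k * sig, floorAbs))
}

#' Fit a penalized cubic smoothing spline with a 0--1 smoothing factor
#'
#' Fits the minimiser of
#' \deqn{\sum_i (y_i - f(t_i))^2 + \lambda(s) \int f''(u)^2 du}
#' with the penalty mapped from the user-facing smoothing factor
#' \eqn{s \in [0,1]} as \eqn{\lambda(s) = r \cdot 256^{3s - 1}}, where
#' \eqn{r} is the data-dependent ratio of the traces of the fidelity and
#' penalty Gram forms (so that mid-scale \eqn{s} balances the two terms).
#' This is the standard 0--1 smoothing-parameter convention of
#' \code{smooth.spline} (its \code{spar}), shared by the growth-curve
#' packages built on it, so factors like 0.3 and 0.7 behave as practitioners
#' expect.
#' \eqn{s = 0} is taken to the interpolation limit (a vanishing penalty,
#' giving the natural cubic interpolant to numerical precision on modest
#' series); \eqn{s = 1} approaches the least-squares line.
#'
#' The fit is computed by \code{\link[stats]{smooth.spline}} with all data
#' points as knots; its internal penalty parameterisation realises exactly
#' the mapping above.
#'
#' @param time Numeric times (hours); at least 4 distinct values.
#' @param values Numeric response, same length.
#' @param s Smoothing factor in \code{[0, 1]}.
#' @param scale \code{"log"} or \code{"od"}: which variable was fitted.
#' @return A [SmoothedCurve-class].
#' @examples
#' tm <- seq(0, 10, 0.5)
#' crv <- fitSmoothingSpline(tm, 2 + 3 * tm, s = 0.7)
#' evalCurve(crv, 5)            # 17
#' evalCurve(crv, 5, deriv = 1) # 3
#' @export
fitSmoothingSpline <- function(time, values, s, scale = c("od", "log")) {
  scale <- match.arg(scale)
  if (length(s) != 1 || is.na(s) || s < 0 || s > 1)
    stopParam("smoothing factor s must be a single number in [0, 1]")
  keep <- !is.na(values)
  time <- time[keep]; values <- values[keep]
  if (length(unique(time)) < 4)
    stopInsufficient("need at least 4 distinct time points to fit a cubic smoothing spline")
  fit <- if (s > 0) {
    stats::smooth.spline(time, values, spar = s, all.knots = TRUE,
                         keep.data = FALSE)
  } else {
    # interpolation limit: a vanishing penalty strictly below lambda(s) for
    # any s > 0, keeping roughness monotone in s
    probe <- stats::smooth.spline(time, values, spar = 0, all.knots = TRUE,
                                  keep.data = FALSE)
    r <- probe$lambda * 256
    lam0 <- max(min(1e-12, r * 256^-1 * 1e-3), 1e-15)
    stats::smooth.spline(time, values, lambda = lam0, all.knots = TRUE,
                         keep.data = FALSE)
  }
  methods::new("SmoothedCurve", fit = fit, smoothingFactor = s, scale = scale,
               tMin = min(time), tMax = max(time))
}

#' @describeIn evalCurve Evaluates the fitted spline strictly within the
#'   observation interval; extrapolation is refused.
setMethod("evalCurve", "SmoothedCurve", function(curve, t, deriv = 0L) {
  if (any(t < curve@tMin - 1e-9) || any(t > curve@tMax + 1e-9))
    stopParam(sprintf("evaluation outside the observation interval [%g, %g] h",
                      curve@tMin, curve@tMax))
  stats::predict(curve@fit, pmin(pmax(t, curve@tMin), curve@tMax),
                 deriv = as.integer(deriv))$y
})

#' @describeIn curveRoughness Trapezoidal approximation on an \code{nGrid}
#'   grid; non-increasing in the smoothing factor for a fixed series.
setMethod("curveRoughness", "SmoothedCurve", function(curve, nGrid = 4001L) {
  g <- seq(curve@tMin, curve@tMax, length.out = nGrid)
  d2 <- evalCurve(curve, g, deriv = 2L)
  sum((d2[-1]^2 + d2[-nGrid]^2) / 2 * diff(g))
})

#' @rdname plateKinetics-accessors
setMethod("smoothingFactor", "SmoothedCurve", function(x) x@smoothingFactor)

#' @rdname plateKinetics-accessors
setMethod("curveScale", "SmoothedCurve", function(x) x@scale)

setMethod("show", "SmoothedCurve", function(object) {
  cat(sprintf("SmoothedCurve (%s scale): s = %.3g on [%.3g, %.3g] h\n",
              object@scale, object@smoothingFactor, object@tMin, object@tMax))
  invisible(NULL)
})
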