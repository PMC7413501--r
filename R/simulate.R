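#' Zwietering-Gompertz growth curve on the log scale
#'
#' \deqn{z(t) = A \exp(-\exp(\frac{\mu e}{A}(\lambda - t) + 1))}
#' the reparameterised Gompertz form whose parameters are exactly the
#' quantities growth-curve analysis estimates: \eqn{\mu} is the maximum
#' slope of \eqn{z(t)} (the maximum specific growth rate, h^-1),
#' \eqn{\lambda} is the intercept of the tangent at that point with
#' \eqn{z = 0} (the lag time, h), and \eqn{A} is the asymptote
#' \eqn{\ln(OD_{plateau}/OD_{baseline})}. This makes parameter-recovery
#' tests of the spline pipeline sharp: the generator's \eqn{\mu} and
#' \eqn{\lambda} are the estimator's own definitions.
#'
#' @param A Log-scale asymptote, > 0.
#' @param mu Maximum specific growth rate (h^-1), >= 0.
#' @param lam Lag time (h).
#' @param t Numeric times (h).
#' @return \eqn{z(t)}, dimensionless.
#' @examples
#' gompertzLogCurve(2, 0.05, 40, c(40, 1000))  # A*exp(-e) at lag, ~A late
#' @export
gompertzLogCurve <- function(A, mu, lam, t) {
  if (length(A) != 1 || is.na(A) || A <= 0) stopParam("A must be a positive number")
  if (mu < 0) stopParam("mu must be non-negative")
  A * exp(-exp((mu * exp(1) / A) * (lam - t) + 1))
}

#' Specification of one simulated well
#'
#' Groups the growth parameters and measurement-artifact settings for a
#' simulated well. Artifact defaults emulate the documented phenomenology of
#' microtiter-plate fungal cultivations: Gaussian read noise; sparse
#' positive spikes from mycelial pellets drifting through the light path;
#' linear OD inflation in evaporating edge wells late in the run; a constant
#' offset from lid condensation; and an optional data-collection gap.
#'
#' @param mu_true Maximum specific growth rate (h^-1).
#' @param lag_true Lag time (h).
#' @param A_true Log-scale asymptote \eqn{\ln(OD_{plateau}/OD_{baseline})}.
#' @param baseline_od Baseline OD (> 0).
#' @param noise_sd Gaussian noise standard deviation, OD units.
#' @param spike_prob Per-reading probability of a positive spike.
#' @param spike_amp_max Maximum spike amplitude (OD); amplitudes are
#'   Uniform(0, spike_amp_max).
#' @param evap_rate Evaporation-driven OD inflation (OD/h) applied after
#'   \code{evap_onset}.
#' @param evap_onset Onset of evaporation inflation (h, default 80).
#' @param condensation_offset Constant additive OD offset from lid
#'   condensation.
#' @param gap Optional \code{c(t_start, t_end)}: readings strictly inside
#'   this open interval are missing (e.g. a power outage).
#' @param sampling_interval Sampling cadence (h): 0.5 for the 100-well
#'   turbidometric reader, 2--3 for the plate-hotel detector.
#' @param duration Total run length (h, default 240 = 10 days).
#' @return Named list of class \code{"wellSpec"}.
#' @export
wellSpec <- function(mu_true = 0.05, lag_true = 50, A_true = log(0.8 / 0.1),
                     baseline_od = 0.1, noise_sd = 0, spike_prob = 0,
                     spike_amp_max = 0.3, evap_rate = 0, evap_onset = 80,
                     condensation_offset = 0, gap = NULL,
                     sampling_interval = 0.5, duration = 240) {
  spec <- list(mu_true = mu_true, lag_true = lag_true, A_true = A_true,
               baseline_od = baseline_od, noise_sd = noise_sd,
               spike_prob = spike_prob, spike_amp_max = spike_amp_max,
               evap_rate = evap_rate, evap_onset = evap_onset,
               condensation_offset = condensation_offset, gap = gap,
               sampling_interval = sampling_interval, duration = duration)
  validateWellSpec(spec)
  class(spec) <- "wellSpec"
  spec
}

validateWellSpec <- function(s) {
  if (s$mu_true < 0) stopParam("mu_true must be >= 0")
  if (s$lag_true < 0) stopParam("lag_true must be >= 0")
  if (s$A_true <= 0) stopParam("A_true must be > 0")
  if (s$baseline_od <= 0) stopParam("baseline_od must be > 0")
  if (s$spike_prob < 0 || s$spike_prob > 1) stopParam("spike_prob must be in [0, 1]")
  if (s$duration <= s$lag_true) stopParam("duration must exceed lag_true")
  if (!is.null(s$gap) && (length(s$gap) != 2 || s$gap[1] >= s$gap[2]))
    stopParam("gap must be c(t_start, t_end) with t_start < t_end")
  invisible(TRUE)
}

#' Simulate one well's OD time course
#'
#' Samples \code{0, dt, 2dt, ..., duration}, removes readings inside the
#' gap, and builds
#' \code{od = baseline_od * exp(z(t)) + noise + spikes + evaporation +
#' condensation} with \code{z} the Zwietering-Gompertz log curve. Fully
#' reproducible from \code{seed}; the caller's RNG state is untouched.
#'
#' @param spec A [wellSpec()].
#' @param seed Integer seed.
#' @return List with \code{time}, \code{od} and \code{truth}
#'   (\code{mu_true}, \code{lag_true},
#'   \code{max_od_true = baseline_od * exp(A_true)}).
#' @examples
#' w <- simulateWell(wellSpec(mu_true = 0.07, lag_true = 40), seed = 1)
#' analyzeWell(w$time, w$od, s = 0.3)
#' @export
simulateWell <- function(spec, seed = 1L) {
  validateWellSpec(spec)
  tm <- seq(0, spec$duration, by = spec$sampling_interval)
  if (!is.null(spec$gap))
    tm <- tm[tm <= spec$gap[1] | tm >= spec$gap[2]]
  z <- gompertzLogCurve(spec$A_true, spec$mu_true, spec$lag_true, tm)
  od <- withSeed(seed, {
    base <- spec$baseline_od * exp(z)
    base <- base + stats::rnorm(length(tm), 0, spec$noise_sd)
    hit <- stats::runif(length(tm)) < spec$spike_prob
    base[hit] <- base[hit] + stats::runif(sum(hit), 0, spec$spike_amp_max)
    base + spec$evap_rate * pmax(0, tm - spec$evap_onset) +
      spec$condensation_offset
  })
  list(time = tm, od = od,
       truth = list(mu_true = spec$mu_true, lag_true = spec$lag_true,
                    max_od_true = spec$baseline_od * exp(spec$A_true)))
}

#' Default plate-simulation scenarios
#'
#' Ready-made scenarios for the two cultivation systems. \code{"BSC"}
#' emulates the 100-well turbidometric reader: 0.5 h sampling for 240 h,
#' 5 replicates per group, low read noise, rare spikes, no edge effects.
#' \code{"Cph"} emulates 96-well plates in an automated plate hotel read
#' every 3 h: 4 replicates, higher noise, 2% spikes of up to 0.3 OD,
#' evaporation inflation in edge wells after 80 h, and a condensation
#' offset when lids stay on. Between-replicate variability is lognormal on
#' \code{mu_true} and \code{A_true} with the given coefficient of variation.
#' Group growth parameters follow the published range for marine fungi on
#' the four substrates (glucose the preferred substrate, no-carbon controls
#' lowest, lags 30--100 h).
#'
#' @param system \code{"BSC"} or \code{"Cph"}.
#' @param strain Strain label used in annotations.
#' @return Scenario list consumable by [simulatePlate()].
#' @export
defaultScenario <- function(system = c("BSC", "Cph"), strain = "strainA") {
  system <- match.arg(system)
  pars <- list(  # mu (h^-1), lag (h), plateau OD per substrate
    glucose   = list(mu = 0.07, lag = 40, plateau = 0.8),
    xylose    = list(mu = 0.05, lag = 50, plateau = 0.6),
    galactose = list(mu = 0.04, lag = 55, plateau = 0.5),
    glycerol  = list(mu = 0.02, lag = 70, plateau = 0.3),
    no_carbon = list(mu = 0.01, lag = 80, plateau = 0.15)
  )
  bsc <- system == "BSC"
  groups <- lapply(names(pars), function(sb) {
    p <- pars[[sb]]
    list(strain = strain, substrate = sb,
         n_replicates = if (bsc) 5L else 4L,
         spec = wellSpec(
           mu_true = p$mu * (if (bsc) 1 else 1.5),
           lag_true = p$lag + (if (bsc) 0 else 20),
           A_true = log(p$plateau / 0.1), baseline_od = 0.1,
           noise_sd = if (bsc) 0.004 else 0.02,
           spike_prob = if (bsc) 0.005 else 0.02,
           spike_amp_max = if (bsc) 0.1 else 0.3,
           sampling_interval = if (bsc) 0.5 else 3,
           duration = 240
         ))
  })
  list(system = system, groups = groups,
       replicate_cv = if (bsc) 0.15 else 0.4,
       edge_evap_rate = if (bsc) 0 else 0.001,
       condensation_offset = if (bsc) 0 else 0.05,
       lid_removed = bsc, wavelength_nm = if (bsc) 600 else 595)
}

#' Simulate a whole annotated plate with ground truth
#'
#' Builds a [PlateTimeSeries-class] from a scenario: for each group
#' (strain x substrate) the requested number of replicate wells is drawn,
#' with lognormal between-replicate variation of the given coefficient of
#' variation on \code{mu_true} and \code{A_true}. In plate-hotel scenarios
#' wells are laid out row-major on the 96-well grid (A1..H12) and outer
#' wells are marked edge wells and receive the scenario's evaporation rate;
#' the 100-well system uses \code{"Well 101"}-style labels and no edge
#' effects. Deterministic given \code{seed}.
#'
#' @param scenario Scenario list (see [defaultScenario()]), or a path to /
#'   string of YAML with the same structure.
#' @param seed Integer seed.
#' @return List with \code{plate} (annotated [PlateTimeSeries-class]) and
#'   \code{truth} (\code{data.frame}: well, mu_true, lag_true, max_od_true).
#' @export
simulatePlate <- function(scenario, seed = 1L) {
  if (is.character(scenario)) scenario <- readScenario(scenario)
  if (is.null(scenario$groups) || !length(scenario$groups))
    stopConfig("scenario must define at least one group")
  system <- if (is.null(scenario$system)) "BSC" else scenario$system
  if (!system %in% systemLevels())
    stopConfig(sprintf("unknown system token '%s'", system))
  cv <- if (is.null(scenario$replicate_cv)) 0 else scenario$replicate_cv
  cph <- system == "Cph"

  nTot <- sum(vapply(scenario$groups, function(g)
    as.integer(if (is.null(g$n_replicates)) if (cph) 4L else 5L else g$n_replicates), 0L))
  if (cph && nTot > 96) stopConfig("scenario needs more than 96 wells")
  wellLabel <- function(i) {
    if (cph) sprintf("%s%d", LETTERS[(i - 1) %/% 12 + 1], (i - 1) %% 12 + 1)
    else sprintf("Well %d", 100 + i)
  }
  isEdge <- function(i) {
    if (!cph) return(FALSE)
    row <- (i - 1) %/% 12 + 1; col <- (i - 1) %% 12 + 1
    row %in% c(1, 8) || col %in% c(1, 12)
  }

  odCols <- list(); ann <- NULL; truth <- NULL; timeRef <- NULL
  idx <- 0L
  for (gi in seq_along(scenario$groups)) {
    g <- scenario$groups[[gi]]
    nRep <- as.integer(if (is.null(g$n_replicates)) if (cph) 4L else 5L else g$n_replicates)
    base <- if (inherits(g$spec, "wellSpec")) g$spec else do.call(wellSpec, g$spec)
    for (r in seq_len(nRep)) {
      idx <- idx + 1L
      wid <- wellLabel(idx)
      edge <- isEdge(idx)
      wseed <- (as.integer(seed) * 1009L + idx * 101L) %% 2147483629L
      spec <- base
      if (cv > 0) {
        # lognormal multipliers; for A_true the multiplier acts on the
        # plateau/baseline OD ratio exp(A), keeping simulated max OD in the
        # instrument's realistic range
        mult <- withSeed(wseed + 7L,
                         exp(stats::rnorm(2, -cv^2 / 2, cv)))
        spec$mu_true <- spec$mu_true * mult[1]
        spec$A_true <- max(spec$A_true + log(mult[2]), 0.05)
      }
      if (edge && !is.null(scenario$edge_evap_rate))
        spec$evap_rate <- scenario$edge_evap_rate
      if (!is.null(scenario$condensation_offset) && !isTRUE(scenario$lid_removed))
        spec$condensation_offset <- scenario$condensation_offset
      w <- simulateWell(spec, seed = wseed)
      if (is.null(timeRef)) timeRef <- w$time
      else if (!isTRUE(all.equal(timeRef, w$time)))
        stopConfig("all groups in one plate must share sampling times")
      odCols[[wid]] <- w$od
      ann <- rbind(ann, data.frame(
        well = wid, strain = g$strain, substrate = g$substrate,
        system = system, replicate = r, edge_well = edge,
        lid_removed = isTRUE(scenario$lid_removed),
        wavelength_nm = if (is.null(scenario$wavelength_nm)) NA_real_
                        else scenario$wavelength_nm,
        stringsAsFactors = FALSE
      ))
      truth <- rbind(truth, data.frame(
        well = wid, mu_true = spec$mu_true, lag_true = spec$lag_true,
        max_od_true = spec$baseline_od * exp(spec$A_true),
        stringsAsFactors = FALSE
      ))
    }
  }
  od <- do.call(cbind, odCols)
  plate <- PlateTimeSeries(time = timeRef, od = od, annotations = ann)
  list(plate = plate, truth = truth)
}

#' Read a scenario configuration from YAML
#'
#' Same structured plain-text dialect as the plate layout: top-level keys
#' \code{system}, \code{replicate_cv}, \code{edge_evap_rate},
#' \code{condensation_offset}, \code{lid_removed}, \code{wavelength_nm} and
#' a \code{groups} sequence of \code{strain}/\code{substrate}/
#' \code{n_replicates}/\code{spec} entries, where \code{spec} holds
#' [wellSpec()] fields.
#'
#' @param source YAML path or string.
#' @return Scenario list.
#' @export
readScenario <- function(source) {
  cfg <- if (length(source) == 1 && file.exists(source)) yaml::read_yaml(source)
         else yaml::yaml.load(paste(source, collapse = "\n"))
  if (is.null(cfg$groups)) stopConfig("scenario YAML must have a 'groups' sequence")
  for (g in cfg$groups) {
    if (is.null(g$strain) || is.null(g$substrate))
      stopConfig("each scenario group needs 'strain' and 'substrate'")
    if (!g$substrate %in% substrateLevels())
      stopConfig(sprintf("unknown substrate token '%s'", g$substrate))
  }
  cfg
}

#' Write ground truth as CSV
#'
#' @param truth Ground-truth \code{data.frame} from [simulatePlate()].
#' @param sink Path or connection.
#' @return Invisibly, \code{sink}.
#' @export
writeGroundTruthCsv <- function(truth, sink) {
  utils::write.csv(truth, sink, row.names = FALSE)
  invisible(sink)
}
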