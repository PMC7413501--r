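test_that("the Gompertz log curve has its defining landmarks", {
  # value at the lag time is A * exp(-e) for any (mu, lam)
  for (p in list(c(2, 0.05, 40), c(1, 0.27, 100), c(3, 0.01, 30))) {
    z <- gompertzLogCurve(p[1], p[2], p[3], p[3])
    expect_equal(z, p[1] * exp(-exp(1)), tolerance = 1e-12)
  }
  # asymptote
  expect_equal(gompertzLogCurve(2, 0.05, 40, 1e6), 2, tolerance = 1e-9)
  expect_error(gompertzLogCurve(-1, 0.05, 40, 0), class = "pkParamError")
})

test_that("the curve's max slope is mu and its tangent intercept is lam (finite differences)", {
  tg <- seq(0, 400, length.out = 200001)
  h <- tg[2] - tg[1]
  for (p in list(c(2, 0.07, 40), c(2, 0.27, 100), c(1.5, 0.03, 60))) {
    z <- gompertzLogCurve(p[1], p[2], p[3], tg)
    d <- diff(z) / h
    i <- which.max(d)
    expect_equal(max(d), p[2], tolerance = 1e-4)
    tmid <- (tg[i] + tg[i + 1]) / 2
    zmid <- gompertzLogCurve(p[1], p[2], p[3], tmid)
    expect_equal(tmid - zmid / max(d), p[3], tolerance = 1e-3)
  }
})

test_that("simulateWell is seed-deterministic and leaves the caller's RNG alone", {
  spec <- wellSpec(mu_true = 0.07, lag_true = 40, noise_sd = 0.01,
                   spike_prob = 0.02)
  w1 <- simulateWell(spec, seed = 4)
  w2 <- simulateWell(spec, seed = 4)
  expect_identical(w1, w2)
  w3 <- simulateWell(spec, seed = 5)
  expect_false(identical(w1$od, w3$od))

  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulateWell(spec, seed = 4)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("an artifact-free well is the exact curve and its parameters are recovered", {
  spec <- wellSpec(mu_true = 0.05, lag_true = 50, A_true = log(8),
                   baseline_od = 0.1)
  w <- simulateWell(spec, seed = 1)
  expect_equal(w$od,
               0.1 * exp(gompertzLogCurve(log(8), 0.05, 50, w$time)),
               tolerance = 1e-12)
  # max observed od approaches baseline * exp(A) (finite-duration gap only)
  expect_equal(max(w$od), w$truth$max_od_true, tolerance = 1e-4)
  r <- analyzeWell(w$time, w$od, s = 0.3)
  expect_equal(r$mu_max, 0.05, tolerance = 0.05 * 0.05)
  expect_equal(r$lag, 50, tolerance = 2)
  expect_equal(r$max_od, 0.8, tolerance = 0.02)
})

test_that("the outage gap removes exactly the readings inside the interval", {
  spec <- wellSpec(gap = c(110, 160))
  w <- simulateWell(spec, seed = 1)
  expect_false(any(w$time > 110 & w$time < 160))
  expect_true(any(w$time == 110) && any(w$time == 160))
})

test_that("artifact terms act as documented", {
  base <- simulateWell(wellSpec(), seed = 1)$od
  # condensation: constant additive offset
  off <- simulateWell(wellSpec(condensation_offset = 0.05), seed = 1)$od
  expect_equal(off - base, rep(0.05, length(base)), tolerance = 1e-12)
  # evaporation: linear inflation after onset only
  w <- simulateWell(wellSpec(evap_rate = 0.002, evap_onset = 80), seed = 1)
  extra <- w$od - base
  expect_equal(extra[w$time <= 80], rep(0, sum(w$time <= 80)), tolerance = 1e-12)
  expect_equal(extra[w$time > 80], 0.002 * (w$time[w$time > 80] - 80),
               tolerance = 1e-12)
  # spikes are positive-only
  sp <- simulateWell(wellSpec(spike_prob = 0.05, spike_amp_max = 0.3), seed = 2)
  expect_true(all(sp$od - base >= 0))
  expect_true(any(sp$od - base > 0))
  expect_true(all(sp$od - base <= 0.3))
})

test_that("simulatePlate counts wells, fills annotations and ground truth", {
  scen <- defaultScenario("BSC")
  scen$groups <- scen$groups[1:2]
  scen$groups[[1]]$n_replicates <- 3L
  scen$groups[[2]]$n_replicates <- 3L
  sim <- simulatePlate(scen, seed = 1)
  expect_equal(nWells(sim$plate), 6)
  expect_equal(nrow(sim$truth), 6)
  ann <- wellAnnotations(sim$plate)
  expect_equal(nrow(ann), 6)
  expect_true(all(ann$system == "BSC"))
  expect_false(any(ann$edge_well))  # honeycomb plates: no edge modelling
  # sampling follows the turbidometric-reader protocol
  expect_equal(plateTime(sim$plate), seq(0, 240, 0.5))
})

test_that("Cph plates mark edge wells on the 96-well perimeter and inflate them", {
  scen <- defaultScenario("Cph")
  sim <- simulatePlate(scen, seed = 1)
  ann <- wellAnnotations(sim$plate)
  expect_true(all(grepl("^[A-H][0-9]+$", ann$well)))
  expect_true(all(ann$edge_well[substr(ann$well, 1, 1) == "A"]))
  expect_equal(plateTime(sim$plate), seq(0, 240, 3))
})

test_that("zero replicate CV and zero noise give identical replicates", {
  scen <- defaultScenario("BSC")
  scen$replicate_cv <- 0
  for (i in seq_along(scen$groups)) {
    scen$groups[[i]]$spec$noise_sd <- 0
    scen$groups[[i]]$spec$spike_prob <- 0
  }
  sim <- simulatePlate(scen, seed = 1)
  od <- plateOD(sim$plate)
  ann <- wellAnnotations(sim$plate)
  for (sb in unique(ann$substrate)) {
    cols <- ann$well[ann$substrate == sb]
    expect_equal(matrixStats <- apply(od[, cols, drop = FALSE], 1, function(r)
      max(r) - min(r)), rep(0, nrow(od)), tolerance = 0)
  }
})

test_that("plate-hotel replicates are noisier than turbidometric-reader replicates", {
  relSem <- function(system, seed) {
    sim <- simulatePlate(defaultScenario(system), seed = seed)
    res <- analyzePlate(sim$plate, smoothing = 0.7)
    ann <- wellAnnotations(sim$plate)
    out <- c()
    for (sb in unique(ann$substrate)) {
      v <- res$mu_max[res$ok & res$substrate == sb]
      if (length(v) >= 3 && mean(v) > 0)
        out <- c(out, (sd(v) / sqrt(length(v))) / mean(v))
    }
    mean(out)
  }
  # averaged over seeded runs, relative SEM is clearly larger in the hotel
  expect_gt(mean(sapply(1:3, function(s) relSem("Cph", s))),
            mean(sapply(1:3, function(s) relSem("BSC", s))))
})

test_that("scenario YAML round-trips through readScenario and simulatePlate", {
  y <- "
system: BSC
replicate_cv: 0
groups:
  - strain: S1
    substrate: glucose
    n_replicates: 2
    spec: {mu_true: 0.07, lag_true: 40, A_true: 2.0, baseline_od: 0.1}
  - strain: S1
    substrate: no_carbon
    n_replicates: 2
    spec: {mu_true: 0.01, lag_true: 80, A_true: 0.4, baseline_od: 0.1}
"
  sim <- simulatePlate(readScenario(y), seed = 1)
  expect_equal(nWells(sim$plate), 4)
  expect_setequal(unique(wellAnnotations(sim$plate)$substrate),
                  c("glucose", "no_carbon"))
  bad <- "groups:\n  - {strain: S1, substrate: lactose}"
  expect_error(readScenario(bad), class = "pkConfigError", regexp = "lactose")
})
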