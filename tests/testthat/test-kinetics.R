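test_that("logTransform implements the baseline-ratio log with flooring", {
  tm <- 0:10
  od <- 0.2 * exp(0.05 * (0:10))
  lt <- logTransform(tm, od)
  # y0 is the mean of the first 3 readings, so z is the exact log ratio to it
  expect_equal(lt$z, log(od / mean(od[1:3])), tolerance = 1e-12)
  expect_false(lt$floored)

  expect_equal(logTransform(tm, rep(0.3, 11))$z, rep(0, 11), tolerance = 1e-12)

  od2 <- rep(0.3, 11); od2[6] <- 0
  lt2 <- logTransform(tm, od2, floorEps = 1e-6)
  expect_true(lt2$floored)
  expect_equal(lt2$z[6], log(1e-6), tolerance = 1e-9)

  expect_error(logTransform(0:1, c(0.1, 0.2)), class = "pkInsufficientDataError")
  expect_error(logTransform(0:4, c(-0.2, -0.1, 0, 0.1, 0.2)), class = "pkDataError")
})

test_that("a line is fitted exactly at any smoothing factor", {
  tm <- seq(0, 10, 0.5)
  y <- 2 + 3 * tm
  for (s in c(0, 0.3, 0.7, 1)) {
    crv <- fitSmoothingSpline(tm, y, s = s)
    expect_lt(max(abs(evalCurve(crv, tm) - y)), 1e-6)
    expect_lt(max(abs(evalCurve(crv, tm, deriv = 1) - 3)), 1e-6)
  }
})

test_that("s = 0 reaches the interpolation limit and matches a natural-spline oracle", {
  tm <- 0:9
  y <- 0.5 + 0.3 * tm - 0.05 * tm^2 + 0.01 * tm^3
  crv <- fitSmoothingSpline(tm, y, s = 0)
  expect_lt(max(abs(evalCurve(crv, tm) - y)), 1e-6)
  oracle <- splinefun(tm, y, method = "natural")
  expect_lt(max(abs(evalCurve(crv, tm) - oracle(tm))), 1e-6)

  # also on noisy data: the s=0 fit passes through the observations
  set.seed(3)
  yn <- y + rnorm(10, 0, 0.3)
  crv2 <- fitSmoothingSpline(tm, yn, s = 0)
  expect_lt(max(abs(evalCurve(crv2, tm) - yn)), 1e-6)
  expect_lt(max(abs(evalCurve(crv2, tm) - splinefun(tm, yn, method = "natural")(tm))), 1e-6)
})

test_that("fit preconditions are enforced", {
  expect_error(fitSmoothingSpline(0:2, c(1, 2, 3), s = 0.3),
               class = "pkInsufficientDataError")
  expect_error(fitSmoothingSpline(0:9, rnorm(10), s = 1.2),
               class = "pkParamError")
  crv <- fitSmoothingSpline(0:9, rnorm(10), s = 0.3)
  expect_error(evalCurve(crv, 10.5), class = "pkParamError")
})

test_that("roughness is non-increasing in the smoothing factor", {
  set.seed(1)
  tm <- seq(0, 240, 0.5)
  y <- gompertzLogCurve(2, 0.07, 50, tm) + rnorm(length(tm), 0, 0.05)
  rough <- vapply(seq(0, 1, length.out = 10), function(s)
    curveRoughness(fitSmoothingSpline(tm, y, s = s)), 0)
  expect_true(all(diff(rough) <= rough[-10] * 1e-8 + 1e-12))
})

test_that("muMax finds rate and time with earliest-time tie-break", {
  tm <- seq(0, 100, 0.5)
  crv <- fitSmoothingSpline(tm, 0.05 * tm, s = 0.3, scale = "log")
  mm <- muMax(crv)
  expect_equal(mm$mu, 0.05, tolerance = 1e-6)
  expect_equal(mm$tMu, 0)  # constant slope: tie broken at the earliest time

  flat <- fitSmoothingSpline(tm, rep(1.3, length(tm)), s = 0.3, scale = "log")
  expect_equal(muMax(flat)$mu, 0, tolerance = 1e-9)

  odc <- fitSmoothingSpline(tm, 0.05 * tm, s = 0.3, scale = "od")
  expect_error(muMax(odc), class = "pkParamError")
})

test_that("muMax recovers the generating rate of a noiseless Gompertz curve", {
  w <- gompertzWell(mu = 0.07, lam = 40)
  z <- logTransform(w$time, w$od)$z
  crv <- fitSmoothingSpline(w$time, z, s = 0.3, scale = "log")
  mm <- muMax(crv)
  expect_equal(mm$mu, 0.07, tolerance = 0.05)
})

test_that("lagTime implements the tangent construction", {
  tm <- seq(0, 100, 0.5)
  crv <- fitSmoothingSpline(tm, 0.05 * tm, s = 0.3, scale = "log")
  mm <- muMax(crv)
  expect_equal(lagTime(crv, mm$mu, mm$tMu), 0, tolerance = 1e-6)

  w <- gompertzWell(mu = 0.07, lam = 40)  # A = 2 by default
  z <- logTransform(w$time, w$od)$z
  zc <- fitSmoothingSpline(w$time, z, s = 0.3, scale = "log")
  mm <- muMax(zc)
  expect_equal(lagTime(zc, mm$mu, mm$tMu), 40, tolerance = 2)

  # no growth: lag absent
  flat <- fitSmoothingSpline(tm, rep(0, length(tm)), s = 0.3, scale = "log")
  fm <- muMax(flat)
  expect_true(is.na(lagTime(flat, fm$mu, fm$tMu)))
})

test_that("maxOD takes the smoothed maximum and suppresses lone spikes", {
  tm <- seq(0, 100, 0.5)
  od <- 0.9 * (1 / (1 + exp(-(tm - 50) / 8))) / (1 / (1 + exp(-50 / 8)))
  expect_equal(maxOD(tm, od, s = 0.3), 0.9, tolerance = 1e-3)

  tm2 <- seq(0, 20, 1)
  od2 <- rep(0.2, 21); od2[10] <- 0.7
  expect_lt(maxOD(tm2, od2, s = 0.7), 0.5)

  expect_equal(maxOD(tm2, rep(0.42, 21), s = 0.7), 0.42, tolerance = 1e-9)
})

test_that("analyzeWell composes the chain and flags artifacts", {
  w <- gompertzWell(mu = 0.05, lam = 50, A = log(0.8 / 0.1))
  r <- analyzeWell(w$time, w$od, s = 0.3)
  expect_true(r$ok)
  expect_equal(r$mu_max, 0.05, tolerance = 0.05 * 0.05)
  expect_equal(r$lag, 50, tolerance = 2)
  expect_equal(r$max_od, 0.8, tolerance = 0.02)
  expect_equal(r$n_points, 481L)
  expect_equal(r$qc_flags, "")

  # data-collection outage: no readings in (110, 160) h
  keep <- w$time <= 110 | w$time >= 160
  r2 <- analyzeWell(w$time[keep], w$od[keep], s = 0.3)
  expect_match(r2$qc_flags, "gap_detected")

  # too few readings yields a failure record, not an error
  r3 <- analyzeWell(c(0, 1, 2), c(0.1, 0.1, 0.1), s = 0.3)
  expect_false(r3$ok)
  expect_match(r3$reason, "4 distinct time points|readings")

  # no growth
  r4 <- analyzeWell(w$time, rep(0.1, length(w$time)), s = 0.7)
  expect_match(r4$qc_flags, "nonpositive_growth")
  expect_true(is.na(r4$lag))
})

test_that("rolling-median despiking removes lone spikes, leaves clean curves alone", {
  w <- gompertzWell(mu = 0.27, lam = 30)
  z <- logTransform(w$time, w$od)$z
  expect_length(detectSpikes(z), 0)  # exact no-op on a monotone curve

  zs <- z
  hit <- c(30, 200, 350)
  zs[hit] <- zs[hit] + 1
  expect_setequal(detectSpikes(zs), hit)
})

test_that("scaling OD leaves mu and lag invariant and scales max OD", {
  w <- gompertzWell(mu = 0.07, lam = 40)
  r1 <- analyzeWell(w$time, w$od, s = 0.3)
  for (c0 in c(0.37, 5)) {
    r2 <- analyzeWell(w$time, c0 * w$od, s = 0.3)
    expect_equal(r2$mu_max, r1$mu_max, tolerance = 1e-9)
    expect_equal(r2$lag, r1$lag, tolerance = 1e-9)
    expect_equal(r2$max_od, c0 * r1$max_od, tolerance = 1e-9)
  }
})

test_that("shifting the time axis shifts t_mu and lag, leaves mu unchanged", {
  w <- gompertzWell(mu = 0.07, lam = 40)
  r1 <- analyzeWell(w$time, w$od, s = 0.3)
  for (shift in c(5, 24)) {
    r2 <- analyzeWell(w$time + shift, w$od, s = 0.3)
    expect_equal(r2$mu_max, r1$mu_max, tolerance = 1e-9)
    expect_equal(r2$t_mu, r1$t_mu + shift, tolerance = 1e-9)
    expect_equal(r2$lag, r1$lag + shift, tolerance = 1e-9)
  }
})
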