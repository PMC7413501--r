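---
title: "Growth kinetics from microtiter-plate OD time series: methods and design"
author: "plateKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth kinetics from microtiter-plate OD time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateKinetics)
```

## The problem

High-throughput characterisation of slow-growing microbes — here,
filamentous marine fungi — is done in microtiter plates read
turbidometrically: a 100-well honeycomb-plate incubator-reader ("BSC",
OD600 every 0.5 h for up to 10 days) or 96-well plates in an automated
plate hotel ("Cph", OD595 every 2–3 h). The readouts of interest per well
are the maximum specific growth rate $\mu_{max}$ (h$^{-1}$), the lag-phase
duration (h), and the maximum OD reached. The raw traces are noisy in
characteristic ways: mycelial pellets drifting through the light path cause
isolated positive spikes; evaporation inflates late readings in edge wells;
condensation on lids adds an offset; power outages leave multi-hour gaps.
This package estimates the three readouts robustly from such traces,
aggregates replicates into the publication-style strain-by-substrate tables
(mean ± SEM with compact significance letters), and ships a seeded simulator
with exact ground truth so every stage is verifiable by parameter recovery.

## Per-well estimation

**Log transform.** The specific growth rate is the slope of log biomass, so
estimation happens on $z_i = \ln(y_i / y_0)$, with $y_0$ the mean of the
first `baselineK = 3` readings. Non-positive readings (instrument blanks
can dip below zero) are floored at $10^{-6} y_0$ and the well is flagged
`negative_od_floored` rather than silently edited. A baseline of three
readings rather than one averages out read noise without eating into the
lag phase at either cadence.

**Despiking.** Pellet spikes are isolated, positive, and large relative to
read noise. Before fitting, each log reading is compared with the median of
its centred 5-point window; for a locally monotone series this deviation is
exactly zero, so clean curves are untouched (an important property: the
despiker cannot bias noiseless data). Readings deviating by more than
$6 \times 1.4826\,\mathrm{med}|d|$ (one-sided, with an absolute floor of
$10^{-6}$) are removed. A window of 5 still catches the occasional pair of
adjacent spikes, while a run of three or more spiked readings — essentially
never produced by pellet transit at these cadences — would be kept. We
despike rather than rely on the penalty alone because no fixed roughness
penalty can both flatten a $\times 4$ log-scale spike at baseline OD and
preserve the ~8 h rise of the fastest observed wells: smoothing strong
enough for the former has an equivalent-kernel bandwidth of tens of hours
and halves the latter's estimated rate. The removal count is reported per
well (`n_spikes`).

**Smoothing spline.** The despiked series is fitted with a cubic smoothing
spline minimising
$$\sum_i (z_i - f(t_i))^2 + \lambda(s) \int f''(u)^2\,du,$$
with the penalty mapped from a user-facing smoothing factor $s \in [0,1]$
as $\lambda(s) = r\,256^{3s-1}$, where $r$ is the ratio of the traces of
the fidelity and penalty Gram forms, so mid-scale $s$ balances the two
terms. This is the standard 0–1 smoothing-parameter convention of
`smooth.spline` (its `spar`), shared by the growth-curve packages built on
it, so the field's habitual factors behave as expected: $s = 0.3$ for
clean, well-growing wells; $s = 0.7$ for noisy or poorly growing wells
(and, in practice, for all plate-hotel data). We examined a lighter
alternative ($\lambda = r\,256^{3s-1.5}$) and rejected it: at $s = 0.7$
under realistic read noise (sd 0.004 OD, 0.5 h cadence) it inflates
max-derivative rate estimates several-fold on near-zero-growth wells,
because the maximum of a barely-smoothed noisy derivative is an extreme
statistic. $s = 0$ is special-cased to the interpolation limit (a penalty
of $\min(10^{-12}, \lambda(0)/1000)$, floored at $10^{-15}$), which keeps
roughness monotone in $s$ and makes the $s = 0$ fit agree with the natural
cubic interpolant to numerical precision on modest series. All data points
serve as knots. There is deliberately no automatic (cross-validated)
choice of $s$: the smoothing factor is an analyst-declared policy, kept
config-driven per group.

**Rate, lag, maximum OD.** $\mu_{max}$ is the maximum of $f'(t)$ over the
entire observation interval — no subjective exponential-phase window —
evaluated on a 2001-point regular grid plus the spline knots, with ties
broken by the earliest time (so a pure exponential reports its rate at
$t_{min}$). The lag is the tangent construction: the intercept of the
tangent at $t_\mu$ with the baseline level $z = 0$,
$\mathrm{lag} = t_\mu - f(t_\mu)/\mu$, clamped to $[0, t_\mu]$. When
$\mu < 0.005$ h$^{-1}$ the tangent is numerically meaningless and the lag
is reported absent with a `nonpositive_growth` flag; the floor sits well
below the smallest published rates (0.01 h$^{-1}$) but above derivative
noise on flat wells. Maximum OD is the maximum of a spline fitted to the
raw (despiked) OD at the same $s$, over the full record: evaporation-
inflated tails are *not* trimmed, because edge-well inflation is a property
of the well that should be visible in the result, carried alongside the
`edge_well` annotation, rather than silently corrected. Sampling gaps
(any interval exceeding 5× the median cadence — a power outage is ~100×)
are flagged `gap_detected`; missing readings are dropped, never
interpolated. A well with fewer than 4 distinct usable time points yields
a per-well failure record rather than an exception, so one bad well never
aborts a plate.

### A known limitation of the tangent lag

The tangent lag is referenced to the *observed* baseline $y_0$. When a
culture is already measurably above its (unobservable) lower asymptote at
the first reading — slow growth combined with a short lag — every
baseline-referenced estimator carries a positive bias of $z(0)/\mu$, where
$z(0)$ is the log-scale head start. For Zwietering–Gompertz growth with
$A = 2$, $\mu = 0.01$ h$^{-1}$ and a 30 h lag this bias is ≈ 3.4 h; it
decays rapidly with longer lags or faster growth (≈ 0.5 h at a 60 h lag)
and is negligible across the rest of the operating range. Removing it
would require extrapolating a parametric growth model below the window,
which this package deliberately does not do (the spline route is the whole
point; parametric forms live only in the simulator).

## Replicate statistics

Within each strain × system row, metric values are compared across
substrate groups by one-way fixed-effects ANOVA (via `stats::aov`),
followed — only when the ANOVA is significant at $\alpha$ (protected
design) — by all pairwise Fisher least-significant-difference tests in the
unbalanced form
$$|m_i - m_j| > t_{1-\alpha/2,\ df_e}\sqrt{MSE\,(1/n_i + 1/n_j)},$$
appropriate for the typical 3–6 replicates per group. The pairwise
significance pattern is encoded as a compact letter display by the
insert-and-absorb algorithm, which guarantees that two groups share a
letter if and only if they do not differ significantly; letters are
assigned from the smallest mean upward, so the no-added-carbon controls —
ordinarily the lowest groups — carry "a". "Fisher's multiple range test"
in the applied-microbiology literature most often means exactly this
protected LSD; Duncan's multiple range test is a documented alternative we
did not implement, and boundary pairs could differ between the two.
Between the two cultivation systems, the same strain × substrate cell is
compared by a classical equal-variance two-sided Student $t$ test
($\alpha = 0.05$) and significant differences are starred in the display
table. Failed wells are excluded listwise with counts logged. No
multiple-testing correction is applied across strains or metrics, matching
standard practice for these tables. Display cells round to 2 decimals;
the CSV outputs keep full precision.

## The simulator

Wells are generated from the Zwietering–Gompertz log curve
$$z(t) = A \exp\!\big(-\exp\!\big(\tfrac{\mu e}{A}(\lambda - t) + 1\big)\big),$$
chosen because its parameters *are* the estimands: $\mu$ is the exact
maximum log-slope and $\lambda$ the exact tangent intercept, which makes
recovery tests sharp rather than approximate. OD is
$y_0 e^{z(t)}$ plus, in order: additive Gaussian read noise; isolated
positive spikes (each reading independently with probability
`spike_prob` gains $U(0, \mathrm{amp})$ — positive because a pellet
entering the beam raises OD); linear evaporation inflation after an 80 h
onset in edge wells (edge effects appear mainly in stationary phase);
a constant lid-condensation offset when lids stay on; and an optional
outage gap that removes readings inside an open interval. Between-replicate
biology is a lognormal multiplier (given CV) on $\mu$ and on the
plateau-to-baseline OD ratio. Everything is reproducible from a single
integer seed, with the caller's RNG state untouched.

Default scenarios encode the two systems' documented conditions: BSC —
0.5 h cadence, 240 h, 5 replicates, read noise 0.004 OD, rare small
spikes, no edge effects, replicate CV 0.15 (giving replicate relative SEMs
in the published 4–10% band); Cph — 3 h cadence, 4 replicates, noise
0.02 OD, 2% spikes up to 0.3 OD, edge-well evaporation 0.001 OD/h,
condensation offset 0.05, CV 0.4 (relative SEMs in the published 10–30%
band). Growth parameters default to the published ranges: rates
0.01–0.27 h$^{-1}$, lags 30–100 h, plateau ODs 0.15–0.8 from a 0.1
baseline. The simulator does *not* model oxygen limitation, substrate
depletion, pellet morphology, wall growth, or instrument cross-calibration
(OD600 vs OD595 values are not comparable between systems); recovery tests
passing on simulated plates therefore validate the estimation pipeline
under the documented artifact phenomenology, not the biology of any real
strain.

## Numerical and interface choices

* Time is hours everywhere; the BioScreen dialect's `hh:mm:ss` clock
  strings are converted on read. CSV parsing is deliberately strict:
  comma-delimited, decimal point, one header row, time first; semicolon
  "European" exports are rejected with a clear message instead of being
  auto-detected. Unparseable cells become missing readings.
* Well labels are opaque strings ("Well 111" and "A1" styles both pass
  through). Substrates and systems are closed vocabularies; unknown tokens
  are configuration errors naming the token.
* Derivative maximisation resolution (2001 grid points plus knots) bounds
  the $t_\mu$ quantisation at 0.12 h on a 240 h record, well below every
  tolerance used; ties take the earliest time.
* Evaluating a fitted curve outside its observation interval is an error —
  no extrapolation, anywhere.
* The problem sizes exercised by the shipped tests — single plates of up
  to 25 wells, 481-point traces, recovery grids of 15–75 wells, 100
  randomized letter-display instances, $10^5$-draw permutation checks —
  were chosen as the smallest sizes at which every property is sharply
  testable; the full test suite runs in well under a minute.

## What passing tests do and do not show

The test suite verifies: exact parameter recovery on noiseless simulated
wells across the published rate range; spike robustness at the published
contamination phenomenology; agreement of the letter display with a
brute-force all-pairs oracle and of the $t$ test with a permutation
oracle; scale- and shift-invariance of the estimators; byte-level
determinism of pipeline outputs from a seed; and structural fidelity of
the output tables. It cannot certify numeric agreement with any specific
published table: that would require the original deposited raw traces, and
the original program's exact smoothing-factor-to-penalty mapping is
unpublished (ours is documented above). On near-zero-growth wells under
realistic Gaussian noise, the max-of-derivative statistic sits at a noise
floor and overestimates rates below ~0.01 h$^{-1}$ unless heavy smoothing
is used — the reason the field's rule of thumb assigns such wells
$s = 0.7$.
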