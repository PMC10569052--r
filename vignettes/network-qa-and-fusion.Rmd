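---
title: "Methods: network quality assurance and model fusion for low-cost PM2.5 sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network quality assurance and model fusion for low-cost PM2.5 sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`aqfuse` turns the raw output of a network of low-cost optical PM2.5
sensors (LCS) into corrected observations and fuses them with a gridded
air-quality model field. This vignette is the package's own account of the
methods: the models and their assumptions, the parameters that matter, what
the synthetic generator does and does not emulate, and the design decisions
taken where the method left room.

## The measurement model

A low-cost optical sensor at site $s$ is modelled as reporting, at hour $t$,

$$\mathrm{LCS}_s(t) = g_s\,C(x_s, t) + b_s(w(t)) + \varepsilon_s(t),$$

where $C(x,t)$ is the true concentration, $g_s$ a multiplicative gain
(factory calibration error; for the sensor family targeted here roughly
$1/0.49 \approx 2$ in winter conditions), $b_s(w)$ an additive offset that
wanders from ISO week to ISO week, and $\varepsilon_s$ Gaussian noise whose
standard deviation grows with relative humidity:
$\sigma(t) = \sigma_0\,(1 + c_{\mathrm{rh}}\max(0, \mathrm{RH}-70)/30)$.
Some units additionally drift linearly in time; some fail outright and emit
output unrelated to ambient air. Reference stations measure
$C(x_r, t)$ with small noise.

All timestamps are hour-beginning local standard time; no daylight-saving
arithmetic happens inside the pipeline, because the windows the method uses
(the 00:00–04:59 night window, calendar months, ISO weeks) are local-clock
constructs. Coordinates are projected metric easting/northing, since the
interpolation needs distances in metres.

## The five-step quality assurance scheme

`run_qa()` applies, in order:

1. **Relocation filter.** All records of a registered sensor at or after
   its relocation timestamp are removed: post-move data no longer describe
   the site of interest.
2. **Coverage filter.** A sensor-month with fewer than
   $\min(365, 0.5\times\text{hours in month})$ non-missing hours is removed
   wholesale. The comparison is strict (`<`), so a month with exactly 365
   valid hours survives.
3. **Blind network correlation screen.** Per calendar month, each sensor's
   nighttime (00:00–04:59) hourly series is correlated with the hour-by-hour
   mean of all sensors present. Nighttime is used because local emissions
   (wood burning, traffic) are minimal then, so concentrations approach a
   shared urban background and healthy sensors should track the network
   closely. A sensor-month with $r \le 0.7$ is removed. An alternative
   data-driven threshold ($\mu - 3\sigma$ of the month's $r$ distribution)
   is available via `corr_mode = "mu3sigma"`.
4. **Gain and weekly offset correction.** Every sensor value is multiplied
   by the gain correction (default 0.49, the reciprocal of the colocation
   slope), then for each sensor and ISO week the offset
   $\mathrm{mean}(\mathrm{ref}) - \mathrm{mean}(\text{corrected sensor})$
   over paired hours is added, aligning the sensor's weekly mean with the
   urban background reference station.
5. **Drift assessment.** Per sensor, the nightly bias
   $b(d) = \overline{\mathrm{sensor}}_{night(d)} - \overline{\mathrm{ref}}_{night(d)}$
   is formed from paired night hours; the longest run of consecutive valid
   days is located; runs under 90 days leave the sensor `unassessed`
   (shorter records cannot establish a baseline). Otherwise the run is
   decomposed by singular spectrum analysis into trend, oscillatory and
   remainder components, an OLS line is fitted, and the slope's two-sided
   t-test at $\alpha = 0.05$ yields `drifted`/`nondrifted`. Verdicts are
   annotations only: no data is removed, and the policy for drifted units
   is left to the user.

Design choices where the scheme was open:

* The step-3 network mean **includes** the sensor under test ("all
  sensors' measurements", read literally); `exclude_self = TRUE` is
  available for robustness. With a healthy network of $n \ge 8$ the
  difference is negligible.
* A screening $r$ computed from fewer than 25 paired night hours (about
  five nights) is too noisy to act on; such sensor-months are kept but
  flagged `insufficient-for-screening` rather than removed on noise.
* A zero-variance (constant) sensor series fails the screen: constant
  output is a malfunction signature, and Pearson $r$ is undefined for it.
* Weeks are ISO calendar weeks in local time; "weekly bias" is otherwise
  undefined. Weeks with fewer than 24 paired reference hours are left
  uncorrected and flagged, rather than corrected from a handful of hours.
* Step 5 fits the regression to the **raw** nightly-bias series by
  default. Fitting the smoothed SSA trend (`fit_target = "ssa-trend"`) is
  offered but anticonservative: OLS p-values on a smoothed series
  understate the variance and over-flag drift. The SSA decomposition is
  always reported for inspection.
* The SSA window defaults to $L = \min(30, \lfloor N/3\rfloor)$ days,
  separating longer-than-monthly trend from shorter oscillations.

### Singular spectrum analysis details

`ssa_decompose()` embeds the series in an $L \times (N-L+1)$ Hankel
trajectory matrix, takes the SVD, reconstructs each elementary component by
anti-diagonal averaging, and groups components: the leading component plus
any component whose reconstruction carries at least half its spectral power
at periods longer than $L$ form the trend (a linear trend spreads over two
components, so grouping by frequency rather than rank recovers it whole);
consecutive pairs with singular values equal to within 5% form the
oscillatory group (the sine/cosine pair signature); the rest is remainder.
Because the elementary decomposition is complete, the three grouped series
sum back to the input to numerical precision — a property the test suite
asserts at $10^{-8}$.

## Colocation calibration

`robust_fit()` regresses daily sensor output on daily reference
concentrations by iteratively reweighted least squares with the bisquare
weight $w(u) = (1-(u/c)^2)^2$ for $|u|<c$ (else 0), $c = 4.685$, where $u$
is the residual scaled by $1.4826\times$ the zero-centred median absolute
deviation, re-estimated each iteration — the conventional "default"
behaviour of robust linear fitting. The fit is through the origin by
default: on daily averages the intercept and an RH covariate are typically
statistically insignificant, and the package's own simulation (in the test
suite) confirms that an intercept fitted to origin-through data is
insignificant in the large majority of replicates. Both toggles are
exposed. The reciprocal slope is the correction factor applied in QA
step 4. Convergence is declared when the coefficient change falls below
`tol` (default $10^{-8}$, relative); a numerically perfect fit (MAD scale
collapsing to zero) short-circuits with unit weights. Coefficient
inference comes from the final weighted least-squares fit; the exact
covariance estimator behind robust-regression p-values varies between
implementations, and this choice is simple, reproducible, and adequate for
the significance screening it serves.

The CEN-style measurement uncertainty (`cen_uncertainty()`) fits a normal
distribution to corrected-minus-reference deviations and expresses the
t-based 95% confidence interval relative to the 24 µg/m³ limit value for
continuous PM2.5 measurement. "Dividing the confidence interval by the
limit value" admits two readings — the larger absolute CI bound, or the CI
width — so both are reported (`uncertainty_pct`, `uncertainty_width_pct`)
and neither is privileged.

## Optimal interpolation

`optimal_interpolation()` computes the standard analysis

$$x_a = x_b + \mathbf{B}H^{\top}(H\mathbf{B}H^{\top} + \mathbf{R})^{-1}(y - Hx_b),$$

with $x_b$ the a-priori model field, $H$ nearest-cell sampling by default
(bilinear optional — at 100 m resolution the difference is below sensor
siting error), $\mathbf{R}$ diagonal with per-source variances, and
$\mathbf{B} = \sigma_b^2\,\rho(d)$ an isotropic correlation model,
Gaussian $\rho(d) = e^{-d^2/2L_c^2}$ by default (exponential optional).
Defaults $\sigma_b = 2$ µg/m³ and $L_c = 2000$ m give smooth, localized
corrections at neighborhood scale; both are configuration, not dogma, since
the "right" values depend on the model error structure of the a-priori
field. Observation error defaults encode the trust hierarchy: reference
stations $\sigma_o = 1$ µg/m³, LCS $\sigma_o = 3$ µg/m³, so reference
innovations are weighted more strongly.

Numerics: the innovation system is solved by Cholesky factorization; a
non-positive-definite system raises an error suggesting larger observation
variances. Observations at identical coordinates are merged by
inverse-variance weighting (with a warning) instead of rejected, keeping
the system well conditioned. An optional hard correlation cutoff
(`localization_radius`) zeroes $\rho$ beyond a radius for large grids; it
is off by default and has no effect at the default domain size. The
analysis is unconstrained and can dip marginally below zero where negative
innovations dominate; difference fields (`innovation_stats()$increment`)
are inherently signed, so grids carry a `check_nonneg` switch.

Seasonal observations (`seasonal_observations()`) are means of hourly
PM2.5 over the season; a site qualifies only with at least 75% seasonal
coverage, so a seasonal mean is never built from an unrepresentative
fragment of the winter.

## Leave-one-out cross-validation

`loocv()` re-runs the assimilation once per observation with that
observation withheld and compares observed values with the background and
with the held-out analysis via MB, RMSE and MAE; improvements are
$100\,(|m_{bg}| - |m_{an}|)/|m_{bg}|$, with a zero background metric
reported as undefined rather than divided by. Reference stations
participate exactly like sensors, and summary metrics are emitted both for
all sites (unweighted across the $N$ sites) and for the reference subset
alone.

## The synthetic study conditions

`synth_config()` defines the conditions every end-to-end test runs under;
they emulate a 90-day winter deployment in a small coastal city where
residential wood combustion loads one valley neighborhood:

| parameter | default | rationale |
|---|---|---|
| domain | 40 × 40 cells of 100 m | a 4 × 4 km urban domain at the model's resolution |
| background mean, spatial sd | 8, 1.5 µg/m³ | winter seasonal means of 8–12 µg/m³ at urban background |
| background correlation length | 1000 m | smooth urban background structure |
| hotspot | amplitude 6 µg/m³, radius 600 m | a wood-smoke valley neighborhood |
| model bias fraction | 0.7 | the a-priori field misses ~70% of the hotspot: a deficit of ~4 µg/m³ at its core, the magnitude of correction a seasonal assimilation should recover |
| sensors | 25 LCS, 8 clustered in the hotspot | mirrors a deployment with a dense valley cluster at a few hundred metres spacing |
| gain | mean 1/0.49, sd 0.08 | factory calibration off by ~2 with modest unit-to-unit spread |
| weekly offset sd | 0.75 µg/m³ | slow additive wander |
| hourly noise sd | 1 µg/m³, RH-coupled | high intra-batch consistency of these sensors at winter concentrations |
| diurnal profile | two-Gaussian mixture peaking 10:00 and 19:00, strength 0.4 | the observed bimodal cycle (morning boundary-layer/traffic peak, evening wood-burning peak) with a shallow night trough |
| day-to-day factor | lognormal, sdlog 0.4 | synoptic variability; daily means vary severalfold across a winter |
| hour-to-hour factor | lognormal AR(1), sdlog 0.3, φ = 0.9 | city-wide sub-daily fluctuation shared by all sites — the common signal the blind correlation screen relies on |
| reference noise | 0.5 µg/m³ | reference-grade instruments |
| missingness | 5% | routine telemetry gaps |

The hourly truth at a point is the seasonal field value modulated by the
diurnal profile and the two shared lognormal factors (all mean-one), so
seasonal means of hourly truth equal the seasonal field up to the realized
mean of the factors — a common multiplicative representativeness error of
a few percent that all sites share, as real seasonal averages do.
Relocations, drifters and corrupted (independent-noise) sensors are off by
default and switched on by the tests that target steps 1, 5 and 3
respectively.

What the generator does **not** emulate: physically based dispersion (the
background is a filtered Gaussian field, not a plume model), meteorology
beyond an RH sinusoid mostly above 70%, concentration-dependent sensor
error, episodic long-range transport, and size-distribution effects on
optical sensing. Passing tests therefore demonstrate that the pipeline's
logic and numerics behave as specified under a realistic error structure —
not that the specific default parameters describe any particular real
network.

The smooth background is generated by Gaussian-kernel filtering of white
noise rather than exact spectral synthesis of a Gaussian random field:
only the qualitative spatial structure (smoothness at the configured
length scale) matters downstream, and the filter is simple and
dependency-free.

## Problem sizes and determinism

End-to-end tests and the acceptance script run the default 90-day,
27-site configuration (about 58,000 hourly records per seed) and repeat it
over 5–10 seeds; screening and drift power checks use 31-day and 120-day
single-purpose scenarios over 50–200 seeds. These sizes give stable Monte
Carlo estimates of the detection and false-alarm rates being asserted
while keeping a full test run around a minute. Every stochastic stage
takes an explicit integer seed, and generation is bit-reproducible under
`(cfg, seed)`.

## Known limitations

* The assimilation is seasonal and spatial only; hourly/sequential
  assimilation with time-dependent covariances is out of scope.
* Background and observation error parameters are fixed configuration, not
  estimated (no innovation-based tuning or ensemble covariances).
* The QA correlation screen can discard accurate sensors that genuinely
  disagree with the network (hyperlocal sources), a known cost of blind
  network screening.
* RH enters the noise model of the generator and the optional calibration
  covariate, but the pipeline applies no explicit humidity-growth
  correction.
* Grid I/O is plain-text ESRI ASCII; projected metric coordinates are
  assumed throughout and no CRS transformation is offered.
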