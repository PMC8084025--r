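---
title: "Quantifying a thermal-hydric niche: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a thermal-hydric niche: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frogniche)
```

# Scope

`frogniche` quantifies how close a moisture-dependent ectotherm lives to its
physiological limits. It was built around the biology of terrestrial-breeding
frogs of Mediterranean-climate southwestern Australia (*Geocrinia alba* and
its sister species *G. vitellina*): eggs develop in moist soil without a
free-swimming tadpole stage, adults absorb water through the skin from the
substrate, and populations persist only where riparian soils stay cool and
wet through the dry summer. The package links three kinds of measurement:

1. **laboratory thermal limits** from incubation experiments (a
   development-rate curve giving the thermal optimum $T_{opt}$ and an
   extrapolated critical thermal maximum $CT_{max}$),
2. **laboratory hydric limits** from water-flux experiments on wetted
   substrates (the absorption threshold $AT$, the driest substrate from
   which a frog can still gain water), and
3. **field microclimate series** (30-minute soil water potential and
   temperature), reduced to days-per-year breaching each limit, warming
   tolerance, and correlations with population size,

with supporting modules for soil water retention curves, agar-model water
loss, and nonparametric climate trend statistics.

# The development-rate curve

## Model form

Embryonic/larval development rate (percent of the stage window completed
per day) is modelled as a five-parameter unimodal function of temperature:

$$ r(T) \;=\; b_1 \, 2^{\,-u^2\,\left(1 + (b_4 u_+)^{5 b_5}\right)},
\qquad u = \frac{T - b_3}{b_2}, \quad u_+ = \max(u, 0). $$

This is a Dallwitz-style asymmetric performance curve: a base-2 Gaussian
below the optimum, with an extra supra-optimal term that produces the sharp
high-temperature collapse typical of ectotherm thermal performance. The
parameters have direct interpretations:

| parameter | units | meaning | default handling |
|---|---|---|---|
| $b_1$ | %·day⁻¹ | peak development rate; $r(b_3) = b_1$ exactly | free |
| $b_2$ | °C | sub-optimal spread: the rate halves at $T = b_3 - b_2$ (so $b_3 - b_2$ is the curve's lower reference temperature) | free |
| $b_3$ | °C | temperature of the peak, $T_{opt}$ | free |
| $b_4$ | — | steepness of the supra-optimal cutoff | free, weakly identified |
| $b_5$ | — | cutoff shape exponent ($5b_5$ is the power of the cutoff term) | fixed at 0.4 |

Below the optimum ($u \le 0$) the cutoff term vanishes and
$r = b_1 2^{-u^2}$; above it the $(b_4 u_+)^{5b_5}$ term takes over. At the
conventional $b_5 = 0.4$ the cutoff term is quadratic in $u^2$, i.e. the
exponent is quartic in $u$. By construction the curve attains its maximum
at exactly $T = b_3$ with value $b_1$, is strictly unimodal, and is
positive everywhere (the "fall to zero" is asymptotic, which is why
$CT_{max}$ is defined by a threshold rule, below).

The packaged reference parameter sets (`default_rate_curves()`) are the
published estimates for the two *Geocrinia* species (for *G. alba*:
$b_1 = 3.02$, $b_2 = 8.94$, $b_3 = 23.33$, $b_4 = 4.9$, $b_5 = 0.4$).
With these values the curve reproduces the published thermal biology of
both species: development at 15 °C takes about 60 days (observed: 63 and
69 days), at 21 °C about 35 days (observed: 36 and 35), and the
fall-to-zero rule lands within 0.1–0.25 °C of the published $CT_{max}$
values for the two species (next section).

```{r}
p <- default_rate_curves()$alba
curve(dev_rate(x, p), from = 5, to = 32, n = 500,
      xlab = "temperature (C)", ylab = "development rate (% / day)")
abline(v = p$b3, lty = 2)
```

## Rate summation under fluctuating temperatures

Incubation under a fluctuating regime is predicted by rate summation:
development accumulates at the instantaneous rate $r(T_t)$ over the hourly
temperature series (recycled periodically, matching a programmed diel sine
cycle) until the cumulative total reaches 100 %, with linear interpolation
inside the final step. For a constant regime this reduces to
$100 / r(T)$; the default 1-hour step reproduces the closed form to well
under 0.5 %. Because rate summation is nonlinear in temperature, a
fluctuating regime whose mean sits near the optimum develops *slower* than
a constant regime at that mean whenever the excursions sample the steep
supra-optimal side — this Jensen effect is a prediction of the fitted
curve, not an assumption; nothing in the fitting imposes it.

Fluctuating regimes are the reason high-temperature behaviour is
estimable at all: constant incubation near $CT_{max}$ is lethal, but a
sine regime peaking at 30 °C exposes embryos to supra-optimal temperatures
for a few hours per day, and those hours carry information about the
cutoff.

## Fitting

`fit_rate_curve()` minimises residuals between observed and predicted
durations with bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`). Residuals are on the **duration (days) scale** by
default — the scale on which observations arrive and on which the
reference fits' residual sums of squares are sized — with a rate-scale
option (`residual_scale = "rate"`) for users who prefer to weight fast
regimes more heavily. Fluctuating regimes enter the objective through
their full hourly series, never through their mean temperature.

The supra-optimal cutoff parameter $b_4$ is weakly identified whenever few
observations lie above the optimum (the reference fits' standard errors
for $b_4$ are 5.5 and 23.6 against estimates of 4.9 and 5.37), so the
optimiser runs from five starts — one data-driven, four jittered by up to
±25 % under a fixed local seed — and keeps the best optimum. $b_5$ is
fixed at 0.4 by default, the conventional value for this curve family;
any subset of parameters can be fixed via `fixed =`. Standard errors come
from the finite-difference Jacobian at the optimum
($\hat\sigma^2 (J^\top J)^{-1}$), and fixed parameters carry no SE.
Zero-noise simulated data are recovered to better than 0.1 % in every free
parameter, and under the study's own design (7 regimes × 4 split clutches,
duration noise SD 1 day) $b_3$ is recovered well within the published
±0.7 °C standard error.

## $T_{opt}$, $CT_{max}$ and the thermal buffer metrics

$T_{opt}$ is the parameter $b_3$. $CT_{max}$ is *not* a parameter: it is
extrapolated as the temperature where the predicted rate "falls to zero".
Since the curve only reaches zero asymptotically, `estimate_ctmax()` scans
upward from $b_3$ on a 0.01 °C grid and reports the first temperature
where $r(T) \le \epsilon\, b_1$, with $\epsilon = 0.01$ by default; the
rule (epsilon, grid step) is recorded in the output, the scan
short-circuits on an exact zero if a future curve family produces one,
and the estimate is monotone non-increasing in $\epsilon$. With the
packaged reference curves the rule yields 29.69 °C (*G. alba*) and
29.77 °C (*G. vitellina*), against published values of 29.6 and 30.0 —
agreement well inside the resolution that a threshold rule on rounded
parameters can claim. Warming tolerance is
$WT = CT_{max} - T_{hab\text{-}max}$ and the thermal safety margin is
$TSM = T_{opt} - T_{hab}$; both are plain differences and may be negative.

# The absorption threshold

Adult water balance is measured as area-normalised flux
(mg cm⁻² h⁻¹, positive = uptake) of frogs resting on substrates wetted to
known water potentials. Surface area uses the anuran allometry
$A = 9.9\,m^{0.56}$ (cm², g) evaluated at the *standard mass* — the mass
of a fully hydrated frog with an empty bladder — which is the one mass the
design defines per animal; fluxes are mass changes over a 2-h exposure
divided by that area and the duration.

`estimate_absorption_threshold()` locates the zero crossing of mean flux
against water potential. The default `"bracket"` method linearly
interpolates between the two adjacent treatment means that bracket zero,
mirroring how the refined two-treatment experiment (−50 / −70 kPa)
localises the threshold between neighbours; a global monotone
(`"isotonic"`) fit is available when treatment means are noisy enough to
be locally non-monotone. Measurements flagged `excluded` (urination or
defecation during the trial) are dropped before averaging — exclusion is
a data flag, not a detection algorithm. Treatment water potentials are
treated as exact; filter-paper calibration is upstream of this package.
Species are pooled by default (the published threshold is a pooled
estimate); fitting per species is just a matter of subsetting the input.

The bracketing estimator is exact when the true mean flux is linear across
the bracketing pair. When the true crossing sits at a kink of the flux
curve between two treatments the interpolation inherits a small bias
(about 1.5 kPa in the packaged generator's worst configuration); with the
default design (10 frogs, 10 treatments, flux noise SD
0.3 mg cm⁻² h⁻¹) the estimator's sampling SD is about 3 kPa around the
−50 kPa truth, with median absolute error under 3 kPa and no systematic
bias beyond 2 kPa over 200 replicates.

# Soil water retention curves

Sensors report soil water potential directly, but hand-held field
measurements report volumetric water content (VWC, %), so threshold
comparisons need a per-soil-class conversion. The package uses the van
Genuchten form with $m = 1 - 1/n$:

$$ S_e = \frac{\theta - \theta_r}{\theta_s - \theta_r}
      = \left[ 1 + (\alpha |\psi|)^n \right]^{-m}, $$

strictly monotone in both directions with closed-form inverse. The two
packaged curves (`default_retention_curves()`) are **synthetic**
parameter sets: $\theta_r$, $\theta_s$ and $n$ are typical textbook values
for a sandy and a clayey soil — adjusted so the clay curve holds more
water than the sand curve at *every* water potential — and $\alpha$ is
then solved in closed form so that each curve passes exactly through its
anchor: 10.5 % VWC (sand) and 27.6 % VWC (clay) at −50 kPa, the published
soil-moisture equivalents of the absorption threshold. They are faithful
at and around those anchors and should not be mistaken for fitted
laboratory retention curves for any particular soil. Round-trip error is
below 0.1 % VWC across the full range. Hysteresis and the temperature
dependence of retention are out of scope.

# Microclimate exceedance

`summarize_site_year()` reduces a 30-minute soil sensor series to one row
per site and July–June year (the southern-hemisphere water year, so one
summer dry season sits wholly inside each window):

* a day **exceeds $AT$** if any non-missing reading has $\psi < AT$
  (strictly: a reading at exactly the threshold does not count),
* a day **exceeds $T_{opt}$ / $CT_{max}$** if any reading has
  $T >$ threshold,
* $T_{hab\text{-}max}$ is the window maximum and $WT$ its difference from
  $CT_{max}$.

The any-reading rule is the deliberate default: breaching a physiological
limit at any time of day is the biologically conservative reading of
"days exceeding", since a frog cannot time-average its exposure through a
30-minute extreme. Daily-mean and daily-extreme rules are exposed as
options (`day_rule`), and the chosen rule is recorded in the summary —
comparisons between datasets should match rules, and counts under the
any-reading rule are systematically higher than under a daily-mean rule
on noisy series. Days with no readings drop out of the denominator; days
with partial readings count normally; nothing is imputed. Removing
readings can therefore never increase a count, and splitting a series at
any day boundary partitions the counts exactly.

Population-level context uses `population_estimate()` (doubled
calling-male counts, assuming a 50:50 sex ratio) and
`exceedance_population_correlation()`, a Spearman rank correlation
(average ranks for ties, coefficient = Pearson correlation of ranks) with
a two-sided p-value from the $t$ approximation
$t = r_s\sqrt{(n-2)/(1-r_s^2)}$ — the approximation reproduces published
values of this statistic at small $n$ exactly, which the exact-permutation
p does not.

# Agar-model water loss

Field desiccation risk is measured with 3 % agar frog models deployed from
sunrise to sunset. `percent_loss_per_hour()` and `standardize_9h()` reduce
each deployment to percent mass lost over a standard 9-hour daytime
exposure (the minimum shared exposure); extrapolations past 100 % are
capped and *flagged*, never silently truncated (with realistic inputs the
cap never binds — the driest observed groups lose about a third of their
mass). `group_summary()` reports mean ± SE and $n$ by habitat (excluding
0-m deployments, which sit on the habitat boundary) or by ground cover ×
size class; empty groups are reported with $n = 0$. Statistical
comparisons across groups (ANOVA, Tukey HSD) are deliberately left to
standard routines — this module's contract ends at correct reductions.

# Climate trend statistics

`mann_kendall()` implements the rank-based trend test with the standard
tie-corrected variance
$\mathrm{var}(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18$ and the ±1
continuity correction on $Z$ — the usual convention for this test.
`sens_slope()` returns the median pairwise slope (per year and per
decade) with the distribution-free rank-interpolated 95 % interval.
`anomaly()` computes deviations (absolute or percent) from the series'
baseline-window mean, defaulting to 1961–1990, the standard climate-normal
reference period; `percentile_rank()` uses the mid-rank convention (the
mean of the < and ≤ conventions), recorded because no single convention is
universal. `autocorrelation()` provides the lag-$k$ sample autocorrelation
with ±1.96/√n white-noise bounds as a pre-test check for serial structure;
serially correlated series inflate the Mann–Kendall false-positive rate
and corrected variants are out of scope. Analysis windows ("the past 30
years") are explicit closed year ranges supplied by the caller
(`window_years()`), never auto-detected.

The implementation is cross-checked in the test suite against two
independent routes: explicit pair enumeration, and
`cor.test(, method = "kendall", exact = FALSE, continuity = TRUE)` against
the year vector, which is algebraically the same test when time is untied
(the joint-tie variance terms vanish); the two agree with the package to
10⁻¹⁰ on a 30-year fixture with ties.

# The synthetic-data generators

Every input the pipeline consumes has a seeded generator with recorded
ground truth; each is a pure function of its arguments and seed (the
global RNG stream is saved and restored). They emulate the study design
that motivated the package, and their defaults *are* those study
conditions:

* `gen_development_data()` — 7 regimes (constant ~15/18/20/21/25 °C,
  sine-wave 21 ± 2.5 and 25 ± 5 °C), 4 split clutches per regime,
  Gaussian duration noise SD 1 day (sized to reproduce the published
  ±0.7 °C SE on $T_{opt}$), truth curve = the *G. alba* reference.
* `gen_flux_data()` — 10 frogs × 10 treatments (0 to −200 kPa), mean flux
  piecewise-linear with knots calibrated to the published qualitative
  behaviour (uptake 3.0 mg cm⁻² h⁻¹ on free water dropping to 1.0 by 30 %
  of the way to the threshold; zero at the −50 kPa truth; −0.8 at 30 kPa
  past it, so that essentially all individuals lose water there under the
  SD 0.3 measurement noise), no per-frog random effect by default.
* `gen_microclimate()` — one July–June year at 30-minute cadence for 8
  sites: winter-saturated soils (−5 kPa) with a mid-summer sinusoidal
  dry-down on the log₁₀ scale to site minima spanning −20 to −180 kPa
  (six of eight drier than −50 kPa, a dry-year scenario), temperature an
  annual sinusoid pinned at ~10 °C in winter with summer maxima of
  ~20–30 °C across sites plus a diel cycle; noise is Gaussian on
  log₁₀|ψ| and on temperature. The noiseless skeleton's exceedance-day
  counts are returned as truth and are recovered exactly by
  `summarize_site_year()` at zero noise.
* `gen_climate_series()` — linear trend plus Gaussian noise (defaults:
  −10.9 mm yr⁻¹ on a 1150 mm rainfall series, SD 80 mm, 30 years).
* `gen_field_deployments()` — habitat means 6.4 / 13.5 / 31.0 % per 9 h
  (frog habitat / adjacent riparian / adjacent terrestrial), juveniles
  scaled ×1.3, adult and juvenile model masses 1.97 ± 0.16 g and
  0.46 ± 0.07 g, exposures 9–11 h.

Noise is Gaussian throughout — the simplest defensible error model where
no empirical error structure is available — so passing recovery tests
demonstrates correctness of the estimators under well-behaved noise, not
robustness to the heavy tails, sensor drift, autocorrelated weather, or
behavioural artefacts of real field data. Two known idealisations matter
for interpretation: the smooth sinusoidal temperature skeleton produces
*sustained* threshold exceedance at the hottest sites where real records
spike briefly (so generated exceedance-day counts at hot sites run higher
than the field values they emulate), and climate noise is serially
independent (no autocorrelated drought persistence).

# Numerical choices and edge cases

* Rate summation uses a 1-hour default step, linear interpolation in the
  final step, and refuses (with an informative error) regimes whose
  temperatures yield no development or exceed a `max_days` horizon.
* The CT_max scan errors rather than extrapolating past 60 °C.
* The bracketing threshold estimator errors when treatment means never
  change sign, when all measurements are excluded, or with fewer than two
  treatments; ties at zero mean flux resolve to the treatment itself.
* Exceedance comparisons are strict (`<` for ψ, `>` for temperature), so
  readings exactly at a threshold never count.
* `sensor_series()` validates strictly increasing timestamps and the
  nominal 30-minute cadence by the median spacing, so isolated gaps pass
  but a mislabelled hourly file fails fast.
* Sen's confidence interval uses rank interpolation and clamps to the
  extreme pairwise slopes for very short series; with fewer than 4 years
  the CI is `NA` while the point estimate is still returned.
* All fitting and generation is deterministic given seeds; `run_pipeline()`
  writes a manifest with MD5 sums, and reruns are byte-identical.

# Problem sizes used by the tests

The test and acceptance suites run entirely on synthetic data at the
study's own scale: 28 incubation observations over 7 regimes per refit;
100 flux measurements per threshold estimate (200 replicates for the
error-distribution checks); eight 17,568-reading sensor series per
microclimate year; 30-year climate series (200 replicates for null
calibration and CI coverage). These sizes were chosen to match the
emulated study design, and the full suite completes in well under a
minute on a single core.

# Known limitations

* The development-rate curve family is one defensible asymmetric unimodal
  form with the documented parameter semantics; other families (beta,
  Lactin, Sharpe–Schoolfield) could fit comparably near the optimum while
  extrapolating differently above it. $CT_{max}$ inherits both the curve
  family and the ε-rule, and should be read as a curve-based
  approximation, not a measured tolerance endpoint.
* Embryonic mortality, acclimation shifts of $CT_{max}$ (±1–2 °C),
  cutaneous resistance, boundary-layer physics and burrowing-depth
  microclimate buffering are all out of scope.
* The retention curves are anchored fixtures (see above), not laboratory
  fits.
* Serial-correlation-corrected Mann–Kendall variants and change-point
  detection are not implemented.
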