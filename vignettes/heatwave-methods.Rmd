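---
title: "Methods: percentile heatwave indices, bias correction, trends and attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: percentile heatwave indices, bias correction, trends and attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatwaveCA)
```

This vignette documents the models, the parameter choices that matter, what
the synthetic generator does and does not emulate, and the numerical
decisions a maintainer would want written down. It states no empirical
result that the test suite does not itself compute.

## 1. Threshold climatology and the yearly indices

**Model.** For a daily Tmax (or Tmin) series, the threshold for calendar
day $d$ is the $q$-th percentile of all base-period values falling within
$\pm h$ days of $d$, pooled across base years. Defaults: $q = 90$,
$h = 7$ (a 15-day centered window — the ETCCDI convention), base period =
the full reference span supplied. Percentiles interpolate linearly between
order statistics (the "type 7" rule); the brute-force oracle in the tests
uses the same rule, so the choice is recorded rather than hidden.

**Calendar convention.** Dates are mapped to a fixed 366-slot calendar in
which Feb-29 always occupies slot 60. Windows are taken on this 366-day
wheel and wrap across the year boundary; in non-leap years the Feb-29 slot
is simply empty, and the Feb-29 threshold is fed by the leap-year values in
its window. A side effect worth knowing: with a pure seasonal cycle, the
mean over a 365-slot year differs from a 366-slot year at the ~0.03 °C
level, which is why the generator's "no-signal" test compares endpoint
years of equal leapness.

**Indices.** A heatwave is a maximal run of $\ge$ `min_duration` days with
Tmax *strictly above* the calendar-day threshold (ties do not count; the
oracle mirrors this). `min_duration = 3` follows the ClimPACT/ETCCDI
heatwave-aspects convention. Per year: HWN = events starting in the year,
HWF = their total days, HWD = longest event, HWM = mean Tmax over all event
days, HWA = hottest event day. Runs crossing Dec-31 are not split — the
whole event is attributed to its start year, a recorded decision flagged
for sensitivity work rather than a claim about the emulated study. Years
with no event record HWM = 0 (matching the "no heatwave" severity row) and
HWA as missing, not 0 — an HWA of 0 °C would be a temperature, not an
absence. Future-period indices are always computed against the historical
reference climatology: thresholds are frozen, so future exceedances are
measured against today's climate.

## 2. Mean–variance bias correction

Per calendar month $m$, the correction is the affine map
$\hat{x} = \mu_o + \frac{\sigma_o}{\sigma_m}(x - \mu_m)$ with moments
pooled over the calibration overlap (defaults to the full common span).
Monthly stratification is a recorded decision: pooling all days would let a
seasonal bias with zero annual mean survive the correction untouched. On
the calibration period the map forces per-month mean and sd to match the
reference identically — the `1e-9` moment-matching criterion is an algebra
check, not a statistical one; the substantive claim, tested on synthetic
data, is the ≥ 50 % held-out reduction of |bias| and RMSE. Parameters are
fit once on the historical overlap and applied unchanged to future periods.
Members are corrected first and ensembled second (equal weights, "one
model, one vote"); since both operations are affine they commute when
members share parameters, and the tests assert exactly that. No quantile
mapping: this is deliberately a two-moment method.

Zero within-month variance aborts with an error naming the month — a
constant month means the inputs are not temperature-like and silently
dividing by a tiny sd would amplify noise without bound.

## 3. Trend testing

`mann_kendall()` computes $S = \sum_{i<j}\mathrm{sign}(y_j - y_i)$,
tie-corrected variance, a $\pm 1$ continuity-corrected normal deviate and a
two-sided p-value; `sens_slope()` is the median of pairwise slopes. Sen's
slope is what the trend tables report — the estimator behind the emulated
study's printed slopes is unstated, and Sen is the standard Mann–Kendall
companion; ordinary least squares is used as the independent oracle in the
recovery tests. No pre-whitening for serial correlation is applied (none is
described for the emulated analysis); for yearly indices at n ≈ 30–60 the
type-I error checks in the acceptance suite show the plain test holds its
nominal level under an iid null, which is what the test can establish —
autocorrelated index series would inflate it. Constant series return
$S = 0$, $p = 1$, slope 0 rather than erroring: a flat index is a valid
answer, not a data defect. Missing years (e.g. HWA in no-event years) are
dropped with their time positions kept, so gaps do not distort the slope
denominator.

## 4. Severity classification and mortality

HWM bins (°C, lower-exclusive/upper-inclusive where bounded): No heatwave
(= 0), Below normal (0, 12], Normal (12, 23], Moderate (23, 31], Severe
(31, 32], Extreme (32, 38], Very extreme (38, 40), Super extreme [40, 50),
Ultra-extreme [50, ∞). Two gaps in the published scheme are closed by
policy: (0, 12] gets an explicit "Below normal" label and (39, 40) folds
into Very extreme — both preserve monotone ordering without inventing new
bins, and the classification is monotone by construction. Of the
overlapping top rows (≥ 40, ≥ 50) the most severe applicable label wins.
Regional categories use coverage quotas — the fraction of stations with HWM
above a category's lower bound must reach 1.00 / 0.80 / 0.70 / 0.30 / 0.03
for Normal / Moderate / Severe / Extreme / Very extreme — and the most
severe attained category is reported even if an intermediate quota fails.

Attributable mortality is
$\mathrm{AM} = \mathrm{heatwave\ days} \times \mathrm{death}_{daily}
\times (RR-1)/RR$ with RR = 1.20 (95 % CI 1.02–1.41) applied uniformly
across countries; only the RR interval is propagated (no Monte Carlo over
demography). Daily deaths are annual totals divided by 365/366. Country
heatwave days aggregate station HWF by the unweighted mean (recorded
default; `aggregate = "sum"` is the alternative) — how the emulated
analysis collapsed 700 locations to national values is not recoverable, and
the mean is population-agnostic. `rr < 1` is allowed but warned about:
protective estimates are meaningful in sensitivity analyses, silent sign
flips are not.

## 5. Spatial products

IDW uses the 4 nearest stations with weights $d^{-2}$; distances are planar
in lon/lat degrees (no projection — recorded, with the exactness and
boundedness invariants unaffected by the metric). A cell coinciding with a
station takes its value exactly. Display bounds pool all finite cells of a
raster group and clip at the 2nd/98th percentiles (same type-7 estimator as
the thresholds, for internal consistency); signed fields use
$(-M, M),\ M = \max(|p_2|, |p_{98}|)$ so zero sits at the colour-bar
centre. A constant raster collapses to $(c, c)$; widening is the display
layer's job.

## 6. The synthetic world

`generate_reference_series()` builds Tmax as
baseline + seasonal cycle + trend + AR(1) noise + injected episodes:

| parameter | default | why |
|---|---|---|
| `baseline_mean` | 18 °C | annual-mean Tmax of a continental mid-latitude station |
| `seasonal_amplitude` | 17 °C | winter ≈ 1 °C, summer ≈ 35 °C peak (mid-July) |
| `trend` | 0.04 °C/yr | ≈ 0.4 °C/decade, the reported regional warming rate |
| `ar1_coeff` | 0.7 | daily temperature is strongly autocorrelated; iid noise would make 3-day runs unrealistically rare |
| `noise_sd` | 3 °C | stationary sd of daily anomalies |
| `episode_rate`, `episode_boost` | 2/summer, 6 °C | a few detectable multi-day heat events per warm season |
| `gcm_bias`, `gcm_var_inflation` | 2 °C, 1.3 | typical raw-GCM miscalibration the correction must remove |

Episodes (3–7 days) are injected only in the warm half-year (May 1–Sep 15),
keeping TX90 exceedances seasonal. Tmin is Tmax minus a seasonally varying
diurnal range floored at 1 °C, so Tmax ≥ Tmin holds identically. The
pseudo-GCM is an affine distortion of the reference plus AR(1) noise
*independent of the reference but shared between Tmax and Tmin* — per-
variable noise would violate Tmax ≥ Tmin on a noticeable fraction of days.
Beyond the reference span the deterministic recipe continues with a
scenario-specific `future_trend` (demo: 0.03 and 0.06 °C/yr for the
intermediate and high pathways). Ground truth (true trend, true bias and
inflation, episode dates) rides along as attributes purely for
parameter-recovery tests.

Demography: logistic population growth, slowly declining crude death rate,
small lognormal noise — smooth, positive, reproducible.

**What a green test does and does not establish.** The generator has no
spatial covariance (stations are independent), no real geography beyond a
bounding box, no precipitation, no urban heat island, and its noise is
Gaussian AR(1) — so passing tests establish that the *machinery* (window
percentiles, run detection, affine correction, rank tests, the risk
formula) is correct and internally consistent, not that the emulated
study's real-data numbers are reproduced. Its headline values depend on
archives this package deliberately does not touch.

A noted small-sample effect: boosted days occupy ≈ 7 % of a warm-season
window pool; with only ~10 base years, binomial fluctuation can push the
90th-percentile threshold into the boost cluster and drop episode recovery
below 90 %. At the default 63-year span the effect vanishes — the
recoverability invariant is therefore tested at the stated default span.

## 7. Scale, determinism and budgets

Acceptance simulations state their scales explicitly (100 seeds for the
correction improvement, 1,000 series for the detector oracle, 10,000
replicates for the type-I error); the Sen recovery test uses yearly noise
σ = 0.5 — a realistic index-level interannual scatter, chosen once. The
end-to-end demo runs 20 stations (not 700) over 60 + 30 + 30 years with
two pseudo-GCMs and two scenarios, and coarsens display rasters to 0.25°
(function default 0.1°) solely to stay inside its runtime budget. Every
generator takes an explicit seed, derives independent sub-streams per
station/member/purpose, and restores the caller's RNG state; pipeline
reruns under one seed are byte-identical, which the suite asserts on file
hashes.

## 8. Known limitations

- No pre-whitening: Mann–Kendall p-values on strongly autocorrelated
  indices will be anti-conservative.
- No field significance across stations (per-location 5 % tests only,
  matching the emulated design) — an open question, not an omission by
  accident.
- NetCDF output is not provided (no NetCDF binding in the supported
  dependency set); all products are plain CSV plus a JSON manifest.
- The severity quota rule reports coverage of *exceedance of a lower
  bound*, so the top unbounded categories carry no quota by design.
- Planar-degree distances distort IDW weights at high latitude; at the
  display-only role of the rasters this is cosmetic.
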