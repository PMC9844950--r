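---
title: "Estimating country-level mobility metrics from sparse smartphone trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating country-level mobility metrics from sparse smartphone trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Opt-in smartphone apps produce location streams that are sparse (a fix
every 20 minutes at best), noisy (tens of metres of positional
uncertainty), intermittent (devices vanish for days), and geographically
biased (app users are not a population sample). `mobimetrics` turns such
streams into two country-level daily metrics:

* **M1**, the average distance travelled per device (km/day), and
* **M2**, the share of devices that did not move during the calendar day.

The estimation chain is deliberately simple and auditable:

1. **Sanitation.** Observations with latitude *and* longitude exactly zero
   are dropped (that is what a failed geolocation looks like); observations
   with only one zero coordinate are legitimate places and are kept.
   Non-positive uncertainties are replaced by 25 m, the typical accuracy of
   Wi-Fi/cell-tower positioning. Sanitation is idempotent and reported
   (counts and replaced fraction).

2. **Uncertainty gating.** For consecutive fixes, the WGS84 ellipsoidal
   geodesic distance *l* is kept only when
   *l ≥ r·u_m + r·u_{m+1}* (boundary inclusive, default *r* = 1), i.e. when
   the two 1-sigma uncertainty disks do not overlap. Without the gate a
   perfectly stationary device accumulates a pseudo-random walk's worth of
   distance; with it, stationary device-days estimate almost exactly zero.

3. **Daily aggregation.** A device-day is *eligible* with at least *n* = 12
   observations spanning at least 12 h (so "a day" is actually observed,
   not extrapolated from a burst). Each segment is attributed to the
   calendar day of its earlier endpoint, so the segment bridging midnight
   counts once, on the earlier day — including when the following day is
   itself ineligible. A device with daily distance below *z* = 0.2 km
   counts as stationary; the 0.2 km allowance absorbs indoor movement.

4. **Stratified weighting.** Devices are assigned to first-level
   administrative divisions by point-in-polygon on their daily mean
   coordinates; region means are combined with population weights
   *w_c = p_c / Σ p_c*. This de-biases the country estimate when app
   penetration differs across regions, and localized events remain visible
   in proportion to the population they affect.

5. **Uncertainty.** A non-parametric bootstrap resamples each region's
   device values with replacement at the region's own sample size,
   recomputes the weighted aggregate *B* = 1000 times, and reports the
   2.5th/97.5th percentiles (equal-tailed, linear interpolation between
   order statistics).

6. **Smoothing.** The *q*-day smoothed regional value is the *pooled* mean
   over all device-days in the trailing window — the pooled sum over the
   pooled count — so busy days weigh proportionally more; with *q* = 1 this
   reduces exactly to the daily estimator. The bootstrap for a smoothed day
   resamples the whole *q*-day pool, which is what gives the smoothed
   intervals their correct (narrower) width. The first *q − 1* days are
   emitted as missing rather than computed from a truncated window.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `n` | 12 | count & hours | eligibility: min observations and min span per device-day |
| `r` | 1 | — | gate multiplier on the summed endpoint uncertainties |
| `z` | 0.2 | km | stationarity threshold for M2 |
| `q` | 1 | days | trailing pooled moving-average window (7, 14, 21, 28 for smoothed series) |
| `B` | 1000 | iterations | bootstrap replications |
| `alpha` | 5 | percent | excluded tail mass: 95% intervals |

The sensitivity layer (`sensitivity_grid()`) recomputes both metrics over
n ∈ {3, 6, 9, 12, 15}, r ∈ {1, 2, 3}, z ∈ {0.1, 0.2, 0.3, 0.4} km and
correlates each cell against transit-stations and residential-type
indices; on synthetic data the spread across the 60 cells is small, which
is the desired insensitivity to these choices. The gate feeds both
metrics, so total M1 distance is non-increasing in `r`.

## Comparison with external indices

External indices in the community-mobility-report dialect are
percent-changes from a baseline by place category. M1 is compared with
transit-stations, parks and retail-and-recreation; M2 with residential
(positive) and workplaces (negative — stored signed, modelled unsigned).
Two conventions matter and are deliberate:

* **Equal smoothing on both sides.** At smoothing level *q* the index gets
  a trailing *q*-day moving average before correlating. Both series share
  a strong weekly cycle; smoothing only one side strips the cycle from it
  and *lowers* the correlation, which would misrepresent what smoothing
  does to agreement. With equal smoothing, correlations rise from *q* = 1
  to *q* = 7 on synthetic data, as they should when daily estimation noise
  averages out.

* **Lag sign.** In `shift_profile()`, at lag Δ the metric at *t* is
  correlated with the index at *t + Δ*: a positive argmax means the index
  is delayed relative to the metric. Shared weekly seasonality produces
  secondary maxima at Δ = ±7, ±14; recovering Δ = 0 as the global argmax
  is the expected signature of well-aligned series.

The penetration model relates a country's unsigned correlation |ρ| to its
average dataset penetration π (mean daily contributing trajectories over
population) by beta regression with a logit link,
logit(μ) = β₀ + β₁·log₁₀(π), precision φ, fitted by maximum likelihood
(BFGS on the log-likelihood, standard errors from the inverse observed
information). Responses on the closed boundary are compressed by
(y·(N−1)+0.5)/N before fitting, since the beta support is open. The
"model vs constant" test uses the squared Wald ratio of the slope referred
to F(1, n−3); at n = 17 this is calibrated close to its nominal 5% level
in simulation. The reported pseudo-R² is the squared correlation between
observed and fitted |ρ|.

## What the synthetic generator emulates — and what it does not

`simulate_trajectories()` generates the full data world: rectangular
first-level divisions with unequal populations, per-region user counts
that may deviate from population shares (app-penetration bias), device
heterogeneity (log-normal activity factors), a pandemic-style mobility dip
with recovery plus a weekend cycle, missing device-days, and observation
times on a regular within-day grid with random phase, which honors the
20-minute spacing constraint by construction, across midnight included.
Ground truth is defined as the path length through the noise-free
observation positions with the same day-attribution rule as the estimator
— exactly the estimand, so estimator-vs-truth comparisons are meaningful.

One choice deserves emphasis: the generator reports `u` = 25 m as the
observation uncertainty but scatters fixes with sd `noise_factor × u`
(default 0.35). Reported smartphone accuracy is a conservative radius, and
consecutive indoor fixes are strongly correlated (cached Wi-Fi and
cell-tower positions), so the effective scatter *between* fixes sits well
below the reported 1-sigma value. Were the scatter literally equal to
`u`, the distance between two independent fixes of a stationary device
would be Rayleigh with scale u√2 and would exceed the gate threshold
2u with probability e⁻¹ ≈ 0.37 — every stay-day would leak distance and no
gate of this form could work, contradicting the observable fact that it
does. Under the default, fewer than 5% of stay-days show any positive
estimated distance.

Features of real data the generator does **not** emulate: road-network
routing (trips are straight out-and-back legs), multi-destination
itineraries, DST discontinuities, heteroskedastic uncertainty by
environment, and spatially correlated missingness. Passing tests therefore
demonstrate the correctness of the estimation machinery under a controlled
data-generating process, not robustness to every pathology of production
location data.

## Numerical choices and degenerate inputs

* Geodesics use the full WGS84 ellipsoid (`geosphere::distGeo`), not the
  haversine sphere; the ~0.3% difference matters when validating against
  closed-form oracles.
* Spacing violations and duplicate timestamps are *thinned* (earlier
  observation kept, count logged) rather than rejected: the constraint is
  a property the delivered stream should already satisfy, and thinning
  restores it with minimal data loss.
* Daily mean longitude switches to the circular mean when a device's
  longitudes straddle the antimeridian, so such devices are assigned to a
  sensible region instead of the mid-Pacific.
* Point-in-polygon is even-odd ray casting over all rings (holes come for
  free) with points on a boundary counting as inside; devices whose daily
  mean falls in no region (coastal noise) are excluded from that day and
  counted in a message.
* Days where a region has no eligible device renormalize the population
  weights over the covered regions — the weighted mean stays proper — and
  a day with no covered region at all is emitted as missing.
* One shared resampling of device indices drives both the M1 and the M2
  bootstrap aggregates per iteration, preserving the device-level joint
  structure; `joint_resampling = FALSE` restores fully independent
  resampling of the two value sets.
* Trajectory CSVs are written with 17 significant digits and re-parsed
  through `strtod`, so write→read round-trips are bit-exact.
* Constant series have no defined Pearson correlation and return `NA` with
  a warning rather than a silent zero.

## Problem sizes used by the test-suite experiments

The statistical checks run at sizes chosen to make their Monte-Carlo error
small relative to the asserted margins while staying desk-scale: 1,000
random trajectories for oracle equivalence; 500 simulated
three-region/200-device datasets for bootstrap coverage; 200 replicates
(400 under the null) for beta-regression recovery and test calibration;
100 seeded runs for lag recovery; and 20 replicates of a 1,000-device
dense population subsampled at six penetrations between 10⁻⁵·⁵ and 10⁻³
for the penetration transition.

## Known limitations

* The equal-tailed percentile bootstrap is slightly anti-conservative for
  a mean of strongly right-skewed per-device distances at region sample
  sizes of a few dozen: in the suite's own coverage experiment the
  stationary-share (M2) intervals sit at nominal coverage while the
  distance (M1) intervals run one-to-two points below 95%. This is a
  property of the percentile method itself, not of its implementation —
  under symmetric device values the same code attains nominal coverage.
  Studentized or BCa intervals would reduce the gap at real computational
  cost; the percentile method is kept as the standard, simplest reading.
* Region assignment uses daily mean coordinates; a device splitting its
  day across a regional border is assigned wholly to the region of its
  mean position.
* The beta regression treats countries' correlations as independent
  observations and fits a single precision φ.
* Penetration is measured against total population, ignoring age or
  device-ownership structure.
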