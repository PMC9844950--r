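# mobimetrics

Country-level human-mobility metrics from sparse, noisy smartphone location
trajectories, with honest uncertainty.

When location streams come from an opt-in smartphone app rather than from a
platform with near-census penetration, three problems dominate: positional
uncertainty of tens of metres, devices that report on some days and not
others, and an app-user population whose geography does not mimic the
country's population. `mobimetrics` implements an estimation pipeline built
around those constraints, for researchers who want mobility covariates
(epidemiology, economics, climate) from modest trajectory datasets, and for
anyone evaluating how small such a dataset can be before its information
content degrades.

## The estimator

Observations are tuples *(ID_k, lat_m, lon_m, u_m, t_m)* with *u_m* the
1-sigma positional uncertainty in metres and *t_m* a local wall-clock
timestamp; consecutive observations of a device are at least 20 minutes
apart. After sanitation (rows with both coordinates exactly zero removed;
non-positive *u* replaced by 25 m), two daily country metrics are produced:

* **M1** — average distance travelled per device, km/day;
* **M2** — percentage of devices that did not move during the 24 h of the
  day (daily distance below *z* = 0.2 km).

The per-device daily distance sums uncertainty-gated geodesic segment
lengths on the WGS84 ellipsoid:

    l̂(m, m+1) = l(m, m+1)   if l(m, m+1) ≥ r·u_m + r·u_{m+1}   (r = 1)
              = 0           otherwise

so a segment counts only when the endpoints' uncertainty disks do not
overlap — this is what keeps a stationary device from accumulating phantom
distance out of GPS noise. The segment bridging midnight accrues to the
earlier day only. A device contributes to a day only with at least *n* = 12
observations spanning at least 12 h.

Devices are assigned (by their daily mean coordinates, point-in-polygon) to
first-level administrative divisions, and region means are combined with
population weights *w_c = p_c / Σ p_c*, which de-biases the estimate when
app users are geographically unrepresentative. Uncertainty comes from a
region-stratified non-parametric bootstrap (*B* = 1000, percentile 95%
intervals). Temporal smoothing is a *q*-day pooled moving average
(*q* ∈ {7, 14, 21, 28}) whose bootstrap pools the whole window, giving
intervals of the correct width.

The comparison layer correlates M1/M2 with external
percent-change-from-baseline mobility indices (community-mobility-report
CSV dialect), computes time-shifted correlation profiles (lags −14…+14
days), and models unsigned correlation against average dataset penetration
*π* (mean daily trajectories / population) with a beta regression,
logit(μ) = β₀ + β₁·log₁₀(π), precision φ. A synthetic trajectory generator
with known ground truth exercises every stage.

## Worked example

```r
library(mobimetrics)

sim <- simulate_trajectories(simulation_config(seed = 42, n_days = 60))
san <- sanitize_trajectories(sim$trajectories)
series <- compute_metrics(san$trajectories, sim$regions,
                          q = c(1, 7), boot = bootstrap_config(B = 1000, seed = 42))
subset(series, date == as.Date("2020-04-15"))
#>   country       date metric q estimate n_trajectories ci_low ci_high
#> 1     SIM 2020-04-15     M1 1   4.3644             90 2.9462  5.8638
#> 2     SIM 2020-04-15     M2 1   0.5664             90 0.4592  0.6718
#> 3     SIM 2020-04-15     M1 7   3.8022             90 3.3119  4.3289
#> 4     SIM 2020-04-15     M2 7   0.6253             90 0.5876  0.6613
```

On that day the 90 contributing devices travelled on average 4.36 km
(95% CI 2.95–5.86) and 56.6% of them stayed put; the 7-day pooled values
(rows 3–4) are less noisy and carry visibly narrower intervals. (M2 is
stored as a fraction; `write_metric_series()` renders it as a percentage.)
Correlating the smoothed M1 with a synthetic transit-stations index derived
from the generator's ground truth:

```r
idx <- simulate_index(data.frame(date = sim$true_series$date,
                                 value = sim$true_series$m1_true),
                      "transit_stations", noise_sd = 3)
m1 <- subset(series, metric == "M1" & q == 7)
correlate_series(data.frame(date = m1$date, value = m1$estimate),
                 smooth_series(idx, 7))
#> rho = 0.992 over 54 days
```

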