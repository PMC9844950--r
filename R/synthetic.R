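#' Default synthetic region geometry
#'
#' Three disjoint rectangular first-level divisions in a 2-degree by
#' 2-degree mid-latitude frame, small enough that planar intuition and
#' geodesic distances agree and point-in-polygon fixtures stay
#' human-checkable. Populations are deliberately unequal so the
#' population-weighting machinery is exercised.
#'
#' @param populations Population counts for the three rectangles.
#' @return A [region_set()] for the synthetic country `SIM`.
#' @export
synthetic_regions <- function(populations = c(5e5, 3e5, 2e5)) {
  rect <- function(lon0, lon1, lat0, lat1) {
    m <- cbind(lon = c(lon0, lon1, lon1, lon0, lon0),
               lat = c(lat0, lat0, lat1, lat1, lat0))
    list(list(m))
  }
  region_set(
    country = "SIM",
    region_id = c("R1", "R2", "R3"),
    population = populations,
    geometry = list(
      rect(0, 1, 44, 45),
      rect(1, 2, 44, 45),
      rect(0, 2, 45, 46)
    )
  )
}

#' Simulation configuration
#'
#' Describes the synthetic smartphone population whose trajectories the
#' generator emits. The movement model is deliberately simple but captures
#' the statistical structure the estimator has to cope with: device
#' heterogeneity, day-to-day signal (a pandemic-style mobility dip with
#' recovery plus a weekly cycle), missing device-days, positional noise with
#' reported 1-sigma uncertainty, and the 20-minute observation spacing
#' honored by construction.
#'
#' Per user and day: with probability `missing_day_prob` the device reports
#' nothing; otherwise it performs, with day-dependent probability
#' `(1 - p_stay) * s_d * w_d`, a single straight out-and-back trip from its
#' home to a destination at log-normal distance (scaled by a per-user
#' log-normal activity factor), during a random daytime window. `s_d` is the
#' trend multiplier (drops by `dip_depth` over `dip_onset_days`, recovers
#' with timescale `recovery_days`) and `w_d` applies `weekend_drop` on
#' Saturdays/Sundays. Observations are taken on a regular within-day grid of
#' `n_obs` points (uniform in `obs_min:obs_max`) with a random phase, which
#' guarantees at least 20 minutes between consecutive observations,
#' including across midnight. Gaussian noise with sd `noise_factor * u_m`
#' metres is added to each coordinate while `u_m` is reported as the
#' observation uncertainty: reported smartphone accuracy is a conservative
#' radius, and consecutive indoor fixes are correlated (cached Wi-Fi/cell
#' positions), so the effective scatter between fixes sits well below the
#' reported 1-sigma value — which is what makes the uncertainty gate
#' effective on stationary devices.
#'
#' @param seed Integer seed; the generator is fully reproducible.
#' @param start_date First day.
#' @param n_days Number of days.
#' @param regions A [region_set()]; homes are drawn uniformly per region.
#' @param n_users Users per region (recycled against the regions). Departing
#'   from population proportionality emulates app-penetration bias.
#' @param p_stay Baseline probability of a stay-at-home day.
#' @param trip_meanlog,trip_sdlog Log-normal one-way trip distance, km.
#' @param activity_sdlog Per-user log-normal activity sd (mean 1).
#' @param obs_min,obs_max Range of observations per reporting day (max 24,
#'   i.e. hourly, keeping the spacing constraint comfortable).
#' @param u_m Reported 1-sigma positional uncertainty, metres.
#' @param noise_factor Ratio of the actual per-coordinate scatter to the
#'   reported uncertainty (default 0.35).
#' @param missing_day_prob Probability a device reports nothing on a day.
#' @param dip_depth,dip_onset_days,recovery_days,weekend_drop Trend shape.
#' @param frac_zero_coord,frac_nonpos_u Fractions of observations corrupted
#'   with `(0, 0)` coordinates / non-positive `u`, for sanitation tests.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              start_date = as.Date("2020-03-11"),
                              n_days = 180L,
                              regions = synthetic_regions(),
                              n_users = c(60, 40, 30),
                              p_stay = 0.35,
                              trip_meanlog = log(6), trip_sdlog = 0.5,
                              activity_sdlog = 0.6,
                              obs_min = 13L, obs_max = 24L,
                              u_m = 25,
                              noise_factor = 0.35,
                              missing_day_prob = 0.25,
                              dip_depth = 0.45, dip_onset_days = 21,
                              recovery_days = 90,
                              weekend_drop = 0.15,
                              frac_zero_coord = 0, frac_nonpos_u = 0) {
  stopifnot(
    n_days >= 1, p_stay >= 0, p_stay <= 1,
    obs_min >= 2, obs_max <= 24, obs_min <= obs_max,
    missing_day_prob >= 0, missing_day_prob < 1,
    u_m > 0, noise_factor > 0, frac_zero_coord >= 0, frac_zero_coord < 1,
    frac_nonpos_u >= 0, frac_nonpos_u < 1
  )
  n_users <- rep_len(n_users, regions$C)
  structure(
    list(
      seed = as.integer(seed), start_date = start_date,
      n_days = as.integer(n_days),
      regions = regions, n_users = as.integer(n_users), p_stay = p_stay,
      trip_meanlog = trip_meanlog, trip_sdlog = trip_sdlog,
      activity_sdlog = activity_sdlog,
      obs_min = as.integer(obs_min), obs_max = as.integer(obs_max),
      u_m = u_m, noise_factor = noise_factor,
      missing_day_prob = missing_day_prob,
      dip_depth = dip_depth, dip_onset_days = dip_onset_days,
      recovery_days = recovery_days, weekend_drop = weekend_drop,
      frac_zero_coord = frac_zero_coord, frac_nonpos_u = frac_nonpos_u
    ),
    class = "simulation_config"
  )
}

# daily movement multiplier: pandemic-style dip plus weekend cycle
trend_multiplier <- function(cfg) {
  d <- seq_len(cfg$n_days)
  s <- 1 - cfg$dip_depth * pmin(1, d / cfg$dip_onset_days) *
    exp(-pmax(0, d - cfg$dip_onset_days) / cfg$recovery_days)
  dow <- as.POSIXlt(cfg$start_date + d - 1)$wday
  w <- ifelse(dow %in% c(0, 6), 1 - cfg$weekend_drop, 1)
  s * w
}

sample_homes <- function(geometry, n) {
  all_pts <- do.call(rbind, unlist(geometry, recursive = FALSE))
  lon_rng <- range(all_pts[, 1])
  lat_rng <- range(all_pts[, 2])
  lon <- numeric(0); lat <- numeric(0)
  while (length(lon) < n) {
    m <- 2 * (n - length(lon)) + 10
    cl <- runif(m, lon_rng[1], lon_rng[2])
    ca <- runif(m, lat_rng[1], lat_rng[2])
    ok <- point_in_multipolygon(cl, ca, geometry)
    lon <- c(lon, cl[ok]); lat <- c(lat, ca[ok])
  }
  cbind(lon = lon[seq_len(n)], lat = lat[seq_len(n)])
}

#' Simulate smartphone trajectories with known ground truth
#'
#' Generates an observation stream in the canonical trajectory layout
#' together with the generating truth: the per-user-day noise-free travelled
#' distance and stationarity, and the true population-weighted country
#' series of both mobility metrics. Truth is defined as the path length
#' through the *noise-free* observation positions (segments attributed to
#' the day of their earlier endpoint, like the estimator), i.e. the exact
#' quantity the estimation pipeline targets.
#'
#' @param cfg A [simulation_config()].
#' @return A `mobility_sim` list: `trajectories` (observation tibble),
#'   `truth` (`id, day, region_id, true_km, true_stationary`), `true_series`
#'   (`date, m1_true, m2_true`, population-weighted; `m2_true` a fraction),
#'   `regions`, `config`.
#' @export
simulate_trajectories <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  regions <- cfg$regions
  n_tot <- sum(cfg$n_users)
  if (n_tot < 1) stop("no users configured")

  # users: homes uniform per region, log-normal activity factor (mean 1)
  region_of_user <- rep(regions$regions$region_id, cfg$n_users)
  homes <- do.call(rbind, lapply(seq_len(regions$C), function(i) {
    sample_homes(regions$regions$geometry[[i]], cfg$n_users[i])
  }))
  users <- tibble::tibble(
    id = sprintf("U%05d", seq_len(n_tot)),
    region_id = region_of_user,
    home_lon = homes[, "lon"], home_lat = homes[, "lat"],
    activity = rlnorm(n_tot, -cfg$activity_sdlog^2 / 2, cfg$activity_sdlog)
  )

  p_move_day <- pmin(1, pmax(0, (1 - cfg$p_stay) * trend_multiplier(cfg)))

  # user-day table
  ud <- tidyr::expand_grid(uix = seq_len(n_tot), d = seq_len(cfg$n_days))
  n_ud <- nrow(ud)
  ud$present <- runif(n_ud) >= cfg$missing_day_prob
  ud$moving <- ud$present & runif(n_ud) < p_move_day[ud$d]
  ud$trip_km <- ifelse(
    ud$moving,
    rlnorm(n_ud, cfg$trip_meanlog, cfg$trip_sdlog) * users$activity[ud$uix],
    0
  )
  ud$bearing <- runif(n_ud, 0, 2 * pi)
  ud$t_start_h <- runif(n_ud, 6, 14)
  ud$dur_h <- runif(n_ud, 2, 8)
  obs_choices <- seq(cfg$obs_min, cfg$obs_max)
  ud$n_obs <- obs_choices[sample.int(length(obs_choices), n_ud, replace = TRUE)]
  # phase keeps the first observation of each day at least 20 min after
  # midnight, so spacing holds across midnight too
  ud$phase <- runif(n_ud, pmin(0.95, 1.1 * ud$n_obs / 72), 1)
  ud <- ud[ud$present, ]

  # expand to observations
  n_obs_tot <- sum(ud$n_obs)
  row <- rep(seq_len(nrow(ud)), ud$n_obs)
  j <- sequence(ud$n_obs)
  step_min <- 1440 / ud$n_obs[row]
  t_min <- (j - 1 + ud$phase[row]) * step_min
  t0 <- as.POSIXct(paste0(format(cfg$start_date), " 00:00:00"), tz = "UTC")
  timestamp <- t0 + (ud$d[row] - 1) * 86400 + floor(t_min * 60)

  # position along the out-and-back path
  t_h <- t_min / 60
  frac <- pmin(1, pmax(0, (t_h - ud$t_start_h[row]) / ud$dur_h[row]))
  along_km <- ifelse(frac <= 0.5, 2 * frac, 2 - 2 * frac) * ud$trip_km[row]
  hlat <- users$home_lat[ud$uix[row]]
  hlon <- users$home_lon[ud$uix[row]]
  km_per_deg_lat <- 110.574
  km_per_deg_lon <- 111.320 * cos(hlat * pi / 180)
  true_lat <- hlat + along_km * cos(ud$bearing[row]) / km_per_deg_lat
  true_lon <- hlon + along_km * sin(ud$bearing[row]) / km_per_deg_lon

  noise_sd <- cfg$noise_factor * cfg$u_m
  noise_lat <- rnorm(n_obs_tot, 0, noise_sd) / (km_per_deg_lat * 1000)
  noise_lon <- rnorm(n_obs_tot, 0, noise_sd) / (km_per_deg_lon * 1000)

  obs <- tibble::tibble(
    id = users$id[ud$uix[row]],
    lat = true_lat + noise_lat,
    lon = true_lon + noise_lon,
    u = rep(cfg$u_m, n_obs_tot),
    timestamp = timestamp,
    country = regions$country
  )

  # ground truth from the noise-free positions, ungated, day of earlier endpoint
  day <- as.Date(obs$timestamp, tz = "UTC")
  same <- obs$id[-n_obs_tot] == obs$id[-1]
  i1 <- which(same)
  truth_seg <- tibble::tibble(
    id = obs$id[i1], day = day[i1],
    km = geodesic_distance(true_lat[i1], true_lon[i1],
                           true_lat[i1 + 1], true_lon[i1 + 1]) / 1000
  ) |>
    dplyr::group_by(.data$id, .data$day) |>
    dplyr::summarise(true_km = sum(.data$km), .groups = "drop")
  truth <- tibble::tibble(id = obs$id, day = day) |>
    dplyr::distinct() |>
    dplyr::left_join(truth_seg, by = c("id", "day"))
  truth$true_km[is.na(truth$true_km)] <- 0
  truth$region_id <- users$region_id[match(truth$id, users$id)]
  truth$true_stationary <- as.integer(truth$true_km < 0.2)

  # true country series: population-weighted region means over present devices
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1
  popn <- regions$regions$population
  rids <- regions$regions$region_id
  true_series <- dplyr::bind_rows(lapply(seq_along(dates), function(k) {
    td <- truth[truth$day == dates[k], ]
    m1 <- vapply(rids, function(r) {
      v <- td$true_km[td$region_id == r]
      if (length(v) == 0) NA_real_ else mean(v)
    }, 0)
    m2 <- vapply(rids, function(r) {
      v <- td$true_stationary[td$region_id == r]
      if (length(v) == 0) NA_real_ else mean(v)
    }, 0)
    tibble::tibble(
      date = dates[k],
      m1_true = country_aggregate(m1, popn),
      m2_true = country_aggregate(m2, popn)
    )
  }))

  # optional corruption for sanitation tests (applied after truth is fixed)
  if (cfg$frac_zero_coord > 0) {
    k <- which(runif(n_obs_tot) < cfg$frac_zero_coord)
    obs$lat[k] <- 0
    obs$lon[k] <- 0
  }
  if (cfg$frac_nonpos_u > 0) {
    k <- which(runif(n_obs_tot) < cfg$frac_nonpos_u)
    obs$u[k] <- 0
  }

  structure(
    list(trajectories = obs, truth = truth, true_series = true_series,
         regions = regions, config = cfg),
    class = "mobility_sim"
  )
}

#' @export
print.mobility_sim <- function(x, ...) {
  cat(sprintf(
    "<mobility_sim> %d observations, %d devices, %d days, %d regions\n",
    nrow(x$trajectories), length(unique(x$trajectories$id)),
    x$config$n_days, x$regions$C
  ))
  invisible(x)
}

#' Simulate an external mobility-index series
#'
#' Derives a percent-change-from-baseline index from a country series, the
#' way community mobility reports express visit counts: an affine response
#' `scale * value + shift` is referenced to the mean of a baseline window
#' and expressed in percent, plus Gaussian noise. The noise sd controls the
#' achievable correlation with the source series
#' (`rho ~ 1/sqrt(1 + sd^2/var(index))`); `scale = -1` yields a
#' workplaces-like, negatively-correlated index.
#'
#' @param series Tibble with columns `date` and `value`.
#' @param index Index name (e.g. `"transit_stations"`).
#' @param scale,shift Affine response applied to `value`.
#' @param noise_sd Gaussian noise sd, percentage points (uses the current
#'   RNG stream; seed upstream for reproducibility).
#' @param baseline_days Length of the baseline window at the start of the
#'   series.
#' @return Tibble `date, index, value`.
#' @export
simulate_index <- function(series, index = "transit_stations",
                           scale = 1, shift = 0, noise_sd = 0,
                           baseline_days = 14) {
  stopifnot(nrow(series) >= baseline_days, baseline_days >= 1)
  v <- scale * series$value + shift
  base <- mean(v[seq_len(baseline_days)])
  if (base == 0) stop("zero baseline mean: index undefined")
  value <- 100 * (v - base) / abs(base) + rnorm(length(v), 0, noise_sd)
  tibble::tibble(date = series$date, index = index, value = value)
}

#' Write a simulated dataset to disk
#'
#' Emits the exact file formats the pipeline consumes: the trajectory CSV,
#' region GeoJSON, population CSV, plus the ground-truth tables.
#'
#' @param sim A `mobility_sim`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    trajectories = file.path(dir, "trajectories.csv"),
    regions = file.path(dir, "regions.geojson"),
    populations = file.path(dir, "populations.csv"),
    truth = file.path(dir, "truth.csv"),
    true_series = file.path(dir, "true_series.csv")
  )
  write_trajectories(sim$trajectories, paths$trajectories)
  write_region_set(sim$regions, paths$regions, paths$populations)
  readr::write_csv(sim$truth, paths$truth, progress = FALSE)
  readr::write_csv(sim$true_series, paths$true_series, progress = FALSE)
  paths
}
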