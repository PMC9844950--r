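# Shared fixtures: tiny handcrafted trajectories, an independent naive
# distance oracle, and small random-trajectory generators.

make_traj <- function(id, times, lat, lon, u = 25, country = "SIM") {
  n <- length(times)
  tibble::tibble(
    id = rep_len(id, n),
    lat = rep_len(lat, n),
    lon = rep_len(lon, n),
    u = rep_len(u, n),
    timestamp = as.POSIXct(times, tz = "UTC"),
    country = country
  )
}

# Independent oracle: explicit loop over consecutive pairs of one device,
# geodesic distance via geosphere directly, gate applied inline. The earlier
# endpoint's calendar day decides attribution.
naive_daily_distance <- function(df, day, r = 1) {
  df <- df[order(df$timestamp), ]
  tot <- 0
  if (nrow(df) < 2) return(0)
  for (m in seq_len(nrow(df) - 1)) {
    if (as.Date(df$timestamp[m], tz = "UTC") == day) {
      l <- geosphere::distGeo(c(df$lon[m], df$lat[m]),
                              c(df$lon[m + 1], df$lat[m + 1]))
      if (l >= r * df$u[m] + r * df$u[m + 1]) tot <- tot + l
    }
  }
  tot / 1000
}

# Random handcrafted trajectories: jittered random walks near a base point,
# spacing >= 20 min by construction, spanning 1-3 days.
random_walk_traj <- function(id, n_obs, base_lat = 44.5, base_lon = 0.5,
                             start = as.POSIXct("2020-03-11 00:05:00", tz = "UTC")) {
  gaps <- sample(20:180, n_obs - 1, replace = TRUE) * 60
  times <- start + cumsum(c(0, gaps))
  lat <- base_lat + cumsum(rnorm(n_obs, 0, 0.004))
  lon <- base_lon + cumsum(rnorm(n_obs, 0, 0.004))
  u <- sample(c(5, 25, 50, 120), n_obs, replace = TRUE)
  make_traj(id, times, lat, lon, u)
}

two_region_set <- function(pop = c(75, 25)) {
  rect <- function(lon0, lon1, lat0, lat1) {
    list(list(cbind(lon = c(lon0, lon1, lon1, lon0, lon0),
                    lat = c(lat0, lat0, lat1, lat1, lat0))))
  }
  region_set("SIM", c("A", "B"), pop, list(rect(0, 1, 44, 45), rect(1, 2, 44, 45)))
}

# Stats tibble shaped like compute_daily_stats() output, for aggregation
# tests that construct device-days directly.
make_stats <- function(id, day, region_id, L_hat, eligible = TRUE, z = 0.2) {
  n <- length(L_hat)
  tibble::tibble(
    id = rep_len(id, n),
    day = rep_len(as.Date(day), n),
    n_obs = 24L, span_hours = 23,
    mean_lat = 44.5, mean_lon = 0.5,
    L_hat = L_hat,
    U_hat = stationarity_flag(L_hat, z),
    eligible = rep_len(eligible, n),
    region_id = rep_len(region_id, n)
  )
}
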