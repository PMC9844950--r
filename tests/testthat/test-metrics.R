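test_that("eligibility requires both the count and the span", {
  day_times <- function(hours) as.POSIXct("2020-03-11", tz = "UTC") + hours * 3600
  expect_false(eligible_day(day_times(seq(8, 22, length.out = 11)), n = 12))  # 11 obs, 14 h
  expect_true(eligible_day(day_times(seq(8, 21, length.out = 12)), n = 12))   # 12 obs, 13 h
  expect_false(eligible_day(day_times(seq(8, 14, length.out = 20)), n = 12))  # 20 obs, 6 h
  expect_true(eligible_day(day_times(seq(0, 12, length.out = 12)), n = 12))   # span exactly 12 h
})

test_that("the stationarity flag uses a strict threshold", {
  expect_equal(stationarity_flag(0.15, 0.2), 1L)
  expect_equal(stationarity_flag(0.2, 0.2), 0L)
  expect_equal(stationarity_flag(0, 0.3), 1L)
  expect_equal(stationarity_flag(c(0.05, 0.25), 0.2), c(1L, 0L))
})

test_that("daily distance sums gated segments and ignores co-located noise", {
  # stationary device: all segments identical points -> 0 km
  x <- make_traj("a", sprintf("2020-03-11 %02d:00:00", 0:23), 44.5, 0.5, u = 25)
  s <- compute_daily_stats(x, estimation_config())
  expect_equal(s$L_hat, 0)
  expect_equal(s$U_hat, 1L)
  expect_true(s$eligible)

  # one 1-km hop between consecutive observations, all others co-located
  dest <- geosphere::destPoint(c(0.5, 44.5), 0, 1000)  # exactly 1 km north
  lat <- rep(44.5, 24); lat[13:24] <- dest[2]
  lon <- rep(0.5, 24); lon[13:24] <- dest[1]
  y <- make_traj("a", sprintf("2020-03-11 %02d:00:00", 0:23), lat, lon, u = 25)
  sy <- compute_daily_stats(y, estimation_config())
  expect_equal(sy$L_hat, 1.0, tolerance = 1e-6)
})

test_that("travel across midnight accrues to the earlier day only", {
  dest <- geosphere::destPoint(c(0.5, 44.5), 0, 2000)  # exactly 2 km north
  times <- c(sprintf("2020-03-11 %02d:30:00", 8:22), "2020-03-11 23:50:00",
             sprintf("2020-03-12 %02d:10:00", 0:14))
  lat <- c(rep(44.5, 16), rep(dest[2], 15))
  lon <- c(rep(0.5, 16), rep(dest[1], 15))
  x <- make_traj("a", times, lat, lon, u = 25)
  s <- compute_daily_stats(x, estimation_config())
  d1 <- s[s$day == as.Date("2020-03-11"), ]
  d2 <- s[s$day == as.Date("2020-03-12"), ]
  expect_equal(d1$L_hat, 2.0, tolerance = 1e-6)
  expect_equal(d2$L_hat, 0)
  # the bridging segment is computed even when day d+1 is ineligible
  y <- make_traj("a", c(sprintf("2020-03-11 %02d:30:00", 8:22),
                        "2020-03-11 23:50:00", "2020-03-12 00:10:00"),
                 c(rep(44.5, 16), dest[2]), c(rep(0.5, 16), dest[1]), u = 25)
  sy <- compute_daily_stats(y, estimation_config())
  expect_equal(sy$L_hat[sy$day == as.Date("2020-03-11")], 2.0, tolerance = 1e-6)
  expect_false(sy$eligible[sy$day == as.Date("2020-03-12")])
})

test_that("daily distances match the naive pairwise oracle on random walks", {
  set.seed(21)
  for (k in 1:25) {
    x <- random_walk_traj(sprintf("d%02d", k), sample(10:60, 1))
    s <- compute_daily_stats(x, estimation_config())
    for (d in unique(s$day)) {
      expect_equal(s$L_hat[s$day == d], naive_daily_distance(x, d),
                   tolerance = 1e-9)
    }
  }
})

test_that("daily distance is non-increasing in the gate multiplier", {
  set.seed(31)
  x <- dplyr::bind_rows(lapply(1:10, function(k) {
    random_walk_traj(sprintf("d%02d", k), 30)
  }))
  L <- sapply(c(1, 2, 3), function(r) {
    s <- compute_daily_stats(x, estimation_config(r = r))
    sum(s$L_hat)
  })
  expect_true(all(diff(L) <= 0))
})

test_that("country aggregation weighs regions by population and renormalizes", {
  expect_equal(country_aggregate(c(10, 20), c(75, 25)), 12.5)
  # equal populations: simple average
  expect_equal(country_aggregate(c(4, 8, 9), c(10, 10, 10)), 7)
  # single region
  expect_equal(country_aggregate(7, 123), 7)
  # missing region: renormalize over covered ones
  expect_equal(country_aggregate(c(10, NA), c(75, 25)), 10)
  expect_equal(country_aggregate(c(NA, NA), c(1, 1)), NA_real_)
})

test_that("region daily means average the chosen field over eligible devices", {
  stats <- make_stats(c("a", "b", "c", "d"), "2020-03-11",
                      c("A", "A", "B", "A"), L_hat = c(10, 20, 7, 5),
                      eligible = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(region_daily_mean(stats, "A", as.Date("2020-03-11"), "L_hat"), 15)
  expect_equal(region_daily_mean(stats, "B", as.Date("2020-03-11"), "L_hat"), 7)
  expect_true(is.na(region_daily_mean(stats, "B", as.Date("2020-03-12"), "L_hat")))
  flags <- make_stats(letters[1:4], "2020-03-11", "A", c(0.1, 0.5, 0.5, 0.1))
  expect_equal(region_daily_mean(flags, "A", as.Date("2020-03-11"), "U_hat"), 0.5)
})

test_that("smoothing pools device-days with count weighting", {
  rs <- two_region_set()
  # region A: day 1 one device at 10 km, day 2 three devices at 20 km
  stats <- make_stats(
    c("a", "b", "c", "d"),
    c("2020-03-11", rep("2020-03-12", 3)),
    "A", L_hat = c(10, 20, 20, 20)
  )
  s <- metric_series(stats, rs, q = 2)
  m1 <- s[s$metric == "M1", ]
  # pooled mean (1*10 + 3*20)/4 = 17.5, not the mean of daily means 15
  expect_equal(m1$estimate[m1$date == as.Date("2020-03-12")], 17.5)
  # first q-1 days are missing
  expect_true(is.na(m1$estimate[m1$date == as.Date("2020-03-11")]))
})

test_that("q = 1 smoothing is the identity and constants are invariant", {
  set.seed(41)
  sim <- simulate_trajectories(simulation_config(seed = 5, n_days = 21,
                                                 n_users = c(12, 8, 6)))
  stats <- suppressMessages(
    compute_daily_stats(sim$trajectories, estimation_config(), sim$regions)
  )
  s1 <- metric_series(stats, sim$regions, q = 1)
  s1b <- metric_series(stats, sim$regions, q = 1)
  expect_identical(s1, s1b)
  # constant series stays constant under any window
  const <- make_stats(rep(letters[1:3], 5),
                      rep(as.Date("2020-03-11") + 0:4, each = 3),
                      "A", L_hat = rep(5, 15))
  for (q in c(1, 2, 4)) {
    sq <- metric_series(const, two_region_set(), q = q)
    est <- sq$estimate[sq$metric == "M1"]
    expect_true(all(est[!is.na(est)] == 5))
    expect_equal(sum(is.na(est)), q - 1)
  }
})

test_that("aggregation is invariant to region relabeling and splitting", {
  rs <- two_region_set(pop = c(60, 40))
  stats <- make_stats(letters[1:6], "2020-03-11",
                      c("A", "A", "A", "B", "B", "B"),
                      L_hat = c(3, 6, 9, 10, 20, 30))
  base <- metric_series(stats, rs, q = 1)
  # relabel regions (and permute region order in the set)
  rs_swapped <- region_set("SIM", c("B", "A"), c(40, 60),
                           rs$regions$geometry[c(2, 1)])
  swapped <- metric_series(stats, rs_swapped, q = 1)
  expect_equal(base$estimate, swapped$estimate)
  # split region A into two co-located pseudo-regions with split population
  rs_split <- region_set("SIM", c("A1", "A2", "B"), c(30, 30, 40),
                         c(rs$regions$geometry[1], rs$regions$geometry[1],
                           rs$regions$geometry[2]))
  stats_split <- stats
  stats_split$region_id <- c("A1", "A2", "A1", "B", "B", "B")
  # both pseudo-regions must carry the same mean for exact invariance
  stats_split$L_hat <- c(6, 6, 6, 10, 20, 30)
  stats_eq <- stats
  stats_eq$L_hat <- c(6, 6, 6, 10, 20, 30)
  expect_equal(metric_series(stats_split, rs_split, q = 1)$estimate,
               metric_series(stats_eq, rs, q = 1)$estimate)
})

test_that("M2 stays in the unit interval and M1 non-negative end to end", {
  sim <- simulate_trajectories(simulation_config(seed = 8, n_days = 30,
                                                 n_users = c(15, 10, 5)))
  s <- suppressMessages(
    compute_metrics(sim$trajectories, sim$regions, q = c(1, 7))
  )
  m1 <- s$estimate[s$metric == "M1"]
  m2 <- s$estimate[s$metric == "M2"]
  expect_true(all(m1[!is.na(m1)] >= 0))
  expect_true(all(m2[!is.na(m2)] >= 0 & m2[!is.na(m2)] <= 1))
})

test_that("metric series CSV renders M2 as a percentage", {
  stats <- make_stats(letters[1:4], "2020-03-11", "A", c(0.1, 0.1, 0.1, 10))
  s <- metric_series(stats, two_region_set(), q = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_series(s, path)
  x <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(x$estimate[x$metric == "M2"], 75)
  expect_equal(x$estimate[x$metric == "M1"], mean(c(0.1, 0.1, 0.1, 10)))
})
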