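test_that("the generator is reproducible and honors the spacing constraint", {
  cfg <- simulation_config(seed = 7, n_days = 10, n_users = c(8, 6, 4))
  a <- simulate_trajectories(cfg)
  b <- simulate_trajectories(cfg)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(a$trajectories, pa)
  write_trajectories(b$trajectories, pb)
  expect_identical(readLines(pa), readLines(pb))
  # spacing >= 20 min within every device, including across midnight
  x <- a$trajectories
  gaps <- diff(as.numeric(x$timestamp))
  same <- x$id[-1] == x$id[-nrow(x)]
  expect_true(all(gaps[same] >= 20 * 60))
  # and the pipeline reader thins nothing
  traj <- read_trajectories(pa, "SIM")
  expect_equal(attr(traj, "n_thinned"), 0L)
})

test_that("an all-stay population yields full stationarity", {
  cfg <- simulation_config(seed = 15, n_days = 14, n_users = c(15, 10, 5),
                           p_stay = 1, missing_day_prob = 0)
  sim <- simulate_trajectories(cfg)
  expect_true(all(sim$truth$true_km == 0))
  expect_true(all(sim$true_series$m2_true == 1))
  s <- suppressMessages(compute_metrics(sim$trajectories, sim$regions, q = 1))
  m2 <- s$estimate[s$metric == "M2" & !is.na(s$estimate)]
  expect_true(all(m2 > 0.95))
})

test_that("the uncertainty gate suppresses noise on stay-days", {
  cfg <- simulation_config(seed = 25, n_days = 20, n_users = c(25, 15, 10),
                           p_stay = 1, missing_day_prob = 0)
  sim <- simulate_trajectories(cfg)
  stats <- compute_daily_stats(sim$trajectories, estimation_config())
  expect_lt(mean(stats$L_hat > 0), 0.05)
})

test_that("a single dense trip is recovered to within five percent", {
  # one user, one region, forced long trip, dense hourly sampling
  rs <- region_set("SIM", "R1", 1e5,
                   list(list(list(cbind(lon = c(0, 2, 2, 0, 0),
                                        lat = c(44, 44, 46, 46, 44))))))
  cfg <- simulation_config(
    seed = 77, n_days = 3, regions = rs, n_users = 1,
    p_stay = 0, missing_day_prob = 0, obs_min = 24, obs_max = 24,
    trip_meanlog = log(2.5), trip_sdlog = 1e-6, activity_sdlog = 1e-6,
    dip_depth = 0, weekend_drop = 0
  )
  sim <- simulate_trajectories(cfg)
  stats <- compute_daily_stats(sim$trajectories, estimation_config())
  truth <- sim$truth
  key <- paste(stats$id, stats$day)
  tk <- truth$true_km[match(key, paste(truth$id, truth$day))]
  expect_true(all(tk > 2))  # the out-and-back covers ~2 x 2.5 km
  expect_true(all(abs(stats$L_hat - tk) / tk < 0.05))
})

test_that("ground-truth series and pipeline estimates agree closely", {
  sim <- simulate_trajectories(simulation_config(seed = 35, n_days = 45))
  s <- suppressMessages(compute_metrics(sim$trajectories, sim$regions, q = 1))
  m1 <- s[s$metric == "M1", ]
  m <- dplyr::inner_join(m1, sim$true_series, by = "date")
  m <- m[!is.na(m$estimate), ]
  expect_gt(cor(m$estimate, m$m1_true), 0.95)
})

test_that("simulated indices respond as configured", {
  set.seed(9)
  base <- tibble::tibble(date = as.Date("2020-03-11") + 0:199,
                         value = 20 + 5 * sin(1:200 / 9) + 1:200 / 50)
  clean <- simulate_index(base, noise_sd = 0)
  expect_equal(cor(clean$value, base$value), 1)
  negated <- simulate_index(base, scale = -1, noise_sd = 0)
  expect_equal(cor(negated$value, base$value), -1)
  expect_error(simulate_index(tibble::tibble(date = base$date,
                                             value = rep(0, 200))),
               "baseline")
})

test_that("index noise attenuates correlation as predicted", {
  set.seed(14)
  d <- 1:900
  base <- tibble::tibble(date = as.Date("2020-03-11") + d - 1,
                         value = 20 + 4 * sin(2 * pi * d / 7) + 6 * sin(d / 60))
  clean <- simulate_index(base, noise_sd = 0)
  target_sd <- sd(clean$value)  # noise sd = signal sd gives rho ~ 1/sqrt(2) ~ 0.71
  hits <- replicate(20, {
    idx <- simulate_index(base, noise_sd = target_sd)
    cor(idx$value, base$value)
  })
  expect_gte(mean(hits > 0.6 & hits < 0.8), 0.9)
})

test_that("corruption knobs inject sanitation work at the configured rates", {
  cfg <- simulation_config(seed = 45, n_days = 10, n_users = c(10, 6, 4),
                           frac_zero_coord = 0.02, frac_nonpos_u = 0.03)
  sim <- simulate_trajectories(cfg)
  res <- sanitize_trajectories(sim$trajectories)
  n <- nrow(sim$trajectories)
  expect_equal(res$report$n_removed_zero_coord / n, 0.02, tolerance = 0.35)
  expect_gt(res$report$n_replaced_uncertainty, 0)
  expect_equal(res$report$n_total_observations, n)
})

test_that("dataset writer emits every artifact the pipeline consumes", {
  dir <- withr::local_tempdir()
  sim <- simulate_trajectories(simulation_config(seed = 3, n_days = 7,
                                                 n_users = c(5, 4, 3)))
  paths <- write_dataset(sim, dir)
  expect_true(all(file.exists(unlist(paths))))
  traj <- read_trajectories(paths$trajectories, "SIM")
  expect_equal(nrow(traj), nrow(sim$trajectories))
  rs <- read_region_set(paths$regions, "SIM", paths$populations)
  expect_equal(rs$regions$population, sim$regions$regions$population)
})
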