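#' Read community-mobility-report index series
#'
#' Parses the Community Mobility Reports CSV dialect: one row per
#' region-date with six place-category columns named
#' `<category>_percent_change_from_baseline`. Country-level rows are those
#' with an empty `sub_region_1` (and `sub_region_2`, where present).
#'
#' @param path Path to the CSV.
#' @param countries Optional vector of `country_region_code` values to keep.
#' @return Tidy tibble `country, date, index, value` where `index` is the
#'   bare category name (e.g. `transit_stations`) and `value` the percent
#'   change from baseline.
#' @export
read_cmr <- function(path, countries = NULL) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  idx_cols <- grep("_percent_change_from_baseline$", names(x), value = TRUE)
  if (length(idx_cols) == 0) stop("no *_percent_change_from_baseline columns found")
  is_blank <- function(v) is.na(v) | v == ""
  keep <- rep(TRUE, nrow(x))
  for (col in intersect(c("sub_region_1", "sub_region_2"), names(x))) {
    keep <- keep & is_blank(x[[col]])
  }
  x <- x[keep, ]
  if (!is.null(countries)) x <- x[x$country_region_code %in% countries, ]
  out <- tibble::tibble(
    country = x$country_region_code,
    date = as.Date(x$date)
  )
  for (col in idx_cols) out[[col]] <- as.numeric(x[[col]])
  out <- tidyr::pivot_longer(out, dplyr::all_of(idx_cols),
                             names_to = "index", values_to = "value")
  out$index <- sub("_percent_change_from_baseline$", "", out$index)
  out[!is.na(out$value), ]
}

#' Pearson correlation of two daily series over their overlap
#'
#' Series are aligned on dates, missing days dropped pairwise, and the
#' product-moment correlation computed over the remaining overlap. A
#' constant series has no defined correlation and yields `NA` with a
#' warning.
#'
#' @param a,b Tibbles with columns `date` and `value`.
#' @param min_overlap Minimum number of overlapping non-missing days.
#' @return `list(rho, n_days)`.
#' @export
correlate_series <- function(a, b, min_overlap = 3) {
  m <- dplyr::inner_join(
    a[, c("date", "value")], b[, c("date", "value")],
    by = "date", suffix = c("_a", "_b")
  )
  m <- m[!is.na(m$value_a) & !is.na(m$value_b), ]
  if (nrow(m) < min_overlap) {
    stop(sprintf("only %d overlapping day(s); need at least %d", nrow(m), min_overlap))
  }
  if (stats::sd(m$value_a) == 0 || stats::sd(m$value_b) == 0) {
    warning("constant series: correlation undefined")
    return(list(rho = NA_real_, n_days = nrow(m)))
  }
  list(rho = stats::cor(m$value_a, m$value_b), n_days = nrow(m))
}

#' Time-shifted correlation profile
#'
#' Correlates series `a` with series `b` displaced by each integer lag
#' `-max_lag ... +max_lag` days: at lag `D`, `a(t)` is correlated with
#' `b(t + D)`, so a positive argmax means `b` is *delayed* relative to `a`
#' (features of `a` show up in `b` that many days later).
#'
#' @param a,b Tibbles with columns `date` and `value`.
#' @param max_lag Maximum absolute lag in days (default 14).
#' @return Tibble `shift, rho, n_days` with `2*max_lag + 1` rows.
#' @export
shift_profile <- function(a, b, max_lag = 14) {
  shifts <- seq(-max_lag, max_lag)
  rows <- lapply(shifts, function(s) {
    bs <- b
    bs$date <- bs$date - s
    r <- correlate_series(a, bs)
    tibble::tibble(shift = s, rho = r$rho, n_days = r$n_days)
  })
  dplyr::bind_rows(rows)
}

# the five metric/index pairings used for comparison
default_pairings <- function() {
  tibble::tibble(
    metric = c("M1", "M1", "M1", "M2", "M2"),
    index = c("transit_stations", "parks", "retail_and_recreation",
              "residential", "workplaces")
  )
}

#' Smooth a daily index series with a trailing moving average
#'
#' Right-aligned `q`-day moving average on the calendar-day grid (gaps are
#' tolerated via `na.rm`); the first `q - 1` days become missing. Used so
#' that smoothed-metric comparisons are made against equally smoothed index
#' series.
#'
#' @param series Tibble `date, value`.
#' @param q Window in days.
#' @return Tibble `date, value`.
#' @export
smooth_series <- function(series, q) {
  if (q == 1) return(series[, c("date", "value")])
  grid <- tibble::tibble(date = seq(min(series$date), max(series$date), by = "day"))
  m <- dplyr::left_join(grid, series[, c("date", "value")], by = "date")
  m$value <- zoo::rollapplyr(m$value, q, function(v) mean(v, na.rm = TRUE),
                             fill = NA)
  m$value[is.nan(m$value)] <- NA
  m[!is.na(m$value), ]
}

#' Correlate metric series with external index series
#'
#' Computes, for every requested smoothing level, the Pearson correlation
#' between each mobility metric and its paired place-category indices:
#' M1 against transit stations, parks and retail-and-recreation; M2 against
#' residential and workplaces. At smoothing level `q` both sides are
#' compared at the same temporal resolution: the metric series are already
#' `q`-day pooled means and the index series get a trailing `q`-day moving
#' average (see [smooth_series()]). Signed correlations are stored
#' (workplaces correlates negatively with M2); take `abs(rho)` for unsigned
#' summaries.
#'
#' @param series Output of [compute_metrics()] (possibly several `q`).
#' @param cmr Tidy index tibble from [read_cmr()] or [simulate_index()],
#'   for the same country.
#' @param pairings Optional tibble `metric, index` overriding the default
#'   five pairs.
#' @return Tibble `country, metric, index, q, rho, n_days`.
#' @export
correlate_metrics_cmr <- function(series, cmr, pairings = default_pairings()) {
  combos <- unique(series[, c("country", "metric", "q")])
  combos <- dplyr::inner_join(combos, pairings, by = "metric",
                              relationship = "many-to-many")
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    s <- series[series$country == combos$country[i] &
                  series$metric == combos$metric[i] &
                  series$q == combos$q[i], ]
    g <- cmr[cmr$index == combos$index[i], ]
    if (nrow(g) == 0) return(NULL)
    r <- correlate_series(
      tibble::tibble(date = s$date, value = s$estimate),
      smooth_series(tibble::tibble(date = g$date, value = g$value),
                    combos$q[i])
    )
    tibble::tibble(
      country = combos$country[i], metric = combos$metric[i],
      index = combos$index[i], q = combos$q[i],
      rho = r$rho, n_days = r$n_days
    )
  })
  dplyr::bind_rows(rows)
}

#' Average data-set penetration
#'
#' The mean daily number of contributing trajectories over the study period
#' divided by the country population: `pi = mean(N_d) / population`. Around
#' one trajectory per 10,000 people (`pi ~ 1e-4`) marks the transition to
#' high agreement with external mobility indices.
#'
#' @param daily_counts Numeric vector of daily contributing-trajectory
#'   counts `N_d` (zeros included).
#' @param population Country population.
#' @return Penetration (dimensionless).
#' @export
average_penetration <- function(daily_counts, population) {
  stopifnot(population > 0, length(daily_counts) >= 1)
  p <- mean(daily_counts) / population
  if (p == 0) warning("zero penetration: no contributing trajectories")
  p
}

#' Sensitivity grid over the estimation parameters
#'
#' Recomputes the unsmoothed M1 and M2 series for every combination of the
#' eligibility threshold `n`, gate multiplier `r` and stationarity threshold
#' `z`, and correlates M1 with a transit-stations-type index and M2 with a
#' residential-type index. The gate feeds both metrics, so M1's total
#' distance is non-increasing in `r`; `z` affects only M2.
#'
#' @param traj Sanitized observation tibble.
#' @param regions A [region_set()].
#' @param index_transit,index_residential Tibbles `date, value`.
#' @param n_values,r_values,z_values Grid values (defaults: the 5 x 3 x 4
#'   grid n in \{3,6,9,12,15\}, r in \{1,2,3\}, z in \{0.1,0.2,0.3,0.4\} km).
#' @param dates Optional output date grid.
#' @return Tibble `n, r, z, rho1_abs, rho2_abs` with one row per cell,
#'   where `rho1_abs` is |cor(M1, transit)| and `rho2_abs`
#'   |cor(M2, residential)|.
#' @export
sensitivity_grid <- function(traj, regions, index_transit, index_residential,
                             n_values = c(3, 6, 9, 12, 15),
                             r_values = c(1, 2, 3),
                             z_values = c(0.1, 0.2, 0.3, 0.4),
                             dates = NULL) {
  rows <- list()
  for (n_i in n_values) {
    for (r_i in r_values) {
      cfg <- estimation_config(n = n_i, r = r_i, z = z_values[1])
      stats <- compute_daily_stats(traj, cfg, regions)
      for (z_i in z_values) {
        stats$U_hat <- stationarity_flag(stats$L_hat, z_i)
        s <- metric_series(stats, regions, q = 1, dates = dates)
        m1 <- s[s$metric == "M1", ]
        m2 <- s[s$metric == "M2", ]
        r1 <- correlate_series(
          tibble::tibble(date = m1$date, value = m1$estimate), index_transit
        )
        r2 <- correlate_series(
          tibble::tibble(date = m2$date, value = m2$estimate), index_residential
        )
        rows[[length(rows) + 1L]] <- tibble::tibble(
          n = n_i, r = r_i, z = z_i,
          rho1_abs = abs(r1$rho), rho2_abs = abs(r2$rho)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
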