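#' Estimation configuration
#'
#' Bundles the three tunable choices of the daily estimator plus the
#' smoothing window:
#' \describe{
#'   \item{`n`}{eligibility threshold: a device contributes to a day only
#'     with at least `n` observations that day spanning at least `n` hours
#'     (default 12).}
#'   \item{`r`}{uncertainty-gate multiplier: a segment counts only when its
#'     length is at least `r` times the sum of its endpoints' 1-sigma
#'     uncertainties (default 1).}
#'   \item{`z`}{stationarity threshold in km: a device with daily distance
#'     below `z` counts as not having moved that day (default 0.2 km,
#'     accommodating indoor movement).}
#'   \item{`q`}{moving-average window in days; 1 means no smoothing.}
#' }
#'
#' @param n Minimum observations and minimum span in hours.
#' @param r Gate multiplier.
#' @param z Stationarity threshold, km.
#' @param q Smoothing window, days.
#' @return An `estimation_config` list.
#' @export
estimation_config <- function(n = 12, r = 1, z = 0.2, q = 1) {
  stopifnot(n >= 2, r > 0, z > 0, q >= 1)
  structure(list(n = n, r = r, z = z, q = as.integer(q)),
            class = "estimation_config")
}

#' Daily eligibility of a device
#'
#' A device contributes to a day's estimate only if it recorded at least `n`
#' observations between 00:00:00 and 23:59:59 local time with a temporal
#' span of at least `n` hours between the first and the last.
#'
#' @param timestamps POSIXct observations of one device within one calendar
#'   day.
#' @param n Threshold (count and hours).
#' @return Logical scalar.
#' @export
eligible_day <- function(timestamps, n = 12) {
  if (length(timestamps) < n) return(FALSE)
  span_h <- as.numeric(difftime(max(timestamps), min(timestamps), units = "hours"))
  span_h >= n
}

#' Stationarity flag
#'
#' @param L_hat Daily travelled distance, km.
#' @param z Threshold, km.
#' @return Integer 0/1; 1 when `L_hat < z` (strict), i.e. the device did not
#'   move during the 24 h of the day.
#' @export
stationarity_flag <- function(L_hat, z = 0.2) {
  as.integer(L_hat < z)
}

# Daily mean longitude; switches to the circular mean when the day's
# longitudes straddle the antimeridian (spread > 180 degrees).
mean_lon_circular <- function(lon) {
  if (length(lon) == 0) return(NA_real_)
  if (max(lon) - min(lon) <= 180) return(mean(lon))
  rad <- lon * pi / 180
  m <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  if (m > 180) m <- m - 360
  m
}

#' Per-device daily distance and stationarity statistics
#'
#' The workhorse of the estimator. For every device and calendar day it
#' computes:
#' * `L_hat`: the daily travelled distance in km — the sum of
#'   uncertainty-gated geodesic distances between consecutive observations
#'   whose *earlier* endpoint falls in the day. The segment bridging the last
#'   observation of day `d` and the first of day `d+1` therefore accrues to
#'   day `d` only, so travel across midnight is counted exactly once.
#' * `U_hat`: 1 when `L_hat < z` km (device did not move that day).
#' * `mean_lat`, `mean_lon`: arithmetic daily mean coordinates (circular mean
#'   of longitude if the device straddles the antimeridian), used for region
#'   assignment.
#' * `eligible`: at least `n` observations spanning at least `n` hours.
#'
#' Bridging segments are computed from the raw observation sequence, so a
#' segment into a day that is itself ineligible still contributes to the
#' earlier, eligible day.
#'
#' @param traj Sanitized observation tibble (see [sanitize_trajectories()]).
#' @param cfg An [estimation_config()].
#' @param regions Optional [region_set()]; when supplied, eligible
#'   device-days are assigned to the region containing their daily mean
#'   coordinates (`region_id` is `NA` for unassigned points, which are
#'   excluded from estimates and counted in a message).
#' @return Tibble with one row per device-day: `id`, `day`, `n_obs`,
#'   `span_hours`, `mean_lat`, `mean_lon`, `L_hat`, `U_hat`, `eligible` and
#'   (with `regions`) `region_id`.
#' @export
compute_daily_stats <- function(traj, cfg = estimation_config(), regions = NULL) {
  x <- dplyr::arrange(traj, .data$id, .data$timestamp)
  n <- nrow(x)
  if (n == 0) {
    out <- tibble::tibble(
      id = character(), day = as.Date(character()), n_obs = integer(),
      span_hours = double(), mean_lat = double(), mean_lon = double(),
      L_hat = double(), U_hat = integer(), eligible = logical()
    )
    if (!is.null(regions)) out$region_id <- character()
    return(out)
  }
  day <- as.Date(x$timestamp, tz = "UTC")
  tsec <- as.numeric(x$timestamp)

  obs <- tibble::tibble(
    id = x$id, day = day, lat = x$lat, lon = x$lon, tsec = tsec
  ) |>
    dplyr::group_by(.data$id, .data$day) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      span_hours = (max(.data$tsec) - min(.data$tsec)) / 3600,
      mean_lat = mean(.data$lat),
      mean_lon = mean_lon_circular(.data$lon),
      .groups = "drop"
    )

  if (n >= 2) {
    same <- x$id[-n] == x$id[-1]
    i1 <- which(same)
  } else {
    i1 <- integer()
  }
  if (length(i1) > 0) {
    i2 <- i1 + 1L
    l <- geodesic_distance(x$lat[i1], x$lon[i1], x$lat[i2], x$lon[i2])
    lg <- gate_distance(l, x$u[i1], x$u[i2], cfg$r)
    segsum <- tibble::tibble(id = x$id[i1], day = day[i1], l_km = lg / 1000) |>
      dplyr::group_by(.data$id, .data$day) |>
      dplyr::summarise(L_hat = sum(.data$l_km), .groups = "drop")
    obs <- dplyr::left_join(obs, segsum, by = c("id", "day"))
    obs$L_hat[is.na(obs$L_hat)] <- 0
  } else {
    obs$L_hat <- 0
  }
  obs$U_hat <- stationarity_flag(obs$L_hat, cfg$z)
  obs$eligible <- obs$n_obs >= cfg$n & obs$span_hours >= cfg$n

  if (!is.null(regions)) {
    obs$region_id <- NA_character_
    el <- which(obs$eligible)
    if (length(el) > 0) {
      obs$region_id[el] <- locate_point(obs$mean_lon[el], obs$mean_lat[el], regions)
      n_out <- sum(is.na(obs$region_id[el]))
      if (n_out > 0) {
        message(sprintf(
          "compute_daily_stats: %d eligible device-day(s) fall outside all region polygons and are excluded",
          n_out
        ))
      }
    }
  }
  obs
}

#' Mean of a daily statistic over one region's eligible devices
#'
#' @param stats Output of [compute_daily_stats()] (with `region_id`).
#' @param region Region id.
#' @param day A `Date`.
#' @param field `"L_hat"` (distance, km) or `"U_hat"` (stationarity flags,
#'   giving the stationary fraction).
#' @return Numeric scalar; `NA` when the region has no eligible devices that
#'   day (the region is then treated as missing and excluded from the
#'   country aggregate).
#' @export
region_daily_mean <- function(stats, region, day, field = c("L_hat", "U_hat")) {
  field <- match.arg(field)
  sel <- stats$eligible & !is.na(stats$region_id) &
    stats$region_id == region & stats$day == day
  v <- stats[[field]][sel]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Population-weighted country aggregate of region values
#'
#' Combines per-region values with population weights
#' `w_c = p_c / sum(p_c)`. When some regions are missing (`NA`, e.g. no
#' eligible devices that day), weights are renormalized over the covered
#' regions so the aggregate remains a proper weighted mean.
#'
#' @param values Numeric vector of per-region values (may contain `NA`).
#' @param population Positive population counts, aligned with `values`.
#' @return Weighted mean; `NA` when every region is missing.
#' @export
country_aggregate <- function(values, population) {
  stopifnot(length(values) == length(population), all(population > 0))
  w <- population / sum(population)
  keep <- !is.na(values)
  if (!any(keep)) return(NA_real_)
  sum(values[keep] * w[keep]) / sum(w[keep])
}

#' Country-level daily metric series
#'
#' Aggregates per-device daily statistics into the country-level series of
#' the two mobility metrics:
#' * **M1** — daily average travelled distance, km;
#' * **M2** — fraction of devices that did not move during the day (stored
#'   as a fraction in `[0, 1]`; rendered as a percentage only at the output
#'   layer).
#'
#' For smoothing window `q > 1` the regional value on day `d` is the
#' *pooled* mean over all eligible device-days in the window
#' `[d-q+1, d]` — the pooled sum divided by the pooled count, so days with
#' more devices weigh proportionally more — and the country value re-applies
#' the population weights to the pooled regional means. With `q = 1` this
#' reduces exactly to the unsmoothed daily series. The first `q - 1` days
#' are emitted as missing.
#'
#' @param stats Output of [compute_daily_stats()] with `region_id`.
#' @param regions A [region_set()].
#' @param q Smoothing window in days (1 = none).
#' @param dates Optional `Date` vector defining the output grid; defaults to
#'   the full span of `stats`.
#' @return Long tibble `country, date, metric, q, estimate, n_trajectories`
#'   with one row per date and metric; `n_trajectories` is the number of
#'   eligible region-assigned devices on that *day* (not window). The
#'   per-day-per-region counts are attached as the `region_counts`
#'   attribute.
#' @export
metric_series <- function(stats, regions, q = 1, dates = NULL) {
  q <- as.integer(q)
  stopifnot(q >= 1, "region_id" %in% names(stats))
  pool <- stats[stats$eligible & !is.na(stats$region_id), ]
  if (is.null(dates)) {
    if (nrow(stats) == 0) stop("no device-days and no explicit date grid")
    dates <- seq(min(stats$day), max(stats$day), by = "day")
  }
  D <- length(dates)
  rids <- regions$regions$region_id
  R <- length(rids)
  di <- match(pool$day, dates)
  ri <- match(pool$region_id, rids)
  keep <- !is.na(di) & !is.na(ri)
  idx <- di[keep] + (ri[keep] - 1L) * D
  Nmat <- matrix(tabulate(idx, D * R), D, R)
  SL <- matrix(0, D, R)
  SU <- matrix(0, D, R)
  if (any(keep)) {
    sums <- rowsum(cbind(pool$L_hat[keep], pool$U_hat[keep]), group = idx)
    pos <- as.integer(rownames(sums))
    SL[pos] <- sums[, 1]
    SU[pos] <- sums[, 2]
  }
  roll <- function(m) {
    if (q == 1) return(m)
    apply(m, 2, function(col) zoo::rollsumr(col, q, fill = NA))
  }
  rollN <- roll(Nmat)
  mL <- roll(SL) / rollN
  mU <- roll(SU) / rollN
  mL[!is.finite(mL)] <- NA
  mU[!is.finite(mU)] <- NA
  w <- region_weights(regions)
  agg <- function(m) {
    num <- rowSums(sweep(m, 2, w, "*"), na.rm = TRUE)
    den <- as.numeric((!is.na(m)) %*% w)
    out <- num / den
    out[den == 0] <- NA
    out
  }
  n_daily <- as.integer(rowSums(Nmat))
  out <- dplyr::bind_rows(
    tibble::tibble(
      country = regions$country, date = dates, metric = "M1", q = q,
      estimate = agg(mL), n_trajectories = n_daily
    ),
    tibble::tibble(
      country = regions$country, date = dates, metric = "M2", q = q,
      estimate = agg(mU), n_trajectories = n_daily
    )
  )
  attr(out, "region_counts") <- `dimnames<-`(Nmat, list(as.character(dates), rids))
  out
}

#' End-to-end metric estimation
#'
#' Convenience wrapper: per-device daily statistics, region assignment,
#' country aggregation for each requested smoothing window, and (optionally)
#' stratified bootstrap confidence intervals.
#'
#' @param traj Sanitized observation tibble.
#' @param regions A [region_set()].
#' @param cfg An [estimation_config()] (its `q` is ignored in favour of the
#'   `q` argument).
#' @param q Integer vector of smoothing windows.
#' @param boot Optional [bootstrap_config()]; when supplied, `ci_low` and
#'   `ci_high` columns are added.
#' @param dates Optional output date grid.
#' @return Long tibble as [metric_series()], stacked over `q`.
#' @export
compute_metrics <- function(traj, regions, cfg = estimation_config(),
                            q = 1, boot = NULL, dates = NULL) {
  stats <- compute_daily_stats(traj, cfg, regions)
  out <- lapply(q, function(qi) {
    s <- metric_series(stats, regions, q = qi, dates = dates)
    if (!is.null(boot)) {
      ci <- bootstrap_series(stats, regions, q = qi, cfg = boot,
                             dates = if (is.null(dates)) unique(s$date) else dates)
      s <- dplyr::left_join(s, ci, by = c("date", "metric"))
    }
    s
  })
  dplyr::bind_rows(out)
}

#' Write a metric series to CSV
#'
#' Writes the `country,date,metric,q,estimate,ci_low,ci_high,n_trajectories`
#' layout. M2 is stored internally as a fraction and, by default, rendered
#' here as a percentage.
#'
#' @param series Output of [compute_metrics()] / [metric_series()].
#' @param path Output path.
#' @param m2_percent Render M2 (and its CI) as a percentage.
#' @export
write_metric_series <- function(series, path, m2_percent = TRUE) {
  out <- series
  if (m2_percent) {
    is_m2 <- out$metric == "M2"
    for (col in intersect(c("estimate", "ci_low", "ci_high"), names(out))) {
      out[[col]][is_m2] <- out[[col]][is_m2] * 100
    }
  }
  for (col in c("ci_low", "ci_high", "n_trajectories")) {
    if (!col %in% names(out)) out[[col]] <- NA
  }
  out <- out[, c("country", "date", "metric", "q", "estimate",
                 "ci_low", "ci_high", "n_trajectories")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
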