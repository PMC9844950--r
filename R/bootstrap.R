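#' Bootstrap configuration
#'
#' @param B Number of bootstrap iterations (default 1000).
#' @param alpha Interval level in percent excluded: `alpha = 5` yields 95%
#'   intervals.
#' @param seed Integer seed; every bootstrap run is seeded so results are
#'   reproducible.
#' @param joint_resampling When `TRUE` (default) one resampling of device
#'   indices per region drives both the distance and the stationarity
#'   aggregate in each iteration, preserving the devices' joint structure.
#'   `FALSE` resamples the two value sets independently.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(B = 1000, alpha = 5, seed = 1L,
                             joint_resampling = TRUE) {
  stopifnot(B >= 2, alpha > 0, alpha < 100)
  structure(list(B = as.integer(B), alpha = alpha, seed = as.integer(seed),
                 joint_resampling = isTRUE(joint_resampling)),
            class = "bootstrap_config")
}

# One stratified bootstrap: resample each region's device values with
# replacement at the region's own sample size, recompute region means, and
# combine with population weights renormalized over non-empty regions.
# Returns the B aggregates (and those of `aux`, resampled with the same
# indices, when given).
boot_aggregate <- function(values_by_region, population, B, aux_by_region = NULL) {
  n_c <- lengths(values_by_region)
  keep <- n_c > 0
  if (!any(keep)) stop("bootstrap: all regions empty")
  w <- population / sum(population)
  w <- w[keep] / sum(w[keep])
  agg <- numeric(B)
  agg_aux <- if (!is.null(aux_by_region)) numeric(B) else NULL
  regions_idx <- which(keep)
  for (j in seq_along(regions_idx)) {
    c_i <- regions_idx[j]
    v <- values_by_region[[c_i]]
    m <- length(v)
    idx <- sample.int(m, B * m, replace = TRUE)
    means <- rowMeans(matrix(v[idx], nrow = B))
    agg <- agg + w[j] * means
    if (!is.null(aux_by_region)) {
      a <- aux_by_region[[c_i]]
      means_a <- rowMeans(matrix(a[idx], nrow = B))
      agg_aux <- agg_aux + w[j] * means_a
    }
  }
  list(agg = agg, aux = agg_aux)
}

percentile_ci <- function(boot, alpha) {
  stats::quantile(boot, probs = c(alpha / 200, 1 - alpha / 200),
                  names = FALSE, type = 7)
}

#' Stratified percentile-bootstrap confidence interval
#'
#' Non-parametric bootstrap for the population-weighted country mean of a
#' per-device statistic. Each region's observed device values are resampled
#' with replacement at the region's own sample size, region means are
#' recomputed and combined with the population weights; the interval is the
#' empirical `alpha/2` and `1 - alpha/2` percentile (linear interpolation
#' between order statistics) of the `B` aggregates.
#'
#' @param values_by_region List of numeric vectors, one per region, aligned
#'   with `population`. Empty regions are allowed and excluded (weights are
#'   renormalized over covered regions).
#' @param population Region population counts.
#' @param cfg A [bootstrap_config()].
#' @return `list(ci_low, ci_high, boot)` where `boot` holds the `B`
#'   bootstrap aggregates.
#' @export
bootstrap_ci <- function(values_by_region, population, cfg = bootstrap_config()) {
  stopifnot(length(values_by_region) == length(population))
  if (sum(lengths(values_by_region)) == 0) stop("bootstrap_ci: empty input")
  set.seed(cfg$seed)
  res <- boot_aggregate(values_by_region, population, cfg$B)
  ci <- percentile_ci(res$agg, cfg$alpha)
  list(ci_low = ci[1], ci_high = ci[2], boot = res$agg)
}

#' Bootstrap confidence intervals for a daily or smoothed metric series
#'
#' For each day `d`, devices are pooled per region over the window
#' `[d-q+1, d]` (the same pooling as the smoothed estimator, so intervals
#' for smoothed series include `q` days of resampled data and have the
#' correct width; `q = 1` gives the plain daily intervals) and a stratified
#' percentile bootstrap of the population-weighted aggregate is run. One
#' shared resampling of device indices per region drives both M1 and M2
#' (see [bootstrap_config()]).
#'
#' @param stats Output of [compute_daily_stats()] with `region_id`.
#' @param regions A [region_set()].
#' @param q Smoothing window in days.
#' @param cfg A [bootstrap_config()].
#' @param dates Optional output date grid (defaults to the span of `stats`).
#' @return Tibble `date, metric, ci_low, ci_high` (long over M1/M2).
#' @export
bootstrap_series <- function(stats, regions, q = 1, cfg = bootstrap_config(),
                             dates = NULL) {
  q <- as.integer(q)
  pool <- stats[stats$eligible & !is.na(stats$region_id), ]
  if (is.null(dates)) {
    dates <- seq(min(stats$day), max(stats$day), by = "day")
  }
  rids <- regions$regions$region_id
  popn <- regions$regions$population
  set.seed(cfg$seed)
  day_int <- as.integer(pool$day)
  date_int <- as.integer(dates)
  ri <- match(pool$region_id, rids)
  out <- vector("list", length(dates))
  for (d in seq_along(dates)) {
    if (d < q) {
      out[[d]] <- tibble::tibble(
        date = dates[d], metric = c("M1", "M2"),
        ci_low = NA_real_, ci_high = NA_real_
      )
      next
    }
    in_win <- day_int >= date_int[d] - q + 1L & day_int <= date_int[d]
    if (!any(in_win)) {
      out[[d]] <- tibble::tibble(
        date = dates[d], metric = c("M1", "M2"),
        ci_low = NA_real_, ci_high = NA_real_
      )
      next
    }
    riw <- ri[in_win]
    Lw <- pool$L_hat[in_win]
    Uw <- pool$U_hat[in_win]
    L_by_r <- lapply(seq_along(rids), function(c_i) Lw[riw == c_i])
    U_by_r <- lapply(seq_along(rids), function(c_i) Uw[riw == c_i])
    if (cfg$joint_resampling) {
      res <- boot_aggregate(L_by_r, popn, cfg$B, aux_by_region = U_by_r)
      bL <- res$agg
      bU <- res$aux
    } else {
      bL <- boot_aggregate(L_by_r, popn, cfg$B)$agg
      bU <- boot_aggregate(U_by_r, popn, cfg$B)$agg
    }
    ciL <- percentile_ci(bL, cfg$alpha)
    ciU <- percentile_ci(bU, cfg$alpha)
    out[[d]] <- tibble::tibble(
      date = dates[d], metric = c("M1", "M2"),
      ci_low = c(ciL[1], ciU[1]), ci_high = c(ciL[2], ciU[2])
    )
  }
  dplyr::bind_rows(out)
}
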