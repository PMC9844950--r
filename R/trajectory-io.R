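#' Read raw trajectory observations
#'
#' Reads a delimited file of anonymized smartphone location observations and
#' returns them as a tidy observation table, one row per observation, grouped
#' by device and sorted by timestamp. Each observation is the tuple
#' `(id, lat, lon, u, timestamp)` where `u` is the 1-sigma positional
#' uncertainty in metres and `timestamp` is local wall-clock time.
#'
#' Consecutive observations of one device are required to be at least
#' `min_gap_min` minutes apart. Rows violating the spacing constraint are
#' thinned greedily: the earlier observation is kept, the later dropped, and
#' the count of dropped rows is reported via a message and stored in the
#' `n_thinned` attribute. Duplicate timestamps within a device are thinned the
#' same way. Rows that cannot be parsed (missing or non-numeric fields,
#' unparsable timestamps) are skipped with a logged count.
#'
#' @param path Path to a comma-separated UTF-8 file with header
#'   `id,lat,lon,u,timestamp`; timestamps ISO-8601 local wall-clock without a
#'   zone offset (e.g. `2020-03-11T08:40:00`).
#' @param country ISO-3 country code attached to every observation.
#' @param min_gap_min Minimum spacing between consecutive observations of one
#'   device, in minutes.
#' @return A tibble with columns `id`, `lat`, `lon`, `u`, `timestamp`
#'   (POSIXct, UTC-encoded local wall-clock) and `country`, sorted by
#'   `id` then `timestamp`. Attributes `n_thinned` and `n_bad_rows` carry the
#'   per-file data-quality counts.
#' @seealso [sanitize_trajectories()], [write_trajectories()]
#' @export
read_trajectories <- function(path, country, min_gap_min = 20) {
  stopifnot(file.exists(path))
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      # numeric fields come in as text and go through strtod (correctly
      # rounded), so 17-digit output round-trips bit-exactly
      lat = readr::col_character(),
      lon = readr::col_character(),
      u = readr::col_character(),
      timestamp = readr::col_datetime(format = "")
    ),
    progress = FALSE
  )
  for (col in c("lat", "lon", "u")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  required <- c("id", "lat", "lon", "u", "timestamp")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- x[required]
  if (nrow(x) == 0) {
    warning("empty trajectory file: ", path)
    out <- tibble::tibble(
      id = character(), lat = double(), lon = double(), u = double(),
      timestamp = as.POSIXct(character(), tz = "UTC"), country = character()
    )
    attr(out, "n_thinned") <- 0L
    attr(out, "n_bad_rows") <- 0L
    return(out)
  }
  ok <- stats::complete.cases(x)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(sprintf("read_trajectories: skipped %d unparsable row(s) in %s", n_bad, path))
    x <- x[ok, ]
  }
  x$country <- country
  x <- dplyr::arrange(x, .data$id, .data$timestamp)
  thinned <- thin_min_spacing(x, min_gap = min_gap_min * 60)
  if (thinned$n_dropped > 0) {
    message(sprintf(
      "read_trajectories: thinned %d observation(s) violating the %g-minute spacing in %s",
      thinned$n_dropped, min_gap_min, path
    ))
  }
  out <- thinned$data
  attr(out, "n_thinned") <- thinned$n_dropped
  attr(out, "n_bad_rows") <- n_bad
  out
}

#' Enforce the minimum-spacing constraint by greedy thinning
#'
#' Scans each device's observations in time order and drops any observation
#' closer than `min_gap` seconds to the previously kept one (the earlier
#' observation always survives). Exposed mainly for testing; normally called
#' by [read_trajectories()].
#'
#' @param x Observation tibble sorted by `id`, `timestamp`.
#' @param min_gap Minimum spacing in seconds.
#' @return `list(data, n_dropped)`.
#' @export
thin_min_spacing <- function(x, min_gap = 20 * 60) {
  n0 <- nrow(x)
  repeat {
    n <- nrow(x)
    if (n < 2) break
    tsec <- as.numeric(x$timestamp)
    same <- c(FALSE, x$id[-1] == x$id[-n])
    gap <- c(Inf, diff(tsec))
    bad <- same & gap < min_gap
    if (!any(bad)) break
    # drop only the first violation of each run per pass: keep-earlier greedy
    first_of_run <- bad & !c(FALSE, bad[-n])
    x <- x[!first_of_run, ]
  }
  list(data = x, n_dropped = n0 - nrow(x))
}

#' Sanitize trajectory observations
#'
#' Applies the two data-cleaning rules for raw smartphone location streams:
#' observations whose latitude *and* longitude are both exactly zero (the
#' value a smartphone reports when geolocation fails) are removed, and
#' non-positive positional uncertainties are replaced by `replacement_u`
#' metres, the typical accuracy of Wi-Fi / cell-tower localization.
#' Observations where only one coordinate is zero are kept. Devices left with
#' no observations are dropped.
#'
#' Sanitation is idempotent: re-sanitizing clean data changes nothing and
#' yields an all-zero report.
#'
#' @param traj Observation tibble as returned by [read_trajectories()].
#' @param replacement_u Replacement uncertainty in metres for `u <= 0`.
#' @return `list(trajectories, report)` where `report` is a
#'   `sanitation_report` with counts `n_removed_zero_coord`,
#'   `n_replaced_uncertainty`, `n_total_observations` and the derived
#'   `fraction_replaced`.
#' @export
sanitize_trajectories <- function(traj, replacement_u = 25) {
  n_total <- nrow(traj)
  zero <- traj$lat == 0 & traj$lon == 0
  n_zero <- sum(zero)
  out <- traj[!zero, ]
  bad_u <- out$u <= 0
  n_bad_u <- sum(bad_u)
  out$u[bad_u] <- replacement_u
  report <- structure(
    list(
      n_removed_zero_coord = as.integer(n_zero),
      n_replaced_uncertainty = as.integer(n_bad_u),
      n_total_observations = as.integer(n_total),
      fraction_replaced = if (n_total > 0) n_bad_u / n_total else 0
    ),
    class = "sanitation_report"
  )
  list(trajectories = out, report = report)
}

#' @export
print.sanitation_report <- function(x, ...) {
  cat("Trajectory sanitation report\n")
  cat(sprintf("  observations:           %d\n", x$n_total_observations))
  cat(sprintf("  zero-coordinate removed:%d\n", x$n_removed_zero_coord))
  cat(sprintf("  uncertainty replaced:   %d (%.3f%%)\n",
              x$n_replaced_uncertainty, 100 * x$fraction_replaced))
  invisible(x)
}

#' Write a sanitation report as JSON
#'
#' @param report A `sanitation_report`.
#' @param path Output path.
#' @export
write_sanitation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write trajectory observations to CSV
#'
#' Writes the canonical `id,lat,lon,u,timestamp` layout with ISO-8601
#' wall-clock timestamps. Coordinates and uncertainties are written with
#' round-trip precision so that `read_trajectories()` recovers them
#' bit-exactly.
#'
#' @param traj Observation tibble.
#' @param path Output path.
#' @export
write_trajectories <- function(traj, path) {
  out <- tibble::tibble(
    id = traj$id,
    # 17 significant digits guarantee bit-exact double round-trips
    lat = sprintf("%.17g", traj$lat),
    lon = sprintf("%.17g", traj$lon),
    u = sprintf("%.17g", traj$u),
    timestamp = format(traj$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
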