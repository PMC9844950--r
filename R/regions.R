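#' First-level administrative divisions of a country
#'
#' A `region_set` bundles a country's first-level administrative divisions
#' (states, regions, departments, ...) with their population counts. Regions
#' are the stratification unit of the estimator: devices are assigned to the
#' region containing their daily mean coordinates, per-region means are
#' computed, and the country value is the population-weighted combination
#' with weights `w_c = p_c / sum(p_c)`.
#'
#' @param country ISO-3 country code.
#' @param region_id Character vector of region identifiers.
#' @param population Positive population counts, one per region.
#' @param geometry List (one element per region) of multi-polygons; each
#'   multi-polygon is a list of polygons, each polygon a list of rings
#'   (first ring outer, any further rings holes), each ring a two-column
#'   numeric matrix of `(lon, lat)` WGS84 vertices. Rings may be open or
#'   explicitly closed.
#' @return A `region_set` object.
#' @export
region_set <- function(country, region_id, population, geometry) {
  stopifnot(
    length(region_id) == length(population),
    length(region_id) == length(geometry),
    !anyDuplicated(region_id),
    all(population > 0)
  )
  structure(
    list(
      country = country,
      regions = tibble::tibble(
        region_id = as.character(region_id),
        population = as.numeric(population),
        geometry = geometry
      ),
      C = length(region_id)
    ),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %s: %d first-level divisions, population %s\n",
              x$country, x$C, format(sum(x$regions$population), big.mark = ",")))
  invisible(x)
}

#' Population weights of a region set
#'
#' @param regions A `region_set`.
#' @return Named numeric vector `w_c = p_c / sum(p_c)` summing to 1.
#' @export
region_weights <- function(regions) {
  w <- regions$regions$population / sum(regions$regions$population)
  stats::setNames(w, regions$regions$region_id)
}

#' Read a region set from GeoJSON plus a population table
#'
#' Expects a GeoJSON `FeatureCollection` with one feature per first-level
#' division (geometry `Polygon` or `MultiPolygon`) and a `region_id` property;
#' populations come either from a `population` property on each feature or
#' from a separate CSV with columns `region_id,population`.
#'
#' @param geojson_path Path to the GeoJSON file.
#' @param country ISO-3 country code.
#' @param population_path Optional CSV path with `region_id,population`.
#' @return A `region_set`.
#' @export
read_region_set <- function(geojson_path, country, population_path = NULL) {
  gj <- jsonlite::read_json(geojson_path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  feats <- gj$features
  ids <- vapply(feats, function(f) as.character(f$properties$region_id), "")
  geom <- lapply(feats, function(f) {
    g <- f$geometry
    ring_mat <- function(r) {
      m <- do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
      storage.mode(m) <- "double"
      colnames(m) <- c("lon", "lat")
      m
    }
    if (identical(g$type, "Polygon")) {
      list(lapply(g$coordinates, ring_mat))
    } else if (identical(g$type, "MultiPolygon")) {
      lapply(g$coordinates, function(poly) lapply(poly, ring_mat))
    } else {
      stop("unsupported geometry type: ", g$type)
    }
  })
  if (!is.null(population_path)) {
    pop_tbl <- readr::read_csv(
      population_path,
      col_types = readr::cols(
        region_id = readr::col_character(),
        population = readr::col_double()
      ),
      progress = FALSE
    )
    pop <- pop_tbl$population[match(ids, pop_tbl$region_id)]
    if (anyNA(pop)) stop("population table lacks entries for some regions")
  } else {
    pop <- vapply(feats, function(f) as.numeric(f$properties$population), 0)
  }
  region_set(country, ids, pop, geom)
}

#' Write a region set to GeoJSON and a population CSV
#'
#' @param regions A `region_set`.
#' @param geojson_path Output GeoJSON path.
#' @param population_path Optional output CSV path for `region_id,population`.
#' @export
write_region_set <- function(regions, geojson_path, population_path = NULL) {
  feats <- lapply(seq_len(regions$C), function(i) {
    geom <- regions$regions$geometry[[i]]
    coords <- lapply(geom, function(poly) {
      lapply(poly, function(ring) {
        ring <- close_ring(ring)
        lapply(seq_len(nrow(ring)), function(j) c(ring[j, 1], ring[j, 2]))
      })
    })
    if (length(coords) == 1) {
      geometry <- list(type = "Polygon", coordinates = coords[[1]])
    } else {
      geometry <- list(type = "MultiPolygon", coordinates = coords)
    }
    list(
      type = "Feature",
      properties = list(
        region_id = regions$regions$region_id[i],
        population = regions$regions$population[i]
      ),
      geometry = geometry
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    geojson_path,
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(population_path)) {
    readr::write_csv(
      tibble::tibble(
        region_id = regions$regions$region_id,
        population = regions$regions$population
      ),
      population_path, progress = FALSE
    )
  }
  invisible(geojson_path)
}

close_ring <- function(ring) {
  n <- nrow(ring)
  if (ring[1, 1] != ring[n, 1] || ring[1, 2] != ring[n, 2]) {
    ring <- rbind(ring, ring[1, , drop = FALSE])
  }
  ring
}

# Even-odd ray casting for one ring; points exactly on an edge are flagged
# separately so the boundary can count as inside. Vectorized over points.
ring_crossings <- function(lon, lat, ring, eps = 1e-12) {
  ring <- close_ring(ring)
  nv <- nrow(ring)
  inside <- logical(length(lon))
  on_edge <- logical(length(lon))
  for (j in seq_len(nv - 1)) {
    x1 <- ring[j, 1]; y1 <- ring[j, 2]
    x2 <- ring[j + 1, 1]; y2 <- ring[j + 1, 2]
    # boundary test: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    tol <- eps * max(1, sqrt(seg_len2))
    on_seg <- abs(cross) <= tol &
      lon >= pmin(x1, x2) - tol & lon <= pmax(x1, x2) + tol &
      lat >= pmin(y1, y2) - tol & lat <= pmax(y1, y2) + tol
    on_edge <- on_edge | on_seg
    # ray cast towards +lon; half-open rule avoids double-counting vertices
    crosses <- ((y1 > lat) != (y2 > lat)) &
      (lon < x1 + (lat - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses)
  }
  list(inside = inside, on_edge = on_edge)
}

#' Test whether points fall inside a multi-polygon
#'
#' Even-odd (ray-casting) point-in-polygon over all rings of a multi-polygon,
#' so holes are handled automatically; points on a boundary count as inside.
#'
#' @param lon,lat Numeric vectors of point coordinates (degrees).
#' @param geometry A multi-polygon in the [region_set()] layout.
#' @return Logical vector.
#' @export
point_in_multipolygon <- function(lon, lat, geometry) {
  inside <- logical(length(lon))
  on_edge <- logical(length(lon))
  for (poly in geometry) {
    for (ring in poly) {
      r <- ring_crossings(lon, lat, ring)
      inside <- xor(inside, r$inside)
      on_edge <- on_edge | r$on_edge
    }
  }
  inside | on_edge
}

#' Locate points in a region set
#'
#' Returns, for each point, the `region_id` of the first-level division whose
#' polygons contain it (boundary inclusive), or `NA` when no region contains
#' the point (e.g. coastal GPS noise placing a daily mean offshore). Regions
#' are tested in their stored order; the packaged and synthetic geometries are
#' disjoint, so order does not affect results there.
#'
#' @param lon,lat Numeric vectors of point coordinates (degrees).
#' @param regions A `region_set`.
#' @return Character vector of region ids, `NA` where unassigned.
#' @export
locate_point <- function(lon, lat, regions) {
  out <- rep(NA_character_, length(lon))
  todo <- rep(TRUE, length(lon))
  for (i in seq_len(regions$C)) {
    if (!any(todo)) break
    hit <- point_in_multipolygon(lon[todo], lat[todo], regions$regions$geometry[[i]])
    idx <- which(todo)[hit]
    out[idx] <- regions$regions$region_id[i]
    todo[idx] <- FALSE
  }
  out
}
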