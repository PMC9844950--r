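#' Geodesic distance on the WGS84 ellipsoid
#'
#' Ellipsoidal geodesic distance between pairs of points, in metres.
#' Vectorized over pairs.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees.
#' @return Distance in metres.
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2) {
  geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2))
}

#' Uncertainty gate for a segment distance
#'
#' A raw segment distance `l` between two observations is kept only when it
#' is at least as large as the sum of the endpoints' scaled 1-sigma
#' positional uncertainties, i.e. when `l >= r*u1 + r*u2` (boundary
#' inclusive); otherwise it is set to 0. With `r = 1` this keeps a segment
#' exactly when the two 1-sigma uncertainty disks do not overlap, suppressing
#' spurious noise-driven distance accumulated by a stationary device.
#'
#' @param l Raw segment distances, metres (non-negative).
#' @param u1,u2 Endpoint 1-sigma uncertainties, metres (positive).
#' @param r Gate multiplier (default 1).
#' @return Gated distances, metres.
#' @export
gate_distance <- function(l, u1, u2, r = 1) {
  stopifnot(r > 0)
  ifelse(l >= r * u1 + r * u2, l, 0)
}
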