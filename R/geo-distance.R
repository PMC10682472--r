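#' Great-circle (haversine) distance in meters
#'
#' Distance between WGS84 coordinate pairs on a sphere of radius
#' 6,371,000 m (mean Earth radius). Vectorized over all arguments with the
#' usual recycling rules.
#'
#' @param lat1,lon1 Origin latitude/longitude in decimal degrees.
#' @param lat2,lon2 Destination latitude/longitude in decimal degrees.
#' @return Numeric vector of distances in meters.
#' @examples
#' haversine_distance(0, 0, 0, 1)   # one degree of longitude at the equator
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2) {
  validate_coords(lat1, lon1)
  validate_coords(lat2, lon2)
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  # clamp guards rounding at antipodal points
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_M * asin(sqrt(a))
}

EARTH_RADIUS_M <- 6371000

validate_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(lon < -180 | lon > 180)) {
    stop("longitude out of range [-180, 180]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a proximity matrix
#'
#' A `proximity_matrix` holds origin x destination values of one proximity
#' metric: great-circle distance (`geometric_m`), street-network route
#' distance (`route_m`), or route travel time (`route_s`). Unreachable
#' origin-destination pairs are stored as `NA` and are excluded from choice
#' sets downstream.
#'
#' @param values Numeric matrix, `length(origin_ids)` x `length(dest_ids)`.
#' @param origin_ids,dest_ids Character vectors of unique ids.
#' @param metric One of `"geometric_m"`, `"route_m"`, `"route_s"`.
#' @return A `proximity_matrix` object.
#' @export
proximity_matrix <- function(values, origin_ids, dest_ids,
                             metric = c("geometric_m", "route_m", "route_s")) {
  metric <- match.arg(metric)
  origin_ids <- as.character(origin_ids)
  dest_ids <- as.character(dest_ids)
  if (anyDuplicated(origin_ids)) stop("duplicate origin ids", call. = FALSE)
  if (anyDuplicated(dest_ids)) stop("duplicate destination ids", call. = FALSE)
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(origin_ids), length(dest_ids)))) {
    stop(sprintf("values must be %d x %d", length(origin_ids), length(dest_ids)),
         call. = FALSE)
  }
  if (any(values[!is.na(values)] < 0) || any(is.infinite(values))) {
    stop("proximity values must be non-negative and finite (NA = unreachable)",
         call. = FALSE)
  }
  dimnames(values) <- list(origin_ids, dest_ids)
  structure(
    list(origin_ids = origin_ids, dest_ids = dest_ids,
         values = values, metric = metric),
    class = "proximity_matrix"
  )
}

#' @export
print.proximity_matrix <- function(x, ...) {
  cat(sprintf("<proximity_matrix> %d origins x %d destinations, metric = %s\n",
              length(x$origin_ids), length(x$dest_ids), x$metric))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf("  %d unreachable pairs\n", n_na))
  invisible(x)
}

#' Geometric origin-destination distance matrix
#'
#' Vectorized haversine over all origin x destination pairs of centroids.
#'
#' @param origins,dests Data frames with columns `id`, `lat`, `lon`.
#' @return A `proximity_matrix` with metric `geometric_m`.
#' @examples
#' o <- data.frame(id = "b1", lat = 22.30, lon = 114.17)
#' d <- data.frame(id = c("p1", "p2"), lat = c(22.31, 22.28), lon = c(114.18, 114.16))
#' build_geometric_matrix(o, d)
#' @export
build_geometric_matrix <- function(origins, dests) {
  check_point_table(origins, "origins")
  check_point_table(dests, "dests")
  vals <- outer(seq_len(nrow(origins)), seq_len(nrow(dests)),
                function(i, j) haversine_distance(origins$lat[i], origins$lon[i],
                                                  dests$lat[j], dests$lon[j]))
  proximity_matrix(vals, origins$id, dests$id, "geometric_m")
}

check_point_table <- function(x, what) {
  if (!is.data.frame(x) || nrow(x) == 0) {
    stop(sprintf("%s must be a non-empty data frame", what), call. = FALSE)
  }
  missing <- setdiff(c("id", "lat", "lon"), names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(x$id)) {
    stop(sprintf("duplicate ids in %s", what), call. = FALSE)
  }
  validate_coords(x$lat, x$lon)
  invisible(TRUE)
}
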