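#' Route providers
#'
#' A route provider answers "what is the walking route distance and time
#' between two points?" behind one contract, so the accessibility models can
#' be fed by a street-network shortest-path router, a detour-factor model, or
#' a cache of previously computed origin-destination results, without any
#' live web-map API.
#'
#' @name route-providers
NULL

#' Detour-factor route provider
#'
#' Models route distance as geometric distance times a detour factor. The
#' factor is either a constant, or drawn per origin-destination pair from a
#' lognormal distribution (default median 1.52, sigma-log 0.1, matching the
#' route-to-geometric ratio observed in dense street networks). Travel time
#' is route distance divided by a constant walking speed. Sampling is
#' deterministic under `seed`.
#'
#' @param factor Constant detour factor (>= 1), or `NULL` to sample.
#' @param meanlog,sdlog Lognormal parameters of the sampled factor.
#' @param speed_kmh Walking speed in km/h used to convert distance to time.
#' @param seed Integer seed controlling factor draws.
#' @return A `route_provider` of class `factor_route_provider`.
#' @examples
#' p <- factor_route_provider(factor = 1.5, speed_kmh = 5)
#' route_metrics(p, list(lat = 0, lon = 0), list(lat = 0, lon = 0.009))
#' @export
factor_route_provider <- function(factor = NULL, meanlog = log(1.52),
                                  sdlog = 0.1, speed_kmh = 4, seed = 1L) {
  if (!is.null(factor)) {
    stopifnot(is.numeric(factor), length(factor) == 1, factor >= 1)
  }
  stopifnot(speed_kmh > 0, sdlog >= 0)
  structure(
    list(factor = factor, meanlog = meanlog, sdlog = sdlog,
         speed_kmh = speed_kmh, seed = as.integer(seed)),
    class = c("factor_route_provider", "route_provider")
  )
}

#' Street-network route provider
#'
#' Snaps origin and destination to the nearest network node (within
#' `snap_radius_m`), runs a non-negative-weight shortest path on edge
#' lengths, and accumulates travel time as the sum of edge length over edge
#' speed along that path. Pairs that cannot be snapped or connected are
#' reported unreachable, never as silent infinities.
#'
#' @param network A `street_network` (see [street_network()]).
#' @param snap_radius_m Maximum snapping distance in meters; beyond it the
#'   pair is unreachable. Default 200 m.
#' @return A `route_provider` of class `graph_route_provider`.
#' @export
graph_route_provider <- function(network, snap_radius_m = 200) {
  stopifnot(inherits(network, "street_network"), snap_radius_m > 0)
  structure(
    list(network = network, snap_radius_m = snap_radius_m),
    class = c("graph_route_provider", "route_provider")
  )
}

#' Street network container
#'
#' @param nodes Data frame with columns `node_id`, `lat`, `lon`.
#' @param edges Data frame with columns `u`, `v`, `length_m`, `speed_kmh`;
#'   edges are undirected.
#' @return A `street_network` object wrapping an igraph graph.
#' @export
street_network <- function(nodes, edges) {
  need_n <- setdiff(c("node_id", "lat", "lon"), names(nodes))
  need_e <- setdiff(c("u", "v", "length_m", "speed_kmh"), names(edges))
  if (length(need_n)) stop("nodes missing column(s): ", paste(need_n, collapse = ", "), call. = FALSE)
  if (length(need_e)) stop("edges missing column(s): ", paste(need_e, collapse = ", "), call. = FALSE)
  if (anyDuplicated(nodes$node_id)) stop("duplicate node ids", call. = FALSE)
  if (any(edges$length_m < 0)) stop("edge lengths must be non-negative", call. = FALSE)
  if (any(edges$speed_kmh <= 0)) stop("edge speeds must be positive", call. = FALSE)
  validate_coords(nodes$lat, nodes$lon)
  nodes$node_id <- as.character(nodes$node_id)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$u), to = as.character(edges$v),
               length_m = edges$length_m,
               time_s = edges$length_m / (edges$speed_kmh / 3.6)),
    directed = FALSE,
    vertices = data.frame(name = nodes$node_id)
  )
  structure(list(graph = g, nodes = tibble::as_tibble(nodes),
                 edges = tibble::as_tibble(edges)),
            class = "street_network")
}

#' @export
print.street_network <- function(x, ...) {
  cat(sprintf("<street_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Cached route provider
#'
#' Replays origin-destination route results from a cache keyed by
#' `(origin_id, dest_id, departure)`; it never computes routes and never
#' touches the network. A missing pair is an error naming the pair.
#'
#' @param cache Data frame with columns `origin_id`, `dest_id`, `departure`,
#'   `distance_m`, `time_s`, or a path to such a CSV.
#' @return A `route_provider` of class `cached_route_provider`.
#' @export
cached_route_provider <- function(cache) {
  if (is.character(cache)) cache <- read_route_cache(cache)
  need <- setdiff(c("origin_id", "dest_id", "departure", "distance_m", "time_s"),
                  names(cache))
  if (length(need)) stop("cache missing column(s): ", paste(need, collapse = ", "), call. = FALSE)
  cache <- tibble::as_tibble(cache)
  cache$key <- paste(cache$origin_id, cache$dest_id, cache$departure, sep = "\r")
  if (anyDuplicated(cache$key)) stop("cache holds duplicate (origin, dest, departure) keys", call. = FALSE)
  structure(list(cache = cache), class = c("cached_route_provider", "route_provider"))
}

#' Route distance and time for one origin-destination pair
#'
#' @param provider A `route_provider`.
#' @param origin,dest Lists or one-row data frames with `lat`, `lon` (and
#'   `id` for the cached provider).
#' @param departure Departure clock time, carried as metadata by the factor
#'   and graph providers and used as part of the cache key by the cached
#'   provider. Default `"08:00"`.
#' @param ... Passed on to methods.
#' @return A list with `distance_m`, `time_s`, and `reachable`; for an
#'   unreachable pair `distance_m` and `time_s` are `NA` and `reachable` is
#'   `FALSE`.
#' @export
route_metrics <- function(provider, origin, dest, departure = "08:00", ...) {
  UseMethod("route_metrics")
}

route_result <- function(distance_m, time_s) {
  list(distance_m = distance_m, time_s = time_s,
       reachable = is.finite(distance_m))
}

unreachable_result <- function() {
  list(distance_m = NA_real_, time_s = NA_real_, reachable = FALSE)
}

#' @export
route_metrics.factor_route_provider <- function(provider, origin, dest,
                                                departure = "08:00", ...) {
  geo <- haversine_distance(origin$lat, origin$lon, dest$lat, dest$lon)
  f <- if (!is.null(provider$factor)) {
    provider$factor
  } else {
    # clamp at 1: a walking route can never be shorter than the chord
    max(1, with_local_seed(pair_seed(provider$seed, origin, dest),
                           stats::rlnorm(1, provider$meanlog, provider$sdlog)))
  }
  d <- geo * f
  route_result(d, d / (provider$speed_kmh / 3.6))
}

#' @export
route_metrics.graph_route_provider <- function(provider, origin, dest,
                                               departure = "08:00", ...) {
  o <- snap_node(provider, origin$lat, origin$lon)
  d <- snap_node(provider, dest$lat, dest$lon)
  if (is.na(o) || is.na(d)) return(unreachable_result())
  if (o == d) return(route_result(0, 0))
  sp <- suppressWarnings(
    igraph::shortest_paths(provider$network$graph, from = o, to = d,
                           weights = igraph::E(provider$network$graph)$length_m,
                           output = "epath"))  # unreachable handled explicitly
  ep <- sp$epath[[1]]
  if (length(ep) == 0) return(unreachable_result())
  route_result(sum(igraph::edge_attr(provider$network$graph, "length_m", ep)),
               sum(igraph::edge_attr(provider$network$graph, "time_s", ep)))
}

#' @export
route_metrics.cached_route_provider <- function(provider, origin, dest,
                                                departure = "08:00", ...) {
  if (is.null(origin$id) || is.null(dest$id)) {
    stop("cached provider needs origin$id and dest$id", call. = FALSE)
  }
  key <- paste(origin$id, dest$id, departure, sep = "\r")
  hit <- match(key, provider$cache$key)
  if (is.na(hit)) {
    stop(sprintf("route cache has no entry for origin '%s' -> dest '%s' at departure '%s'",
                 origin$id, dest$id, departure), call. = FALSE)
  }
  route_result(provider$cache$distance_m[hit], provider$cache$time_s[hit])
}

# nearest node id within the snap radius, NA otherwise
snap_node <- function(provider, lat, lon) {
  nd <- provider$network$nodes
  d <- haversine_distance(lat, lon, nd$lat, nd$lon)
  i <- which.min(d)
  if (d[i] > provider$snap_radius_m) NA_character_ else nd$node_id[i]
}

#' Route distance and time matrices for all origin-destination pairs
#'
#' Assembles the provider's answers into two aligned [proximity_matrix()]
#' objects (metrics `route_m` and `route_s`). Unreachable pairs become `NA`
#' entries with one summary warning.
#'
#' @inheritParams route_metrics
#' @param origins,dests Data frames with columns `id`, `lat`, `lon`.
#' @return List with elements `route_m` and `route_s`.
#' @export
build_route_matrices <- function(provider, origins, dests, departure = "08:00") {
  check_point_table(origins, "origins")
  check_point_table(dests, "dests")
  UseMethod("build_route_matrices")
}

#' @export
build_route_matrices.factor_route_provider <- function(provider, origins, dests,
                                                       departure = "08:00") {
  geo <- build_geometric_matrix(origins, dests)$values
  f <- if (!is.null(provider$factor)) {
    provider$factor
  } else {
    # clamped at 1: routes cannot undercut the great-circle chord
    pmax(1, with_local_seed(provider$seed,
                            matrix(stats::rlnorm(length(geo), provider$meanlog,
                                                 provider$sdlog),
                                   nrow = nrow(geo))))
  }
  dist <- geo * f
  finish_route_matrices(dist, dist / (provider$speed_kmh / 3.6),
                        origins$id, dests$id)
}

#' @export
build_route_matrices.graph_route_provider <- function(provider, origins, dests,
                                                      departure = "08:00") {
  g <- provider$network$graph
  wl <- igraph::E(g)$length_m
  o_nodes <- vapply(seq_len(nrow(origins)), function(i)
    snap_node(provider, origins$lat[i], origins$lon[i]), character(1))
  d_nodes <- vapply(seq_len(nrow(dests)), function(j)
    snap_node(provider, dests$lat[j], dests$lon[j]), character(1))
  nd <- matrix(NA_real_, nrow(origins), nrow(dests))
  nt <- nd
  ok_d <- !is.na(d_nodes)
  for (i in seq_len(nrow(origins))) {
    if (is.na(o_nodes[i]) || !any(ok_d)) next
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = o_nodes[i], to = d_nodes[ok_d],
                             weights = wl, output = "epath"))
    dist_i <- rep(NA_real_, sum(ok_d))
    time_i <- rep(NA_real_, sum(ok_d))
    same <- d_nodes[ok_d] == o_nodes[i]
    for (jj in seq_along(sp$epath)) {
      ep <- sp$epath[[jj]]
      if (length(ep) == 0 && !same[jj]) next  # disconnected
      dist_i[jj] <- sum(igraph::edge_attr(g, "length_m", ep))
      time_i[jj] <- sum(igraph::edge_attr(g, "time_s", ep))
    }
    nd[i, ok_d] <- dist_i
    nt[i, ok_d] <- time_i
  }
  finish_route_matrices(nd, nt, origins$id, dests$id)
}

#' @export
build_route_matrices.cached_route_provider <- function(provider, origins, dests,
                                                       departure = "08:00") {
  keys <- outer(origins$id, dests$id,
                function(o, d) paste(o, d, departure, sep = "\r"))
  hit <- match(keys, provider$cache$key)
  if (anyNA(hit)) {
    mi <- which(is.na(hit))[1]
    row <- (mi - 1) %% nrow(origins) + 1
    col <- (mi - 1) %/% nrow(origins) + 1
    stop(sprintf("route cache has no entry for origin '%s' -> dest '%s' at departure '%s'",
                 origins$id[row], dests$id[col], departure), call. = FALSE)
  }
  nd <- matrix(provider$cache$distance_m[hit], nrow(origins))
  nt <- matrix(provider$cache$time_s[hit], nrow(origins))
  finish_route_matrices(nd, nt, origins$id, dests$id)
}

finish_route_matrices <- function(dist, time, origin_ids, dest_ids) {
  n_un <- sum(is.na(dist))
  if (n_un > 0) {
    warning(sprintf("%d origin-destination pair(s) unreachable; excluded from choice sets",
                    n_un), call. = FALSE)
  }
  list(route_m = proximity_matrix(dist, origin_ids, dest_ids, "route_m"),
       route_s = proximity_matrix(time, origin_ids, dest_ids, "route_s"))
}

# run expr under a temporary RNG seed, restoring global RNG state after
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-pair seed from the provider seed and both coordinates
pair_seed <- function(seed, origin, dest) {
  key <- sprintf("%.7f|%.7f|%.7f|%.7f", origin$lat, origin$lon, dest$lat, dest$lon)
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
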