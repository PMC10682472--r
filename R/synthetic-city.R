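#' Synthetic city configuration
#'
#' Parameters of the seeded toy-city generator. Defaults emulate, at desk
#' scale, the structure of a high-density Asian city: street blocks
#' clustered into dense neighborhoods with lognormal populations, parks with
#' lognormal areas spanning tens of square meters to tens of hectares
#' (mean near 10,000 m2), attribute presence probabilities rising weakly
#' with log park area, and walking routes generated either by a detour
#' factor (lognormal, median 1.52) over geometric distance or on a grid
#' street network.
#'
#' @param n_blocks,n_parks Counts (>= 1).
#' @param bbox Named numeric: `lat_min`, `lat_max`, `lon_min`, `lon_max`.
#' @param n_clusters Number of residential clusters (<= `n_blocks`).
#' @param pop_meanlog,pop_sdlog Lognormal block-population parameters.
#' @param park_size_meanlog,park_size_sdlog Lognormal park-area parameters
#'   (defaults give mean area ~1e4 m2); areas are clamped to
#'   \[10, 687,237\] m2.
#' @param size_ai_coupling Strength of the log-area effect on attribute
#'   presence (0 = attributes independent of size). The default gives the
#'   weak area-attractiveness correlation seen in real park inventories
#'   (R2 of order 0.1-0.3).
#' @param route_model `"factor"` or `"grid"`.
#' @param factor_meanlog,factor_sdlog Detour-factor lognormal parameters.
#' @param walk_speed_kmh Walking speed for the factor route model.
#' @param grid_nx,grid_ny Grid-network dimensions (route_model `"grid"`).
#' @param edge_deletion_rate Fraction of grid edges to try deleting while
#'   preserving connectivity.
#' @param speed_range_kmh Range of per-edge walking speeds.
#' @param tpu_grid,dc_grid Planning-unit grids (rows, cols); `tpu_grid`
#'   must nest inside `dc_grid` (elementwise divisible) so every block has
#'   exactly one TPU inside exactly one DC.
#' @param seed Integer seed; identical seed and config give an identical
#'   city.
#' @return A `city_config` list.
#' @export
city_config <- function(n_blocks = 200, n_parks = 80,
                        bbox = c(lat_min = 22.20, lat_max = 22.36,
                                 lon_min = 114.10, lon_max = 114.26),
                        n_clusters = 6,
                        pop_meanlog = log(3000), pop_sdlog = 0.8,
                        park_size_meanlog = log(10000) - 1.5^2 / 2,
                        park_size_sdlog = 1.5,
                        size_ai_coupling = 1.1,
                        route_model = c("factor", "grid"),
                        factor_meanlog = log(1.52), factor_sdlog = 0.1,
                        walk_speed_kmh = 4,
                        grid_nx = 12, grid_ny = 12,
                        edge_deletion_rate = 0.05,
                        speed_range_kmh = c(3.5, 5),
                        tpu_grid = c(4, 4), dc_grid = c(2, 2),
                        seed = 1L) {
  route_model <- match.arg(route_model)
  stopifnot(n_blocks >= 1, n_parks >= 1, n_clusters >= 1,
            bbox["lat_max"] > bbox["lat_min"], bbox["lon_max"] > bbox["lon_min"],
            all(tpu_grid %% dc_grid == 0))
  if (n_clusters > n_blocks) {
    stop("infeasible config: more clusters than blocks", call. = FALSE)
  }
  structure(as.list(environment()), class = "city_config")
}

#' Generate a complete synthetic city
#'
#' Deterministically (under `config$seed`) generates street blocks with
#' populations and nested TPU/DC planning-unit assignments, parks with
#' areas, NDVI surrogates, the ten binary attributes and the resulting
#' attractiveness index, and a route source (detour-factor provider or grid
#' street network). All randomness flows through one seeded generator; the
#' caller's RNG state is untouched.
#'
#' @param config A [city_config()].
#' @return List with `blocks`, `parks`, `provider`, `network` (or `NULL`),
#'   and the `config`.
#' @export
generate_city <- function(config = city_config()) {
  stopifnot(inherits(config, "city_config"))
  with_local_seed(config$seed, generate_city_impl(config))
}

generate_city_impl <- function(cfg) {
  bb <- cfg$bbox
  lat_span <- bb["lat_max"] - bb["lat_min"]
  lon_span <- bb["lon_max"] - bb["lon_min"]

  # residential clusters: blocks scatter around cluster centres
  centers <- tibble::tibble(
    lat = stats::runif(cfg$n_clusters, bb["lat_min"] + 0.15 * lat_span,
                       bb["lat_max"] - 0.15 * lat_span),
    lon = stats::runif(cfg$n_clusters, bb["lon_min"] + 0.15 * lon_span,
                       bb["lon_max"] - 0.15 * lon_span))
  cl <- sample.int(cfg$n_clusters, cfg$n_blocks, replace = TRUE)
  blat <- clamp(centers$lat[cl] + stats::rnorm(cfg$n_blocks, 0, lat_span / 25),
                bb["lat_min"], bb["lat_max"])
  blon <- clamp(centers$lon[cl] + stats::rnorm(cfg$n_blocks, 0, lon_span / 25),
                bb["lon_min"], bb["lon_max"])
  pop <- round(stats::rlnorm(cfg$n_blocks, cfg$pop_meanlog, cfg$pop_sdlog))

  tpu <- grid_cell(blat, blon, bb, cfg$tpu_grid)
  dcr <- cfg$tpu_grid / cfg$dc_grid  # tpu cells per dc cell, per axis
  dc <- paste0("D", sprintf("%02d", (ceiling(tpu$row / dcr[1]) - 1) * cfg$dc_grid[2] +
                              ceiling(tpu$col / dcr[2])))
  # block footprint area (km2) from its TPU cell, split among co-resident blocks
  cell_km2 <- cell_area_km2(bb, cfg$tpu_grid)
  blocks <- tibble::tibble(
    id = sprintf("SB%04d", seq_len(cfg$n_blocks)),
    lat = as.numeric(blat), lon = as.numeric(blon),
    population = as.numeric(pop),
    tpu_id = tpu$id, dc_id = dc)
  blocks$area_km2 <- cell_km2 / ave(rep(1, nrow(blocks)), blocks$tpu_id, FUN = sum)

  # parks: lognormal areas, size-coupled attributes, NDVI surrogate
  plat <- stats::runif(cfg$n_parks, bb["lat_min"], bb["lat_max"])
  plon <- stats::runif(cfg$n_parks, bb["lon_min"], bb["lon_max"])
  area <- clamp(stats::rlnorm(cfg$n_parks, cfg$park_size_meanlog,
                              cfg$park_size_sdlog), 10, 687237)
  z <- as.numeric(scale(log(area)))
  if (all(is.na(z))) z <- rep(0, cfg$n_parks)  # single park / zero variance
  base <- c(activity_spaces = 0.5, children_playground = 0.6,
            water_features = 0.25, wildlife_gardens = 0.3,
            walking_path = 0.9, public_art = 0.25, public_toilets = 0.5,
            car_parking = 0.35, barbeque = 0.15)
  parks <- tibble::tibble(
    id = sprintf("P%04d", seq_len(cfg$n_parks)),
    lat = plat, lon = plon, area_m2 = area)
  for (attr in names(base)) {
    p <- stats::plogis(stats::qlogis(base[[attr]]) + cfg$size_ai_coupling * z)
    parks[[attr]] <- stats::rbinom(cfg$n_parks, 1, p)
  }
  # greenery: NDVI rises weakly with size; trees flag binarized at 0.2
  parks$ndvi_mean <- clamp(0.22 + 0.06 * cfg$size_ai_coupling * z +
                             stats::rnorm(cfg$n_parks, 0, 0.12), -1, 1)
  parks$trees <- as.integer(ndvi_to_trees_flag(parks$ndvi_mean))
  parks <- parks[, c("id", "lat", "lon", "area_m2", park_attribute_names,
                     "ndvi_mean")]
  parks <- add_ai(parks)

  if (cfg$route_model == "factor") {
    provider <- factor_route_provider(meanlog = cfg$factor_meanlog,
                                      sdlog = cfg$factor_sdlog,
                                      speed_kmh = cfg$walk_speed_kmh,
                                      seed = cfg$seed + 1L)
    network <- NULL
  } else {
    network <- generate_grid_network(bbox = bb, nx = cfg$grid_nx,
                                     ny = cfg$grid_ny,
                                     deletion_rate = cfg$edge_deletion_rate,
                                     speed_range_kmh = cfg$speed_range_kmh)
    # snap radius generous enough to reach the lattice from any block
    spacing <- max(haversine_distance(bb["lat_min"], bb["lon_min"],
                                      bb["lat_min"] + lat_span / (cfg$grid_ny - 1),
                                      bb["lon_min"]),
                   haversine_distance(bb["lat_min"], bb["lon_min"], bb["lat_min"],
                                      bb["lon_min"] + lon_span / (cfg$grid_nx - 1)))
    provider <- graph_route_provider(network, snap_radius_m = spacing)
  }
  list(blocks = blocks, parks = parks, provider = provider,
       network = network, config = cfg)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

grid_cell <- function(lat, lon, bb, dims) {
  row <- pmin(pmax(ceiling((lat - bb["lat_min"]) /
                             (bb["lat_max"] - bb["lat_min"]) * dims[1]), 1), dims[1])
  col <- pmin(pmax(ceiling((lon - bb["lon_min"]) /
                             (bb["lon_max"] - bb["lon_min"]) * dims[2]), 1), dims[2])
  list(row = row, col = col,
       id = paste0("T", sprintf("%02d", (row - 1) * dims[2] + col)))
}

cell_area_km2 <- function(bb, dims) {
  h_m <- haversine_distance(bb["lat_min"], bb["lon_min"], bb["lat_max"], bb["lon_min"])
  mid <- (bb["lat_min"] + bb["lat_max"]) / 2
  w_m <- haversine_distance(mid, bb["lon_min"], mid, bb["lon_max"])
  unname(h_m * w_m / 1e6 / prod(dims))
}

#' Generate a connected grid street network
#'
#' Builds an `nx` x `ny` lattice of nodes over the bounding box, connects
#' horizontal/vertical neighbors with edges whose lengths are great-circle
#' distances, assigns per-edge walking speeds uniformly from
#' `speed_range_kmh`, then attempts random edge deletions that are rolled
#' back whenever they would disconnect the network — the result is always a
#' single component.
#'
#' @param bbox Named numeric bounding box (see [city_config()]).
#' @param nx,ny Grid dimensions, each >= 2.
#' @param deletion_rate Fraction of edges to try deleting.
#' @param speed_range_kmh Min/max per-edge walking speed.
#' @return A [street_network()].
#' @export
generate_grid_network <- function(bbox = c(lat_min = 22.20, lat_max = 22.36,
                                           lon_min = 114.10, lon_max = 114.26),
                                  nx = 12, ny = 12, deletion_rate = 0,
                                  speed_range_kmh = c(3.5, 5)) {
  stopifnot(nx >= 2, ny >= 2, deletion_rate >= 0, deletion_rate < 1)
  lats <- seq(bbox["lat_min"], bbox["lat_max"], length.out = ny)
  lons <- seq(bbox["lon_min"], bbox["lon_max"], length.out = nx)
  idx <- function(r, c) paste0("N", sprintf("%03d_%03d", r, c))
  nodes <- tibble::tibble(
    node_id = as.vector(outer(seq_len(ny), seq_len(nx), idx)),
    lat = rep(lats, times = nx), lon = rep(lons, each = ny))
  e <- list()
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    if (c < nx) e[[length(e) + 1]] <- c(idx(r, c), idx(r, c + 1))
    if (r < ny) e[[length(e) + 1]] <- c(idx(r, c), idx(r + 1, c))
  }
  em <- do.call(rbind, e)
  coord <- function(id) nodes[match(id, nodes$node_id), c("lat", "lon")]
  a <- coord(em[, 1]); b <- coord(em[, 2])
  edges <- tibble::tibble(
    u = em[, 1], v = em[, 2],
    length_m = haversine_distance(a$lat, a$lon, b$lat, b$lon),
    speed_kmh = stats::runif(nrow(em), speed_range_kmh[1], speed_range_kmh[2]))
  if (deletion_rate > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("u", "v")], directed = FALSE)
    target <- floor(deletion_rate * nrow(edges))
    cand <- sample.int(nrow(edges))
    kept <- rep(TRUE, nrow(edges))
    removed <- 0
    for (i in cand) {
      if (removed >= target) break
      trial <- kept; trial[i] <- FALSE
      gt <- igraph::subgraph_from_edges(g, which(trial), delete.vertices = FALSE)
      if (igraph::is_connected(gt)) {
        kept <- trial
        removed <- removed + 1
      }
    }
    edges <- edges[kept, ]
  }
  street_network(nodes, edges)
}

#' Population density per planning unit
#'
#' Sums block populations and block footprint areas within each unit of the
#' requested level and returns persons per square kilometer, as needed for
#' hotspot flagging.
#'
#' @param blocks Block table with `population`, `area_km2`, `tpu_id`,
#'   `dc_id`.
#' @param level `"TPU"`, `"DC"`, or `"territory"`.
#' @return Tibble with `unit_id`, `density` (persons/km2).
#' @export
population_density <- function(blocks, level = c("TPU", "DC", "territory")) {
  level <- match.arg(level)
  group <- switch(level, TPU = blocks$tpu_id, DC = blocks$dc_id,
                  territory = rep("territory", nrow(blocks)))
  tibble::tibble(unit_id = group, population = blocks$population,
                 area_km2 = blocks$area_km2) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(density = sum(.data$population) / sum(.data$area_km2),
                     .groups = "drop")
}
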