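#' File adapters
#'
#' Readers and writers for the pipeline's plain-text formats: block and park
#' tables (CSV or GeoJSON points), street networks (node+edge CSV or GeoJSON
#' lines), proximity matrices (long CSV), route caches (CSV), accessibility
#' surfaces (CSV, GeoJSON), and YAML run configs. GeoJSON coordinates follow
#' the standard lon,lat order; internally everything is lat,lon — the
#' adapters own the swap. All files are UTF-8 with mandatory headers, and
#' floats are written at full precision so exact algebraic identities
#' survive a round trip.
#'
#' @name io-adapters
NULL

is_geojson_path <- function(path) grepl("\\.(geojson|json)$", path, ignore.case = TRUE)

# CSV writer that renders doubles with 17 significant digits so that a
# write/read cycle reproduces every value bit for bit
write_csv_full <- function(df, path) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      out <- sprintf("%.17g", df[[col]])
      out[is.na(df[[col]])] <- NA_character_
      df[[col]] <- out
    }
  }
  readr::write_csv(df, path)
  invisible(path)
}

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s file '%s' is missing column(s): %s", what, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read / write street-block tables
#'
#' Columns: `id`, `lat`, `lon`, `population`, `tpu_id`, `dc_id`, optional
#' `area_km2`. GeoJSON uses Point features with the non-spatial columns as
#' properties.
#'
#' @param path File path (`.csv`, `.geojson`/`.json`).
#' @return Tibble of blocks.
#' @export
read_blocks <- function(path) {
  df <- if (is_geojson_path(path)) {
    read_geojson_points(path)
  } else {
    read_table_checked(path, c("id", "lat", "lon", "population", "tpu_id", "dc_id"),
                       "blocks")
  }
  bad <- which(!is.finite(df$population) | df$population < 0)
  if (length(bad)) {
    stop(sprintf("blocks file '%s': invalid population at row %d", path, bad[1]),
         call. = FALSE)
  }
  check_point_table(df, "blocks")
  df$id <- as.character(df$id)
  tibble::as_tibble(df)
}

#' @rdname read_blocks
#' @param blocks Block table.
#' @export
write_blocks <- function(blocks, path) {
  if (is_geojson_path(path)) write_geojson_points(blocks, path)
  else readr::write_csv(blocks, path)
  invisible(path)
}

#' Read / write park tables
#'
#' Columns: `id`, `lat`, `lon`, `area_m2`, the ten 0/1 attribute columns,
#' optional `ndvi_mean` and `ai`.
#'
#' @param path File path (`.csv`, `.geojson`/`.json`).
#' @return Tibble of parks.
#' @export
read_parks <- function(path) {
  df <- if (is_geojson_path(path)) read_geojson_points(path)
  else read_table_checked(path, c("id", "lat", "lon", "area_m2"), "parks")
  bad <- which(!is.finite(df$area_m2) | df$area_m2 <= 0)
  if (length(bad)) {
    stop(sprintf("parks file '%s': non-positive area at row %d", path, bad[1]),
         call. = FALSE)
  }
  check_point_table(df, "parks")
  df$id <- as.character(df$id)
  tibble::as_tibble(df)
}

#' @rdname read_parks
#' @param parks Park table.
#' @export
write_parks <- function(parks, path) {
  if (is_geojson_path(path)) write_geojson_points(parks, path)
  else readr::write_csv(parks, path)
  invisible(path)
}

#' Read / write a street network
#'
#' CSV form: a node file (`node_id`, `lat`, `lon`) and an edge file
#' (`u`, `v`, `length_m`, `speed_kmh`).
#'
#' @param nodes_path,edges_path CSV paths.
#' @return A [street_network()].
#' @export
read_network <- function(nodes_path, edges_path) {
  nodes <- read_table_checked(nodes_path, c("node_id", "lat", "lon"), "network nodes")
  edges <- read_table_checked(edges_path, c("u", "v", "length_m", "speed_kmh"),
                              "network edges")
  street_network(nodes, edges)
}

#' @rdname read_network
#' @param network A [street_network()].
#' @export
write_network <- function(network, nodes_path, edges_path) {
  readr::write_csv(network$nodes, nodes_path)
  readr::write_csv(network$edges, edges_path)
  invisible(c(nodes_path, edges_path))
}

#' Read / write proximity matrices as long CSV
#'
#' Columns: `origin_id`, `dest_id`, `metric`, `value`; unreachable pairs are
#' empty `value` cells.
#'
#' @param path CSV path.
#' @return A [proximity_matrix()].
#' @export
read_proximity_matrix <- function(path) {
  df <- read_table_checked(path, c("origin_id", "dest_id", "metric", "value"),
                           "proximity matrix")
  metric <- unique(df$metric)
  if (length(metric) != 1) {
    stop("proximity matrix file must hold exactly one metric, found: ",
         paste(metric, collapse = ", "), call. = FALSE)
  }
  o <- unique(as.character(df$origin_id))
  d <- unique(as.character(df$dest_id))
  m <- matrix(NA_real_, length(o), length(d), dimnames = list(o, d))
  m[cbind(match(as.character(df$origin_id), o),
          match(as.character(df$dest_id), d))] <- df$value
  proximity_matrix(m, o, d, metric)
}

#' @rdname read_proximity_matrix
#' @param matrix A [proximity_matrix()].
#' @export
write_proximity_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "proximity_matrix"))
  long <- tidyr::expand_grid(origin_id = matrix$origin_ids,
                             dest_id = matrix$dest_ids)
  long$metric <- matrix$metric
  long$value <- as.vector(t(matrix$values))
  write_csv_full(long, path)
  invisible(path)
}

#' Read / write route caches
#'
#' Columns: `origin_id`, `dest_id`, `departure`, `distance_m`, `time_s`.
#'
#' @param path CSV path.
#' @return Tibble cache, usable with [cached_route_provider()].
#' @export
read_route_cache <- function(path) {
  if (!file.exists(path)) stop("route cache file not found: ", path, call. = FALSE)
  # departure is an opaque key (e.g. "08:00"); never let it parse as a time
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(departure = readr::col_character(),
                                                .default = readr::col_guess()))
  miss <- setdiff(c("origin_id", "dest_id", "departure", "distance_m", "time_s"),
                  names(df))
  if (length(miss)) {
    stop(sprintf("route cache file '%s' is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df$origin_id <- as.character(df$origin_id)
  df$dest_id <- as.character(df$dest_id)
  df$departure <- as.character(df$departure)
  df
}

#' @rdname read_route_cache
#' @param cache Cache tibble.
#' @export
write_route_cache <- function(cache, path) {
  write_csv_full(cache[, c("origin_id", "dest_id", "departure",
                           "distance_m", "time_s")], path)
  invisible(path)
}

#' Build a route cache from any provider
#'
#' Materializes a provider's answers for all origin-destination pairs into
#' the cache schema, so later runs can use [cached_route_provider()].
#'
#' @inheritParams build_route_matrices
#' @return Cache tibble.
#' @export
build_route_cache <- function(provider, origins, dests, departure = "08:00") {
  mats <- build_route_matrices(provider, origins, dests, departure)
  tidyr::expand_grid(origin_id = origins$id, dest_id = dests$id) |>
    dplyr::mutate(departure = departure,
                  distance_m = as.vector(t(mats$route_m$values)),
                  time_s = as.vector(t(mats$route_s$values)))
}

#' Read / write accessibility surfaces
#'
#' Long CSV: `level`, `unit_id`, `variant`, `pwp`, `unit` (m or s),
#' `population`.
#'
#' @param path CSV path.
#' @return Tibble of surface rows.
#' @export
read_surfaces <- function(path) {
  read_table_checked(path, c("level", "unit_id", "variant", "pwp", "unit",
                             "population"), "surfaces")
}

#' @rdname read_surfaces
#' @param surfaces Surface tibble (from [run_model()]).
#' @export
write_surfaces <- function(surfaces, path) {
  readr::write_csv(surfaces, path)
  invisible(path)
}

#' Write an SB-level surface as GeoJSON points
#'
#' Joins a surface's values onto block centroids and writes Point features
#' with the PWP value as a property, for quick mapping.
#'
#' @param surface Tibble with `unit_id`, `pwp` (SB level).
#' @param blocks Block table providing centroids.
#' @param path Output path.
#' @export
write_surface_geojson <- function(surface, blocks, path) {
  df <- dplyr::inner_join(
    tibble::tibble(id = as.character(surface$unit_id), pwp = surface$pwp),
    dplyr::mutate(blocks, id = as.character(.data$id)), by = "id")
  write_geojson_points(df, path)
  invisible(path)
}

# --- GeoJSON (RFC 7946 subset: Point FeatureCollections) ---------------------

read_geojson_points <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection in ", path, call. = FALSE)
  }
  rows <- lapply(gj$features, function(f) {
    if (f$geometry$type != "Point") {
      stop("only Point geometries are supported, found ", f$geometry$type,
           call. = FALSE)
    }
    coords <- f$geometry$coordinates  # GeoJSON order: lon, lat
    c(list(lat = coords[[2]], lon = coords[[1]]), f$properties)
  })
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

write_geojson_points <- function(df, path) {
  props <- setdiff(names(df), c("lat", "lon"))
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$lon[i], df$lat[i])),  # lon, lat
         properties = as.list(df[i, props, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Keys: input paths (`blocks`, `parks`, optional `network_nodes`,
#' `network_edges`, `route_cache`), `variants`, decay parameters (`alpha`,
#' `beta`, `lambda`), `k`, floors, `ndvi_threshold`, `levels`, `out_dir`,
#' `seed`. Referenced paths are checked at validation time.
#'
#' @param path YAML file.
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(variants = c("PWGD", "PWRD", "PWRD_Attr", "PWRT_Attr"),
                   alpha = 0.85, beta = 1.91, lambda = 0.52, k = 7,
                   proximity_floor = 10, ai_floor = 0.1, ndvi_threshold = 0.2,
                   levels = c("TPU", "DC", "territory"),
                   out_dir = ".", seed = 1L, departure = "08:00")
  cfg <- utils::modifyList(defaults, cfg)
  if (cfg$k < 1) stop("config: k must be >= 1", call. = FALSE)
  if (length(cfg$variants) < 1) stop("config: at least one variant required", call. = FALSE)
  for (key in c("blocks", "parks", "network_nodes", "network_edges", "route_cache")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop(sprintf("config: %s path does not exist: %s", key, cfg[[key]]),
           call. = FALSE)
    }
  }
  cfg
}
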