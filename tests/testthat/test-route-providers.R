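test_that("constant-factor provider scales geometric distance and converts time", {
  p <- factor_route_provider(factor = 1.5, speed_kmh = 5)
  # pick coordinates exactly 1000 m apart along the equator
  dlon <- 1000 / (6371000 * pi / 180)
  r <- route_metrics(p, list(lat = 0, lon = 0), list(lat = 0, lon = dlon))
  expect_equal(r$distance_m, 1500, tolerance = 1e-9)
  expect_equal(r$time_s, 1080, tolerance = 1e-9)  # 1500 m at 5 km/h
  expect_true(r$reachable)
})

test_that("constant-factor route matrix equals factor times geometric exactly", {
  o <- random_points(4, "o", 3); d <- random_points(6, "d", 4)
  geo <- build_geometric_matrix(o, d)
  mats <- build_route_matrices(factor_route_provider(factor = 1.5, speed_kmh = 4),
                               o, d)
  expect_identical(mats$route_m$values, geo$values * 1.5)
  expect_identical(mats$route_s$values, mats$route_m$values / (4 / 3.6))
  expect_equal(mats$route_m$metric, "route_m")
  expect_equal(mats$route_s$metric, "route_s")
})

test_that("sampled-factor provider is deterministic under its seed and factors >= 1 typically exceed geometric", {
  o <- random_points(5, "o", 5); d <- random_points(5, "d", 6)
  p <- factor_route_provider(seed = 99)
  m1 <- build_route_matrices(p, o, d)
  m2 <- build_route_matrices(p, o, d)
  expect_identical(m1$route_m$values, m2$route_m$values)
  # scalar calls are deterministic per pair too
  r1 <- route_metrics(p, o[1, ], d[1, ])
  r2 <- route_metrics(p, o[1, ], d[1, ])
  expect_identical(r1$distance_m, r2$distance_m)
  # lognormal median 1.52, sigma 0.1: factors concentrate well above 1
  geo <- build_geometric_matrix(o, d)
  ratios <- m1$route_m$values / geo$values
  expect_true(all(ratios > 1))
  expect_equal(median(ratios), 1.52, tolerance = 0.15)
})

test_that("graph provider routes a single-edge network and handles origin == dest", {
  nodes <- data.frame(node_id = c("a", "b"), lat = c(0, 0.0063), lon = c(0, 0))
  net <- street_network(nodes, data.frame(u = "a", v = "b",
                                          length_m = 700, speed_kmh = 5))
  p <- graph_route_provider(net, snap_radius_m = 500)
  r <- route_metrics(p, list(lat = 0, lon = 0), list(lat = 0.0063, lon = 0))
  expect_equal(r$distance_m, 700)
  expect_equal(r$time_s, 700 / (5 / 3.6))
  same <- route_metrics(p, list(lat = 0, lon = 0), list(lat = 0, lon = 0))
  expect_equal(same$distance_m, 0)
  expect_equal(same$time_s, 0)
})

test_that("graph provider matches brute-force path enumeration on random small graphs", {
  set.seed(21)
  for (trial in 1:8) {
    n <- sample(4:8, 1)
    # random connected graph: spanning chain plus random extra edges
    nodes <- data.frame(node_id = paste0("n", 1:n),
                        lat = runif(n, 22.2, 22.21), lon = runif(n, 114.1, 114.11))
    chain <- data.frame(u = paste0("n", 1:(n - 1)), v = paste0("n", 2:n))
    extra_n <- sample(0:3, 1)
    extra <- data.frame(u = paste0("n", sample(n, extra_n, TRUE)),
                        v = paste0("n", sample(n, extra_n, TRUE)))
    edges <- rbind(chain, extra)
    edges <- edges[edges$u != edges$v, ]
    edges$length_m <- runif(nrow(edges), 50, 800)
    edges$speed_kmh <- runif(nrow(edges), 3, 6)
    net <- street_network(nodes, edges)
    p <- graph_route_provider(net, snap_radius_m = 5000)
    from <- sample(n, 1); to <- sample(n, 1)
    got <- route_metrics(p, nodes[from, c("lat", "lon")], nodes[to, c("lat", "lon")])
    want <- brute_force_route(edges, paste0("n", from), paste0("n", to))
    expect_equal(got$distance_m, want$distance_m, tolerance = 1e-9)
  }
})

test_that("graph route distance is never below the snapped-node great-circle distance", {
  set.seed(31)
  net <- generate_grid_network(nx = 5, ny = 5, deletion_rate = 0.1)
  p <- graph_route_provider(net, snap_radius_m = 10000)
  nd <- net$nodes
  for (i in 1:20) {
    a <- nd[sample(nrow(nd), 1), ]; b <- nd[sample(nrow(nd), 1), ]
    r <- route_metrics(p, a, b)
    expect_gte(r$distance_m + 1e-9,
               haversine_distance(a$lat, a$lon, b$lat, b$lon))
  }
})

test_that("disconnected or unsnappable pairs are reported unreachable, not infinite", {
  nodes <- data.frame(node_id = c("a", "b", "c", "d"),
                      lat = c(0, 0.001, 0.1, 0.101), lon = c(0, 0, 0, 0))
  edges <- data.frame(u = c("a", "c"), v = c("b", "d"),
                      length_m = c(100, 100), speed_kmh = 5)
  p <- graph_route_provider(street_network(nodes, edges), snap_radius_m = 300)
  r <- route_metrics(p, list(lat = 0, lon = 0), list(lat = 0.1, lon = 0))
  expect_false(r$reachable)
  expect_true(is.na(r$distance_m))
  # far outside the snap radius
  far <- route_metrics(p, list(lat = 0.05, lon = 0.05), list(lat = 0, lon = 0))
  expect_false(far$reachable)
  # matrix build warns and stores NA, never Inf
  o <- data.frame(id = "o1", lat = 0, lon = 0)
  d <- data.frame(id = c("d1", "d2"), lat = c(0.001, 0.1), lon = 0)
  expect_warning(mats <- build_route_matrices(p, o, d), "unreachable")
  expect_equal(mats$route_m$values[1, "d1"], 100)
  expect_true(is.na(mats$route_m$values[1, "d2"]))
})

test_that("cached provider replays results and names missing pairs", {
  cache <- data.frame(origin_id = "o1", dest_id = "d1", departure = "08:00",
                      distance_m = 123.5, time_s = 99)
  p <- cached_route_provider(cache)
  r <- route_metrics(p, list(id = "o1"), list(id = "d1"))
  expect_equal(r$distance_m, 123.5)
  expect_equal(r$time_s, 99)
  expect_error(route_metrics(p, list(id = "o1"), list(id = "dX")),
               "o1.*dX", perl = TRUE)
  # departure is part of the key
  expect_error(route_metrics(p, list(id = "o1"), list(id = "d1"),
                             departure = "09:00"), "09:00")
})

test_that("a cache written by one provider feeds the cached provider identically", {
  o <- random_points(3, "o", 8); d <- random_points(4, "d", 9)
  fp <- factor_route_provider(factor = 1.3, speed_kmh = 4)
  cache <- build_route_cache(fp, o, d)
  cp <- cached_route_provider(cache)
  direct <- build_route_matrices(fp, o, d)
  replay <- build_route_matrices(cp, o, d)
  expect_identical(direct$route_m$values, replay$route_m$values)
  expect_identical(direct$route_s$values, replay$route_s$values)
})
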