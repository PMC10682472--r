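toy_matrix <- function(p, ids = paste0("P", seq_along(p)), block = "SB1",
                       metric = "route_m") {
  proximity_matrix(matrix(p, nrow = 1, dimnames = list(block, ids)),
                   block, ids, metric)
}

test_that("choice set keeps the k nearest reachable parks with deterministic ties", {
  # fewer parks than k: all selected
  cs <- select_choice_set("SB1", toy_matrix(c(300, 100, 200)), k = 7)
  expect_equal(cs$park_ids, c("P2", "P3", "P1"))
  expect_equal(cs$proximities, c(100, 200, 300))
  # exactly k: the farthest is excluded
  cs8 <- select_choice_set("SB1", toy_matrix(seq(100, 800, by = 100)), k = 7)
  expect_length(cs8$park_ids, 7)
  expect_false("P8" %in% cs8$park_ids)
  # tie for the last slot goes to the lower park id
  ptie <- toy_matrix(c(100, 200, 300, 400, 500, 600, 500, 500),
                     ids = c("P1", "P2", "P3", "P4", "P9", "P6", "P5", "P7"))
  cst <- select_choice_set("SB1", ptie, k = 7)
  expect_length(cst$park_ids, 7)
  # 500-m ties: P5, P7, P9 compete for two slots after P6 at 600 excluded
  expect_true(all(c("P5", "P7") %in% cst$park_ids))
  expect_false("P6" %in% cst$park_ids)
  # unreachable parks are never candidates
  csna <- select_choice_set("SB1", toy_matrix(c(NA, 400)), k = 7)
  expect_equal(csna$park_ids, "P2")
  # zero reachable parks: explicit empty signal
  cs0 <- select_choice_set("SB1", toy_matrix(c(NA_real_, NA_real_)), k = 7)
  expect_length(cs0$park_ids, 0)
})

test_that("visit probabilities normalize scores", {
  expect_equal(visit_probabilities(rep(2, 7)), rep(1 / 7, 7))
  expect_equal(visit_probabilities(c(3, 1)), c(0.75, 0.25))
  expect_equal(visit_probabilities(5), 1)
  expect_error(visit_probabilities(c(1, 0)), "positive")
  expect_error(visit_probabilities(numeric(0)), "empty")
})

test_that("block PWP is the probability-weighted proximity with convexity bounds", {
  # single park: PWP equals its proximity
  expect_equal(pwp_block(420, 1), 420)
  # equal scores at 100 m and 300 m average to 200 m
  expect_equal(pwp_block(c(100, 300), c(0.5, 0.5)), 200)
  expect_error(pwp_block(c(1, 2), 1), "mismatch")
  set.seed(12)
  for (i in 1:25) {
    n <- sample(1:7, 1)
    p <- runif(n, 50, 4000)
    pr <- visit_probabilities(runif(n, 0.1, 5))
    v <- pwp_block(p, pr)
    expect_gte(v, min(p)); expect_lte(v, max(p))
  }
})

test_that("aggregation is the population-weighted mean with convexity bounds", {
  blocks <- data.frame(id = c("a", "b"), population = c(1, 3),
                       tpu_id = "T1", dc_id = "D1")
  bp <- data.frame(unit_id = c("a", "b"), pwp = c(100, 200))
  agg <- pwp_aggregate(bp, blocks, "TPU")
  expect_equal(agg$pwp, 175)  # (1*100 + 3*200) / 4
  expect_equal(agg$population, 4)
  # single-block unit passes through; constant PWP is preserved
  one <- pwp_aggregate(bp[1, ], blocks[1, ], "DC")
  expect_equal(one$pwp, 100)
  bp$pwp <- c(250, 250)
  expect_equal(pwp_aggregate(bp, blocks, "territory")$pwp, 250)
  # zero-population unit is emitted with NA
  blocks0 <- data.frame(id = "z", population = 0, tpu_id = "T9", dc_id = "D9")
  agg0 <- pwp_aggregate(data.frame(unit_id = "z", pwp = 50), blocks0, "TPU")
  expect_true(is.na(agg0$pwp))
})

test_that("one-block one-park city yields the park proximity at every level", {
  blocks <- data.frame(id = "SB1", lat = 22.3, lon = 114.2, population = 500,
                       tpu_id = "T1", dc_id = "D1")
  parks <- make_parks(1, seed = 9)
  pm <- build_geometric_matrix(blocks, parks)
  surf <- run_model(blocks, parks, pm, "PWGD")
  expect_equal(unique(surf$pwp), pm$values[1, 1])
  expect_setequal(surf$level, c("SB", "TPU", "DC", "territory"))
})

test_that("full pipeline matches the independent naive oracle on random instances", {
  set.seed(33)
  for (trial in 1:10) {
    nb <- sample(1:5, 1); np <- sample(1:9, 1)
    blocks <- make_blocks(nb, seed = trial)
    parks <- make_parks(np, seed = trial + 100)
    pm <- build_geometric_matrix(blocks, parks)
    for (vn in c("PWGD")) {
      surf <- run_model(blocks, parks, pm, vn, k = 7)
      sb <- surf[surf$level == "SB", ]
      want <- naive_block_pwp(blocks, parks, pm$values, decay_params(),
                              use_attr = FALSE, k = 7)
      expect_equal(setNames(sb$pwp, sb$unit_id), want[sb$unit_id],
                   tolerance = 1e-9)
      tpu <- surf[surf$level == "TPU", ]
      want_tpu <- naive_aggregate(want, blocks, "tpu_id")
      expect_equal(setNames(tpu$pwp, tpu$unit_id), want_tpu[tpu$unit_id],
                   tolerance = 1e-9)
    }
    # attractiveness/time variants against the same oracle on route matrices
    mats <- build_route_matrices(factor_route_provider(seed = trial), blocks, parks)
    surf3 <- run_model(blocks, parks, mats, "PWRD_Attr", k = 7)
    sb3 <- surf3[surf3$level == "SB", ]
    want3 <- naive_block_pwp(blocks, parks, mats$route_m$values, decay_params(),
                             use_attr = TRUE, k = 7)
    expect_equal(setNames(sb3$pwp, sb3$unit_id), want3[sb3$unit_id],
                 tolerance = 1e-9)
  }
})

test_that("probability conservation, convexity, scale equivariance, and lambda-reduction hold across random cities", {
  # 100 random synthetic cities, fixed seed family
  for (s in 1:100) {
    city <- generate_city(city_config(n_blocks = 6, n_parks = 8,
                                      n_clusters = 2, seed = s))
    pm <- build_geometric_matrix(city$blocks, city$parks)
    A <- interaction_matrix(city$parks, pm, variant = model_variant("PWGD"))
    probs_ok <- TRUE; convex_ok <- TRUE
    for (b in city$blocks$id) {
      cs <- select_choice_set(b, pm, k = 7)
      pr <- visit_probabilities(A[b, cs$park_ids])
      if (abs(sum(pr) - 1) > 1e-12) probs_ok <- FALSE
      v <- pwp_block(cs$proximities, pr)
      if (v < min(cs$proximities) - 1e-9 || v > max(cs$proximities) + 1e-9) {
        convex_ok <- FALSE
      }
    }
    expect_true(probs_ok); expect_true(convex_ok)
    # scale equivariance: c * proximities => c * PWP (use floor-free range)
    cfac <- 1.7
    pm2 <- proximity_matrix(pm$values * cfac, pm$origin_ids, pm$dest_ids,
                            pm$metric)
    s1 <- run_model(city$blocks, city$parks, pm, "PWGD", proximity_floor = 1e-9)
    s2 <- run_model(city$blocks, city$parks, pm2, "PWGD", proximity_floor = 1e-9)
    expect_equal(s2$pwp, s1$pwp * cfac, tolerance = 1e-9)
    # lambda = 0 reduces PWRD_Attr to PWRD bit-for-bit
    mats <- build_route_matrices(city$provider, city$blocks, city$parks)
    p0 <- decay_params(lambda = 0)
    r2 <- run_model(city$blocks, city$parks, mats, "PWRD", params = p0)
    r3 <- run_model(city$blocks, city$parks, mats, "PWRD_Attr", params = p0)
    expect_identical(r2$pwp, r3$pwp)
  }
})

test_that("constant-factor provider ties the model variants together exactly", {
  city <- generate_city(city_config(n_blocks = 12, n_parks = 10, seed = 5))
  speed <- 5
  prov <- factor_route_provider(factor = 1.5, speed_kmh = speed)
  geo <- build_geometric_matrix(city$blocks, city$parks)
  mats <- build_route_matrices(prov, city$blocks, city$parks)
  # route = 1.5 x geometric  =>  PWRD surface = 1.5 x PWGD surface exactly
  pwgd <- run_model(city$blocks, city$parks, geo, "PWGD")
  pwrd <- run_model(city$blocks, city$parks, mats, "PWRD")
  expect_equal(pwrd$pwp, pwgd$pwp * 1.5, tolerance = 1e-12)
  # constant speed v  =>  PWRT_Attr surface = PWRD_Attr / v
  pwrd_a <- run_model(city$blocks, city$parks, mats, "PWRD_Attr")
  pwrt_a <- run_model(city$blocks, city$parks, mats, "PWRT_Attr")
  expect_equal(pwrt_a$pwp, pwrd_a$pwp / (speed / 3.6), tolerance = 1e-9)
})

test_that("missing matrices and unknown blocks raise clear errors", {
  blocks <- make_blocks(2, seed = 1); parks <- make_parks(2, seed = 1)
  pm <- build_geometric_matrix(blocks, parks)
  expect_error(run_model(blocks, parks, pm, "PWRD"), "route_m")
  expect_error(select_choice_set("nope", pm), "not found")
})
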