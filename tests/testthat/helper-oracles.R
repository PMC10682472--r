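# Independent naive oracles used to cross-check the package implementation.
# These deliberately share no code with R/: plain loops, no vectorization.

# expected proximity per block: interaction scores -> choice probabilities ->
# probability-weighted proximity, written as straight loops
naive_block_pwp <- function(blocks, parks, pm, params, use_attr, k = 7,
                            proximity_floor = 10, ai_floor = 0.1) {
  out <- numeric(0)
  for (i in seq_len(nrow(blocks))) {
    b <- as.character(blocks$id[i])
    p <- pm[b, ]
    ok <- which(!is.na(p))
    if (length(ok) == 0) next
    ord <- ok[order(p[ok], colnames(pm)[ok])]
    sel <- utils::head(ord, k)
    A <- numeric(length(sel))
    for (s in seq_along(sel)) {
      j <- sel[s]
      row <- match(colnames(pm)[j], as.character(parks$id))
      S <- parks$area_m2[row]
      a <- if (use_attr) max(parks$ai[row], ai_floor) else 1
      pp <- max(p[j], proximity_floor)
      A[s] <- a^params$lambda * S^params$alpha / pp^params$beta
    }
    P <- A / sum(A)
    out[b] <- sum(P * p[sel])
  }
  out
}

# population-weighted mean over member blocks, one group at a time
naive_aggregate <- function(block_pwp, blocks, group_col) {
  groups <- unique(as.character(blocks[[group_col]][
    as.character(blocks$id) %in% names(block_pwp)]))
  out <- numeric(0)
  for (g in groups) {
    ids <- as.character(blocks$id[as.character(blocks[[group_col]]) == g])
    ids <- ids[ids %in% names(block_pwp)]
    pops <- blocks$population[match(ids, as.character(blocks$id))]
    out[g] <- sum(pops * block_pwp[ids]) / sum(pops)
  }
  out
}

# minimum-length route via exhaustive simple-path enumeration (tiny graphs)
brute_force_route <- function(edges, from, to) {
  if (from == to) return(list(distance_m = 0, time_s = 0))
  adj <- list()
  add <- function(a, b, len, t) {
    adj[[a]] <<- rbind(adj[[a]], data.frame(to = b, len = len, t = t))
  }
  for (r in seq_len(nrow(edges))) {
    t_s <- edges$length_m[r] / (edges$speed_kmh[r] / 3.6)
    add(as.character(edges$u[r]), as.character(edges$v[r]), edges$length_m[r], t_s)
    add(as.character(edges$v[r]), as.character(edges$u[r]), edges$length_m[r], t_s)
  }
  best <- list(distance_m = Inf, time_s = Inf)
  walk <- function(node, visited, dist, time) {
    if (node == to) {
      if (dist < best$distance_m) best <<- list(distance_m = dist, time_s = time)
      return(invisible())
    }
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      if (nb$to[r] %in% visited) next
      walk(nb$to[r], c(visited, nb$to[r]), dist + nb$len[r], time + nb$t[r])
    }
  }
  walk(from, from, 0, 0)
  best
}

# closed-form simple linear regression
naive_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# random point tables for property tests
random_points <- function(n, prefix, seed) {
  set.seed(seed)
  data.frame(id = paste0(prefix, seq_len(n)),
             lat = runif(n, 22.2, 22.4),
             lon = runif(n, 114.1, 114.3))
}

# minimal valid park table with explicit attribute flags
make_parks <- function(n, seed = 1) {
  set.seed(seed)
  p <- random_points(n, "P", seed)
  p$area_m2 <- exp(runif(n, log(100), log(100000)))
  for (a in parkaccess::park_attribute_names) p[[a]] <- rbinom(n, 1, 0.5)
  parkaccess::add_ai(p)
}

make_blocks <- function(n, seed = 1) {
  set.seed(seed + 1000)
  b <- random_points(n, "SB", seed + 1000)
  b$population <- rpois(n, 2000)
  b$tpu_id <- paste0("T", 1 + (seq_len(n) - 1) %% max(1, n %/% 2))
  b$dc_id <- paste0("D", 1 + (seq_len(n) - 1) %% 2)
  b
}
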