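#' Route-versus-geometric distance regression and conversion factor
#'
#' Ordinary least squares of route distance on geometric distance (with
#' intercept, never forced through the origin). Because "conversion factor"
#' can mean either the fitted slope or the average per-pair ratio, both are
#' reported side by side.
#'
#' @param geometric,route Paired positive distance vectors of equal length
#'   (>= 2). `NA` pairs are dropped.
#' @return List with `slope`, `intercept`, `r_squared`, `mean_ratio`, `n`.
#' @export
fit_distance_regression <- function(geometric, route) {
  if (length(geometric) != length(route)) {
    stop("geometric and route must be paired vectors of equal length", call. = FALSE)
  }
  ok <- !is.na(geometric) & !is.na(route)
  geometric <- geometric[ok]; route <- route[ok]
  if (length(geometric) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (any(geometric <= 0) || any(route <= 0)) {
    stop("distances must be positive", call. = FALSE)
  }
  if (stats::var(geometric) == 0) {
    stop("degenerate predictor: geometric distances have zero variance", call. = FALSE)
  }
  fit <- stats::lm(route ~ geometric)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       mean_ratio = mean(route / geometric),
       n = length(geometric))
}

#' Relative difference between two accessibility surfaces
#'
#' Elementwise `(a - b) / b` over matched planning units, e.g. to quantify
#' how much farther route-based expected distances are than geometric ones.
#'
#' @param a,b Surfaces: data frames with `unit_id` and `pwp` (same units),
#'   or named numeric vectors.
#' @return Tibble with `unit_id` and `rel_diff` (unitless).
#' @export
relative_difference <- function(a, b) {
  a <- as_surface(a); b <- as_surface(b)
  only_a <- setdiff(a$unit_id, b$unit_id)
  only_b <- setdiff(b$unit_id, a$unit_id)
  if (length(only_a) || length(only_b)) {
    stop(sprintf("surface unit ids differ; only in a: {%s}; only in b: {%s}",
                 paste(only_a, collapse = ", "), paste(only_b, collapse = ", ")),
         call. = FALSE)
  }
  bv <- b$pwp[match(a$unit_id, b$unit_id)]
  if (any(bv <= 0)) stop("reference surface values must be positive", call. = FALSE)
  tibble::tibble(unit_id = a$unit_id, rel_diff = (a$pwp - bv) / bv)
}

as_surface <- function(x) {
  if (is.data.frame(x)) {
    need <- setdiff(c("unit_id", "pwp"), names(x))
    if (length(need)) stop("surface missing column(s): ", paste(need, collapse = ", "), call. = FALSE)
    tibble::tibble(unit_id = as.character(x$unit_id), pwp = x$pwp)
  } else if (is.numeric(x) && !is.null(names(x))) {
    tibble::tibble(unit_id = names(x), pwp = unname(x))
  } else {
    stop("a surface is a data frame with unit_id/pwp or a named numeric vector",
         call. = FALSE)
  }
}

#' Implied walking speed from distance and time surfaces
#'
#' Divides an expected-distance surface (meters) by the matching
#' expected-time surface (seconds), converted to km/h. Comparing the
#' route-distance and route-time models this way exposes where terrain or
#' crossings slow walking below the citywide norm.
#'
#' @param distance_surface Surface in meters (`unit_id`, `pwp`).
#' @param time_surface Surface in seconds over the same units.
#' @return Tibble with `unit_id` and `speed_kmh`.
#' @export
walking_speed <- function(distance_surface, time_surface) {
  d <- as_surface(distance_surface); t <- as_surface(time_surface)
  only_d <- setdiff(d$unit_id, t$unit_id); only_t <- setdiff(t$unit_id, d$unit_id)
  if (length(only_d) || length(only_t)) {
    stop(sprintf("surface unit ids differ; only in distance: {%s}; only in time: {%s}",
                 paste(only_d, collapse = ", "), paste(only_t, collapse = ", ")),
         call. = FALSE)
  }
  tv <- t$pwp[match(d$unit_id, t$unit_id)]
  if (any(tv <= 0)) stop("time surface values must be positive", call. = FALSE)
  tibble::tibble(unit_id = d$unit_id,
                 speed_kmh = (d$pwp / 1000) / (tv / 3600))
}

#' Flag planning-unit hotspots
#'
#' A hotspot is a unit that is simultaneously extreme on an accessibility
#' metric and dense in population — the places where poor access affects
#' the most people. Units at or above the `density_quantile` of population
#' density AND at or above (`direction = "high"`) or at or below
#' (`direction = "low"`, e.g. for walking speed) the `metric_quantile` of
#' the metric are flagged. Thresholds are inclusive, so ties flag together.
#'
#' @param metric_surface Surface (`unit_id`, `pwp`) of the metric.
#' @param pop_density Named numeric vector or data frame (`unit_id`,
#'   `density`) of persons per square kilometer over the same units.
#' @param metric_quantile,density_quantile Quantile cutoffs in (0, 1);
#'   defaults 0.9 and 0.9.
#' @param direction `"high"` if large metric values are bad, `"low"` if
#'   small values are bad.
#' @return List with `unit_ids` (flagged), `criterion`, `thresholds`.
#' @export
flag_hotspots <- function(metric_surface, pop_density,
                          metric_quantile = 0.9, density_quantile = 0.9,
                          direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (metric_quantile < 0 || metric_quantile >= 1 ||
      density_quantile < 0 || density_quantile >= 1) {
    stop("quantiles must lie in [0, 1); 0 disables that filter", call. = FALSE)
  }
  s <- as_surface(metric_surface)
  if (is.data.frame(pop_density)) {
    dens <- stats::setNames(pop_density$density, as.character(pop_density$unit_id))
  } else {
    dens <- pop_density
  }
  if (!all(s$unit_id %in% names(dens))) {
    stop("pop_density missing unit(s): ",
         paste(setdiff(s$unit_id, names(dens)), collapse = ", "), call. = FALSE)
  }
  if (nrow(s) < 5) stop("need at least 5 units for quantile-based flagging", call. = FALSE)
  dens <- dens[s$unit_id]
  d_thr <- if (density_quantile == 0) -Inf else stats::quantile(dens, density_quantile, names = FALSE)
  m_thr <- if (metric_quantile == 0) {
    if (direction == "high") -Inf else Inf
  } else {
    stats::quantile(s$pwp, metric_quantile, names = FALSE)
  }
  metric_hit <- if (direction == "high") s$pwp >= m_thr else s$pwp <= m_thr
  flagged <- s$unit_id[metric_hit & dens >= d_thr]
  list(unit_ids = flagged,
       criterion = sprintf(
         "population density >= q%.2f AND metric %s q%.2f (inclusive)",
         density_quantile, if (direction == "high") ">=" else "<=", metric_quantile),
       thresholds = c(metric = m_thr, density = d_thr))
}

#' Scatter plot of route against geometric distances with the fitted line
#'
#' @param geometric,route Paired distance vectors (meters).
#' @return A ggplot object.
#' @export
plot_distance_regression <- function(geometric, route) {
  fit <- fit_distance_regression(geometric, route)
  df <- tibble::tibble(geometric = geometric, route = route)
  ggplot2::ggplot(df, ggplot2::aes(x = geometric, y = route)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "red") +
    ggplot2::labs(
      x = "geometric distance (m)", y = "route distance (m)",
      subtitle = sprintf("route = %.1f + %.3f x geometric;  R² = %.3f;  mean ratio = %.3f",
                         fit$intercept, fit$slope, fit$r_squared, fit$mean_ratio)) +
    ggplot2::theme_minimal()
}
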