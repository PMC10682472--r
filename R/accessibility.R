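#' Choice set of the k nearest reachable parks
#'
#' A resident's candidate destinations are taken to be the k nearest parks
#' (default 7, an information-processing-theory estimate of how many nearby
#' parks a resident weighs when choosing one). Ranking uses the same
#' proximity metric as the model variant being run. Ties are broken by
#' ascending park id so selection is deterministic across platforms.
#' Unreachable parks (`NA` proximity) are never candidates.
#'
#' @param block_id Origin block id (one row of the matrix).
#' @param matrix A [proximity_matrix()] covering the block.
#' @param k Maximum choice-set size, >= 1. If fewer than `k` parks are
#'   reachable, all of them are used.
#' @return List with `block_id`, `park_ids`, `proximities` (ascending), or a
#'   zero-length choice set when no park is reachable.
#' @export
select_choice_set <- function(block_id, matrix, k = 7) {
  stopifnot(inherits(matrix, "proximity_matrix"), k >= 1)
  block_id <- as.character(block_id)
  row <- match(block_id, matrix$origin_ids)
  if (is.na(row)) stop("block '", block_id, "' not found in proximity matrix", call. = FALSE)
  p <- matrix$values[row, ]
  ok <- which(!is.na(p))
  ord <- ok[order(p[ok], matrix$dest_ids[ok])]
  sel <- utils::head(ord, k)
  list(block_id = block_id,
       park_ids = matrix$dest_ids[sel],
       proximities = unname(p[sel]))
}

#' Park-visit probabilities over a choice set
#'
#' Normalizes interaction scores into destination-choice probabilities:
#' the probability of visiting park j is its score divided by the summed
#' scores over the choice set.
#'
#' @param scores Positive interaction scores over the choice set.
#' @return Probabilities summing to 1, proportional to `scores`.
#' @export
visit_probabilities <- function(scores) {
  if (length(scores) == 0) stop("empty choice set has no probabilities", call. = FALSE)
  if (any(!is.finite(scores)) || any(scores <= 0)) {
    stop("interaction scores must be positive and finite", call. = FALSE)
  }
  scores / sum(scores)
}

#' Block-level population-weighted proximity
#'
#' Expected proximity (distance or time) from a block to its nearby parks:
#' the probability-weighted mean of choice-set proximities. Block population
#' multiplies and divides out at this level, so the value is the same for
#' any population; population enters when aggregating upward.
#'
#' @param proximities Choice-set proximities.
#' @param probabilities Matching visit probabilities.
#' @return Scalar expected proximity, bounded by the choice-set range.
#' @export
pwp_block <- function(proximities, probabilities) {
  if (length(proximities) != length(probabilities)) {
    stop(sprintf("length mismatch: %d proximities vs %d probabilities",
                 length(proximities), length(probabilities)), call. = FALSE)
  }
  sum(probabilities * proximities)
}

#' Aggregate block PWP values to a higher planning unit level
#'
#' Population-weighted mean of member-block PWP values within each unit of
#' the requested level (`TPU`, `DC`, or the whole `territory`). Blocks with
#' zero population keep their own PWP but contribute zero weight here; a
#' unit whose member blocks have zero total population is emitted with `NA`.
#'
#' @param block_pwp Data frame with columns `unit_id` (block id) and `pwp`.
#' @param blocks Block table with `id`, `population`, `tpu_id`, `dc_id`.
#' @param level `"TPU"`, `"DC"`, or `"territory"`.
#' @return Tibble with `unit_id`, `pwp`, `population`.
#' @export
pwp_aggregate <- function(block_pwp, blocks, level = c("TPU", "DC", "territory")) {
  level <- match.arg(level)
  need <- setdiff(c("id", "population", "tpu_id", "dc_id"), names(blocks))
  if (length(need)) stop("blocks missing column(s): ", paste(need, collapse = ", "), call. = FALSE)
  if (any(blocks$population < 0)) stop("populations must be non-negative", call. = FALSE)
  df <- dplyr::inner_join(
    block_pwp,
    dplyr::transmute(blocks, unit_id = as.character(.data$id),
                     population = .data$population,
                     tpu_id = as.character(.data$tpu_id),
                     dc_id = as.character(.data$dc_id)),
    by = "unit_id")
  group <- switch(level, TPU = df$tpu_id, DC = df$dc_id,
                  territory = rep("territory", nrow(df)))
  df |>
    dplyr::mutate(.unit = group) |>
    dplyr::group_by(.data$.unit) |>
    dplyr::summarise(
      pwp = if (sum(.data$population) > 0)
        sum(.data$population * .data$pwp) / sum(.data$population)
      else NA_real_,
      population = sum(.data$population), .groups = "drop") |>
    dplyr::rename(unit_id = ".unit")
}

#' Run one accessibility model end to end
#'
#' Executes the three-step procedure for one model variant: (1) interaction
#' scores for every block-park pair from the variant's proximity matrix,
#' (2) visit probabilities over each block's k-nearest choice set,
#' (3) block-level expected proximity, then population-weighted aggregation
#' to the requested planning-unit levels.
#'
#' @param blocks Block table: `id`, `lat`, `lon`, `population`, `tpu_id`,
#'   `dc_id`.
#' @param parks Park table: `id`, `lat`, `lon`, `area_m2`, attribute columns
#'   and/or `ai`.
#' @param matrices Named list of [proximity_matrix()] objects (names or
#'   metrics must cover the variant's metric), or a single matrix.
#' @param variant A [model_variant()] or its name.
#' @param params A [decay_params()].
#' @param k Choice-set size (default 7).
#' @param levels Aggregation levels to emit alongside `"SB"`.
#' @param proximity_floor,ai_floor Floors passed to [interaction_matrix()].
#' @param scheme [weight_scheme()] used to compute `ai` when the variant
#'   needs it and `parks` lacks the column.
#' @return Tibble: `level`, `unit_id`, `variant`, `pwp`, `unit` (`"m"` or
#'   `"s"`), `population`. Blocks with no reachable park are dropped with a
#'   warning.
#' @export
run_model <- function(blocks, parks, matrices,
                      variant = model_variant("PWGD"),
                      params = decay_params(), k = 7,
                      levels = c("TPU", "DC", "territory"),
                      proximity_floor = 10, ai_floor = 0.1,
                      scheme = weight_scheme()) {
  if (is.character(variant)) variant <- model_variant(variant)
  if (inherits(matrices, "proximity_matrix")) matrices <- list(matrices)
  mat <- NULL
  for (m in matrices) if (m$metric == variant$proximity_metric) mat <- m
  if (is.null(mat)) {
    stop("no proximity matrix with metric '", variant$proximity_metric,
         "' supplied for variant ", variant$name, call. = FALSE)
  }
  if (variant$use_attractiveness && is.null(parks$ai)) {
    parks <- add_ai(parks, scheme)
  }
  A <- interaction_matrix(parks, mat, params, variant,
                          proximity_floor = proximity_floor, ai_floor = ai_floor)

  block_ids <- as.character(blocks$id)
  pwp <- vapply(block_ids, function(b) {
    cs <- select_choice_set(b, mat, k)
    if (length(cs$park_ids) == 0) return(NA_real_)
    scores <- A[b, cs$park_ids]
    pwp_block(cs$proximities, visit_probabilities(scores))
  }, numeric(1))

  if (anyNA(pwp)) {
    warning(sprintf("%d block(s) have no reachable park and were dropped: %s",
                    sum(is.na(pwp)),
                    paste(utils::head(block_ids[is.na(pwp)], 5), collapse = ", ")),
            call. = FALSE)
  }
  sb <- tibble::tibble(unit_id = block_ids, pwp = unname(pwp)) |>
    dplyr::filter(!is.na(.data$pwp))

  unit <- if (variant$proximity_metric == "route_s") "s" else "m"
  pop <- blocks$population[match(sb$unit_id, block_ids)]
  out <- tibble::tibble(level = "SB", unit_id = sb$unit_id,
                        variant = variant$name, pwp = sb$pwp,
                        unit = unit, population = pop)
  for (lev in levels) {
    agg <- pwp_aggregate(sb, blocks, lev)
    out <- dplyr::bind_rows(out, tibble::tibble(
      level = lev, unit_id = agg$unit_id, variant = variant$name,
      pwp = agg$pwp, unit = unit, population = agg$population))
  }
  out
}
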