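#' Decay parameters of the resident-park interaction model
#'
#' Exponents of the gravity-type interaction score
#' `A = attr^lambda * S^alpha / p^beta`: `alpha` for park size, `beta` for
#' proximity (travel distance or time; the same value is used for both given
#' their shared physical meaning), and `lambda` for attractiveness. Defaults
#' (0.85, 1.91, 0.52) are the published survey-based estimates the framework
#' adopts; alternatives can be supplied when local estimates exist.
#'
#' @param alpha Size exponent, >= 0.
#' @param beta Proximity decay exponent, > 0.
#' @param lambda Attractiveness exponent, >= 0.
#' @return A `decay_params` object.
#' @export
decay_params <- function(alpha = 0.85, beta = 1.91, lambda = 0.52) {
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, lambda = lambda),
            class = "decay_params")
}

#' Interaction model variants
#'
#' The four resident-park interaction models compared by the framework:
#' \describe{
#'   \item{PWGD}{park size over geometric distance (`geometric_m`).}
#'   \item{PWRD}{park size over route distance (`route_m`).}
#'   \item{PWRD_Attr}{adds attractiveness to PWRD.}
#'   \item{PWRT_Attr}{attractiveness and size over route travel time
#'     (`route_s`).}
#' }
#'
#' @param name One of `"PWGD"`, `"PWRD"`, `"PWRD_Attr"`, `"PWRT_Attr"`.
#' @return A `model_variant` with fields `name`, `proximity_metric`,
#'   `use_attractiveness`.
#' @export
model_variant <- function(name = c("PWGD", "PWRD", "PWRD_Attr", "PWRT_Attr")) {
  name <- match.arg(name)
  spec <- switch(name,
    PWGD      = list(metric = "geometric_m", attr = FALSE),
    PWRD      = list(metric = "route_m",     attr = FALSE),
    PWRD_Attr = list(metric = "route_m",     attr = TRUE),
    PWRT_Attr = list(metric = "route_s",     attr = TRUE)
  )
  structure(list(name = name, proximity_metric = spec$metric,
                 use_attractiveness = spec$attr),
            class = "model_variant")
}

#' Resident-park interaction score
#'
#' Gravity-model score `A = attr^lambda * S^alpha / p^beta` (the
#' attractiveness term is dropped for variants that ignore it). Strictly
#' decreasing in proximity, increasing in park size and attractiveness.
#'
#' @param S Park area in square meters, > 0. Vectorized.
#' @param p Proximity (meters or seconds), > 0.
#' @param attr Attractiveness score, > 0 when the variant uses it.
#' @param params A [decay_params()].
#' @param variant A [model_variant()] (controls whether `attr` enters).
#' @return Numeric score(s), finite and positive.
#' @examples
#' interaction_score(10000, 500, 50, decay_params(), model_variant("PWRD_Attr"))
#' @export
interaction_score <- function(S, p, attr = 1, params = decay_params(),
                              variant = model_variant("PWRD_Attr")) {
  stopifnot(inherits(params, "decay_params"), inherits(variant, "model_variant"))
  if (any(!is.finite(S)) || any(S <= 0)) stop("park size S must be positive and finite", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0)) stop("proximity p must be positive and finite", call. = FALSE)
  if (variant$use_attractiveness) {
    if (any(!is.finite(attr)) || any(attr <= 0)) {
      stop("attractiveness must be positive and finite when the variant uses it",
           call. = FALSE)
    }
    attr^params$lambda * S^params$alpha / p^params$beta
  } else {
    S^params$alpha / p^params$beta
  }
}

#' Interaction score matrix over blocks x parks
#'
#' Elementwise application of [interaction_score()] to a proximity matrix.
#' Proximities are floored (default 10 m / 10 s) before exponentiation so a
#' block centroid lying inside a park cannot produce an unbounded score, and
#' zero attractiveness is floored (default 0.1) so a featureless park is not
#' silently removed from every choice set. Unreachable pairs stay `NA` and
#' are excluded from choice sets downstream.
#'
#' @param parks Data frame with `id`, `area_m2`, and (for attractiveness
#'   variants) `ai`, aligned by id with the matrix destinations.
#' @param matrix A [proximity_matrix()] whose metric matches the variant.
#' @param params A [decay_params()].
#' @param variant A [model_variant()].
#' @param proximity_floor Floor applied to proximities before `p^beta`.
#' @param ai_floor Floor applied to attractiveness scores.
#' @return Numeric matrix of scores, `NA` where unreachable.
#' @export
interaction_matrix <- function(parks, matrix, params = decay_params(),
                               variant = model_variant("PWRD_Attr"),
                               proximity_floor = 10, ai_floor = 0.1) {
  stopifnot(inherits(matrix, "proximity_matrix"))
  if (matrix$metric != variant$proximity_metric) {
    stop(sprintf("proximity matrix metric '%s' does not match variant '%s' metric '%s'",
                 matrix$metric, variant$name, variant$proximity_metric),
         call. = FALSE)
  }
  idx <- match(matrix$dest_ids, as.character(parks$id))
  if (anyNA(idx)) {
    stop("parks table is missing destination id(s): ",
         paste(matrix$dest_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  S <- parks$area_m2[idx]
  if (any(!is.finite(S)) || any(S <= 0)) stop("park areas must be positive", call. = FALSE)
  p <- pmax(matrix$values, proximity_floor)
  if (variant$use_attractiveness) {
    if (is.null(parks$ai)) stop("variant uses attractiveness but parks have no 'ai' column", call. = FALSE)
    a <- pmax(parks$ai[idx], ai_floor)
    sweep(p^(-params$beta), 2, a^params$lambda * S^params$alpha, `*`)
  } else {
    sweep(p^(-params$beta), 2, S^params$alpha, `*`)
  }
}
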