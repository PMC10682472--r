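#' Park attribute categories
#'
#' The ten binary park attributes grouped into three categories:
#' sports and recreation (activity spaces, children's playground), nature
#' (water features, wildlife and gardens, trees, walking path), and general
#' amenities (public art, public toilets, car parking, barbeque facilities).
#'
#' @format Named list of character vectors (category -> attribute names).
#' @export
park_attribute_categories <- list(
  sports_recreation = c("activity_spaces", "children_playground"),
  nature            = c("water_features", "wildlife_gardens", "trees", "walking_path"),
  general_amenities = c("public_art", "public_toilets", "car_parking", "barbeque")
)

#' All ten park attribute names
#' @export
park_attribute_names <- unlist(park_attribute_categories, use.names = FALSE)

#' Attribute weighting scheme
#'
#' Category-level weights for the attractiveness index. The default weights
#' (sports and recreation 13.3, nature 66.0, general amenities 20.7) come
#' from an expert-panel audit of which park attributes drive participation
#' in physical activity. Each category weight is divided equally among the
#' attributes inside that category.
#'
#' @param sports_recreation,nature,general_amenities Positive category weights.
#' @return A `weight_scheme` object.
#' @export
weight_scheme <- function(sports_recreation = 13.3, nature = 66.0,
                          general_amenities = 20.7) {
  w <- c(sports_recreation = sports_recreation, nature = nature,
         general_amenities = general_amenities)
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("category weights must be positive and finite", call. = FALSE)
  }
  structure(list(category_weights = w), class = "weight_scheme")
}

#' Per-attribute weights under the equal-division rule
#'
#' @param scheme A [weight_scheme()].
#' @return Named numeric vector over the ten attributes; the weights sum to
#'   the sum of the category weights.
#' @examples
#' attribute_weights(weight_scheme())["water_features"]  # 66.0 / 4
#' @export
attribute_weights <- function(scheme = weight_scheme()) {
  stopifnot(inherits(scheme, "weight_scheme"))
  out <- unlist(lapply(names(park_attribute_categories), function(cat) {
    members <- park_attribute_categories[[cat]]
    if (length(members) == 0) stop("empty attribute category: ", cat, call. = FALSE)
    stats::setNames(rep(scheme$category_weights[[cat]] / length(members),
                        length(members)), members)
  }))
  out[park_attribute_names]
}

#' Attractiveness Index of a park
#'
#' Weighted sum of the ten binary attribute indicators:
#' `AI = sum_j BI_j * w_j`, where `BI_j` is 0/1 presence of attribute j and
#' `w_j` its weight under `scheme`. A park with every attribute present
#' scores the sum of the category weights (100 under the defaults).
#'
#' @param attrs Named logical/0-1 vector over the ten attribute names, or a
#'   data frame with one column per attribute (one row per park).
#' @param scheme A [weight_scheme()].
#' @return Numeric AI score(s).
#' @examples
#' a <- setNames(rep(0, 10), park_attribute_names)
#' a[park_attribute_categories$nature] <- 1
#' compute_ai(a)  # 66.0
#' @export
compute_ai <- function(attrs, scheme = weight_scheme()) {
  w <- attribute_weights(scheme)
  if (is.data.frame(attrs)) {
    flags <- as.matrix(attrs[, park_attribute_names, drop = FALSE])
  } else {
    missing <- setdiff(park_attribute_names, names(attrs))
    if (length(missing)) {
      stop("attrs missing attribute(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    flags <- matrix(as.numeric(attrs[park_attribute_names]), nrow = 1)
  }
  storage.mode(flags) <- "double"
  if (any(!flags %in% c(0, 1))) {
    stop("attribute flags must be strictly binary (0/1)", call. = FALSE)
  }
  as.numeric(flags %*% w)
}

#' Add an `ai` column to a park table
#'
#' @param parks Data frame with the ten 0/1 attribute columns.
#' @param scheme A [weight_scheme()].
#' @return `parks` with an `ai` column appended (replaced if present).
#' @export
add_ai <- function(parks, scheme = weight_scheme()) {
  parks$ai <- compute_ai(parks, scheme)
  parks
}

#' Binarize a mean NDVI value into the "trees" attribute flag
#'
#' NDVI (normalized difference vegetation index) serves as a proxy for the
#' quantity of greenery inside a park; the flag is set when the park's mean
#' NDVI reaches the threshold (inclusive). The default threshold of 0.2 is a
#' common vegetated-pixel cutoff.
#'
#' @param ndvi_mean Mean NDVI in \[-1, 1\].
#' @param threshold Cutoff; values at or above it map to `TRUE`.
#' @return Logical vector.
#' @export
ndvi_to_trees_flag <- function(ndvi_mean, threshold = 0.2) {
  if (any(!is.finite(ndvi_mean)) || any(ndvi_mean < -1 | ndvi_mean > 1)) {
    stop("ndvi_mean must lie in [-1, 1]", call. = FALSE)
  }
  ndvi_mean >= threshold
}
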