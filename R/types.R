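#' Demand points
#'
#' Validates and classes a table of demand points: population-weighted town
#' centroids carrying the count of residents aged 65 and over. Coordinates
#' are planar (projected, km); the package consumes precomputed route
#' distances and never derives geodesics.
#'
#' @param x A data frame with columns `id`, `region_id`, `county_id`,
#'   `population`, `x_km`, `y_km`.
#' @return A tibble of class `fca_demand`.
#' @export
demand_points <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("id", "region_id", "county_id", "population", "x_km", "y_km")
  check_columns(x, need, "demand")
  x$id <- as.character(x$id)
  x$region_id <- as.character(x$region_id)
  x$county_id <- as.character(x$county_id)
  bad <- which(is.na(x$population) | x$population < 0)
  if (length(bad)) {
    stop(row_msg("demand: population must be a non-negative count", bad),
         call. = FALSE)
  }
  dup <- which(duplicated(x$id))
  if (length(dup)) {
    stop(row_msg("demand: duplicate id", dup), call. = FALSE)
  }
  class(x) <- c("fca_demand", class(x))
  x
}

#' Facilities
#'
#' Validates and classes a table of service points, each with a positive
#' capacity (provider head count) and a consumer rating on the 1-5 scale
#' used by online platforms such as Google.
#'
#' @param x A data frame with columns `id`, `region_id`, `county_id`,
#'   `capacity`, `rating`, `x_km`, `y_km`.
#' @return A tibble of class `fca_facilities`.
#' @export
facilities <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("id", "region_id", "county_id", "capacity", "rating", "x_km", "y_km")
  check_columns(x, need, "facilities")
  x$id <- as.character(x$id)
  x$region_id <- as.character(x$region_id)
  x$county_id <- as.character(x$county_id)
  bad <- which(is.na(x$capacity) | x$capacity <= 0)
  if (length(bad)) {
    stop(row_msg("facilities: capacity must be positive", bad), call. = FALSE)
  }
  bad <- which(is.na(x$rating) | x$rating < 1 | x$rating > 5)
  if (length(bad)) {
    stop(row_msg("facilities: rating must lie in [1, 5]", bad), call. = FALSE)
  }
  dup <- which(duplicated(x$id))
  if (length(dup)) {
    stop(row_msg("facilities: duplicate id", dup), call. = FALSE)
  }
  class(x) <- c("fca_facilities", class(x))
  x
}

#' Travel costs
#'
#' A sparse long-format table of demand-to-facility route distances in km.
#' A pair absent from the table is unreachable (effectively infinite
#' distance); this makes sparse matrices valid input. The same table serves
#' both directions, demand to facility and facility to demand.
#'
#' @param x A data frame with columns `demand_id`, `facility_id`,
#'   `distance_km`.
#' @param demand_ids,facility_ids Optional id universes (so that a demand
#'   point with no reachable facility is still a known id). Default to the
#'   ids present in `x`.
#' @return A tibble of class `fca_costs` with the id universes attached as
#'   attributes.
#' @export
travel_costs <- function(x, demand_ids = NULL, facility_ids = NULL) {
  x <- tibble::as_tibble(x)
  check_columns(x, c("demand_id", "facility_id", "distance_km"), "distances")
  x$demand_id <- as.character(x$demand_id)
  x$facility_id <- as.character(x$facility_id)
  bad <- which(is.na(x$distance_km) | x$distance_km < 0)
  if (length(bad)) {
    stop(row_msg("distances: distance_km must be non-negative", bad),
         call. = FALSE)
  }
  dup <- which(duplicated(x[c("demand_id", "facility_id")]))
  if (length(dup)) {
    stop(row_msg("distances: duplicate (demand_id, facility_id) pair", dup),
         call. = FALSE)
  }
  demand_ids <- as.character(demand_ids %||% unique(x$demand_id))
  facility_ids <- as.character(facility_ids %||% unique(x$facility_id))
  unknown <- setdiff(x$demand_id, demand_ids)
  if (length(unknown)) {
    stop("distances reference demand ids outside the given universe: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(x$facility_id, facility_ids)
  if (length(unknown)) {
    stop("distances reference facility ids outside the given universe: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  attr(x, "demand_ids") <- demand_ids
  attr(x, "facility_ids") <- facility_ids
  class(x) <- c("fca_costs", class(x))
  x
}

check_columns <- function(x, need, what) {
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

row_msg <- function(msg, rows) {
  sprintf("%s (row%s %s)", msg, if (length(rows) > 1) "s" else "",
          paste(utils::head(rows, 10), collapse = ", "))
}
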