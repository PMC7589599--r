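#' @importFrom rlang .data
NULL

ACCESS_METHODS <- c("A0", "A1", "A2", "A3", "A4")

method_mode <- function(method) {
  switch(method,
    A1 = "none",
    A2 = "capacity",
    A3 = "rating",
    A4 = "capacity_rating",
    stop(sprintf("unknown method '%s' (expected A1, A2, A3 or A4)", method),
         call. = FALSE)
  )
}

# Dense decay matrix (demand x facility) from the sparse cost table.
# An entry is the kernel value f(d); pairs absent from the table, or past
# the outermost band edge, are 0 -- equivalently, out of catchment.
decay_matrix <- function(demand, facilities, costs, params = decay_params()) {
  stopifnot(inherits(demand, "fca_demand"), inherits(facilities, "fca_facilities"),
            inherits(costs, "fca_costs"))
  d_ids <- demand$id
  f_ids <- facilities$id
  F <- matrix(0, nrow = length(d_ids), ncol = length(f_ids),
              dimnames = list(d_ids, f_ids))
  ri <- match(costs$demand_id, d_ids)
  ci <- match(costs$facility_id, f_ids)
  keep <- !is.na(ri) & !is.na(ci)
  if (any(keep)) {
    F[cbind(ri[keep], ci[keep])] <- distance_decay(costs$distance_km[keep], params)
  }
  F
}

#' Facility selection weights (choice probabilities)
#'
#' For each demand point, splits its demand across the facilities inside its
#' catchment in proportion to `m_j * f(d_ij)`, where the multiplier `m_j` is
#' the facility capacity (`mode = "capacity"`), its rating
#' (`mode = "rating"`), or their product (`mode = "capacity_rating"`). The
#' weights over a non-empty catchment sum to 1 and are interpreted as the
#' probability that the demand point uses each facility. Facilities outside
#' the catchment get weight 0; a demand point with an empty catchment has an
#' all-zero row.
#'
#' @param demand A [demand_points()] table.
#' @param facilities A [facilities()] table.
#' @param costs A [travel_costs()] table.
#' @param params A [decay_params()] object.
#' @param mode One of `"capacity"`, `"rating"`, `"capacity_rating"`.
#' @return A numeric matrix (demand x facility, dimnames are the ids) of
#'   class `fca_weights` with the mode attached as an attribute.
#' @export
selection_weights <- function(demand, facilities, costs,
                              params = decay_params(),
                              mode = c("capacity", "rating", "capacity_rating")) {
  mode <- match.arg(mode)
  F <- decay_matrix(demand, facilities, costs, params)
  W <- weight_matrix(F, facilities, mode)
  structure(W, mode = mode, class = c("fca_weights", class(W)))
}

weight_matrix <- function(F, facilities, mode) {
  if (mode == "none") {
    W <- (F > 0) * 1
  } else {
    m <- switch(mode,
      capacity = facilities$capacity,
      rating = facilities$rating,
      capacity_rating = facilities$capacity * facilities$rating
    )
    W <- sweep(F, 2, m, `*`)
    rs <- rowSums(W)
    pos <- rs > 0
    W[pos, ] <- W[pos, , drop = FALSE] / rs[pos]
    W[!pos, ] <- 0
  }
  W
}

#' Facility service ratios (step one of the floating catchment methods)
#'
#' Computes each facility's supply-to-weighted-demand ratio
#' `R_j = S_j / sum_k w_kj * P_k * f(d_kj)`, where the sum runs over demand
#' points within the outermost band edge of the facility and `w_kj` is the
#' demand point's selection weight for the facility (1 when `weights` is
#' `NULL`, the unweighted two-step variant). Facilities whose weighted
#' reachable demand is zero have an undefined ratio: they are returned with
#' `ratio = NA`, `flagged = TRUE`, and a warning, and are excluded from the
#' scoring step.
#'
#' @inheritParams selection_weights
#' @param weights An [selection_weights()] matrix, or `NULL` for the
#'   unweighted variant.
#' @return A tibble with columns `facility_id`, `ratio`, `flagged`.
#' @export
facility_service_ratio <- function(demand, facilities, costs,
                                   params = decay_params(), weights = NULL) {
  F <- decay_matrix(demand, facilities, costs, params)
  W <- if (is.null(weights)) (F > 0) * 1 else unclass(weights)
  stopifnot(identical(dim(W), dim(F)))
  ratios <- service_ratios(F, W, demand$population, facilities$capacity)
  flagged <- is.na(ratios)
  if (any(flagged)) {
    warning(sprintf(
      "%d facilit%s with zero reachable (weighted) demand excluded from scoring: %s",
      sum(flagged), if (sum(flagged) > 1) "ies" else "y",
      paste(utils::head(facilities$id[flagged], 5), collapse = ", ")
    ), call. = FALSE)
  }
  tibble::tibble(facility_id = facilities$id, ratio = ratios, flagged = flagged)
}

service_ratios <- function(F, W, population, capacity) {
  load <- unname(colSums(W * F * population))
  ifelse(load > 0, capacity / load, NA_real_)
}

new_access_result <- function(demand, score, method, scale_factor) {
  out <- tibble::tibble(
    id = demand$id,
    region_id = demand$region_id,
    county_id = demand$county_id,
    population = demand$population,
    score = score
  )
  attr(out, "method") <- method
  attr(out, "scale_factor") <- scale_factor
  class(out) <- c("fca_access", class(out))
  out
}

#' Regional average accessibility (method A0)
#'
#' Capacity per capita within each administrative region, ignoring distance
#' and any cross-region use of facilities: for region `i`,
#' `A_i = scale * sum(S_j over facilities in region i) / P_i`. Every demand
#' point inherits its region's score. Facilities whose `region_id` matches no
#' demand region are orphans: they contribute to no score and are reported
#' with a warning. A region with zero population but facilities present has
#' an undefined ratio; its score is set to 0 with a warning.
#'
#' @inheritParams selection_weights
#' @param scale_factor Score scale; the default 10,000 expresses providers
#'   per 10,000 persons.
#' @return A tibble of class `fca_access` with per-demand-point scores and
#'   the method and scale factor as attributes.
#' @export
regional_average <- function(demand, facilities, scale_factor = 10000) {
  stopifnot(inherits(demand, "fca_demand"), inherits(facilities, "fca_facilities"))
  orphans <- setdiff(facilities$region_id, demand$region_id)
  if (length(orphans)) {
    warning(sprintf(
      "%d facility region(s) match no demand region and are ignored: %s",
      length(orphans), paste(utils::head(orphans, 5), collapse = ", ")
    ), call. = FALSE)
  }
  supply <- vapply(
    demand$region_id,
    function(r) sum(facilities$capacity[facilities$region_id == r]),
    numeric(1)
  )
  pop_by_region <- tapply(demand$population, demand$region_id, sum)
  region_pop <- as.numeric(pop_by_region[demand$region_id])
  score <- numeric(nrow(demand))
  ok <- region_pop > 0
  score[ok] <- scale_factor * supply[ok] / region_pop[ok]
  undefined <- !ok & supply > 0
  if (any(undefined)) {
    warning(sprintf(
      "%d region(s) have facilities but zero demand population; score set to 0: %s",
      length(unique(demand$region_id[undefined])),
      paste(utils::head(unique(demand$region_id[undefined]), 5), collapse = ", ")
    ), call. = FALSE)
  }
  new_access_result(demand, score, "A0", scale_factor)
}

#' Floating catchment area accessibility scores (methods A1-A4)
#'
#' Two-step (A1) and three-step (A2-A4) floating catchment area scores.
#' Step one computes each facility's service ratio `R_j` (see
#' [facility_service_ratio()]); step two accumulates the reachable ratios at
#' each demand point: `A_i = scale * sum_j w_ij * R_j * f(d_ij)` over the
#' facilities in the demand point's catchment. The selection weights `w_ij`
#' are 1 for A1 and the choice probabilities of [selection_weights()] for
#' A2 (capacity), A3 (rating) and A4 (capacity x rating); they enter
#' symmetrically on the demand side in step one and the access side in step
#' two, which conserves total supply: `sum_i P_i * A_i / scale` equals the
#' total capacity of facilities with reachable demand. A demand point with
#' an empty catchment scores 0.
#'
#' @param method One of `"A1"`, `"A2"`, `"A3"`, `"A4"`.
#' @inheritParams regional_average
#' @inheritParams selection_weights
#' @return A tibble of class `fca_access` (see [regional_average()]).
#' @export
accessibility_scores <- function(method, demand, facilities, costs,
                                 params = decay_params(), scale_factor = 10000) {
  stopifnot(length(method) == 1L)
  mode <- method_mode(method)
  F <- decay_matrix(demand, facilities, costs, params)
  W <- weight_matrix(F, facilities, mode)
  ratios <- service_ratios(F, W, demand$population, facilities$capacity)
  flagged <- is.na(ratios)
  if (any(flagged)) {
    warning(sprintf(
      "%s: %d facilit%s with zero reachable demand excluded from scoring",
      method, sum(flagged), if (sum(flagged) > 1) "ies" else "y"
    ), call. = FALSE)
  }
  r <- ifelse(flagged, 0, ratios)
  score <- scale_factor * as.numeric((W * F) %*% r)
  new_access_result(demand, score, method, scale_factor)
}

#' Run every accessibility method in one pass
#'
#' Computes A0 (regional average), A1 (two-step FCA) and the three
#' choice-probability variants A2-A4 on one dataset, sharing the decay and
#' catchment computations.
#'
#' @inheritParams accessibility_scores
#' @param methods Subset of `c("A0", ..., "A4")` to run.
#' @return A named list of `fca_access` tibbles, one per method.
#' @export
run_all_methods <- function(demand, facilities, costs,
                            params = decay_params(), scale_factor = 10000,
                            methods = ACCESS_METHODS) {
  stopifnot(all(methods %in% ACCESS_METHODS))
  out <- list()
  if ("A0" %in% methods) {
    out$A0 <- regional_average(demand, facilities, scale_factor)
  }
  fca <- setdiff(methods, "A0")
  if (length(fca)) {
    F <- decay_matrix(demand, facilities, costs, params)
    warned <- FALSE
    for (m in fca) {
      W <- weight_matrix(F, facilities, method_mode(m))
      ratios <- service_ratios(F, W, demand$population, facilities$capacity)
      flagged <- is.na(ratios)
      if (any(flagged) && !warned) {
        warning(sprintf(
          "%d facilit%s with zero reachable demand excluded from scoring",
          sum(flagged), if (sum(flagged) > 1) "ies" else "y"
        ), call. = FALSE)
        warned <- TRUE
      }
      r <- ifelse(flagged, 0, ratios)
      score <- scale_factor * as.numeric((W * F) %*% r)
      out[[m]] <- new_access_result(demand, score, m, scale_factor)
    }
  }
  out[intersect(methods, names(out))]
}
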