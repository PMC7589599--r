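# Independent per-definition oracles, kept free of the package's vectorized
# code paths: plain scalar loops over the printed formulas.

oracle_decay <- function(d) {
  if (is.na(d) || d > 30) return(0)
  if (d <= 3) return(1)
  if (d <= 15) return(3 / d)
  15 / d^2
}

# demand/facility tables + dense distance matrix with NA = unreachable
oracle_dist_matrix <- function(demand, facilities, costs) {
  m <- matrix(NA_real_, nrow(demand), nrow(facilities),
              dimnames = list(demand$id, facilities$id))
  for (r in seq_len(nrow(costs))) {
    m[costs$demand_id[r], costs$facility_id[r]] <- costs$distance_km[r]
  }
  m
}

oracle_scores <- function(demand, facilities, dmat, mode, scale = 10000) {
  nd <- nrow(demand); nf <- nrow(facilities)
  P <- demand$population
  S <- facilities$capacity
  V <- facilities$rating
  Fm <- matrix(0, nd, nf)
  for (i in seq_len(nd)) for (j in seq_len(nf)) Fm[i, j] <- oracle_decay(dmat[i, j])
  m <- switch(mode, none = rep(1, nf), capacity = S, rating = V,
              capacity_rating = S * V)
  W <- matrix(0, nd, nf)
  for (i in seq_len(nd)) {
    den <- 0
    for (j in seq_len(nf)) if (Fm[i, j] > 0) den <- den + m[j] * Fm[i, j]
    for (j in seq_len(nf)) {
      if (Fm[i, j] > 0) {
        W[i, j] <- if (mode == "none") 1 else m[j] * Fm[i, j] / den
      }
    }
  }
  R <- numeric(nf)
  for (j in seq_len(nf)) {
    den <- 0
    for (i in seq_len(nd)) den <- den + W[i, j] * P[i] * Fm[i, j]
    R[j] <- if (den > 0) S[j] / den else 0
  }
  A <- numeric(nd)
  for (i in seq_len(nd)) {
    for (j in seq_len(nf)) A[i] <- A[i] + W[i, j] * R[j] * Fm[i, j]
  }
  scale * A
}

# population-weighted Gini by the mean-absolute-difference formula
oracle_gini_mad <- function(scores, populations) {
  p <- populations / sum(populations)
  abar <- sum(p * scores)
  if (abar == 0) return(0)
  g <- 0
  for (i in seq_along(scores)) {
    for (j in seq_along(scores)) {
      g <- g + p[i] * p[j] * abs(scores[i] - scores[j])
    }
  }
  g / (2 * abar)
}

# small random instance: uniform points in a box wide enough that some
# pairs fall outside the 30-km radius; a few pairs dropped (unreachable)
random_instance <- function(seed, n_demand = 12, n_facility = 6,
                            box_km = 60, drop_frac = 0.1) {
  withr::with_seed(seed, {
    demand <- demand_points(tibble::tibble(
      id = sprintf("d%02d", seq_len(n_demand)),
      region_id = sprintf("r%02d", seq_len(n_demand)),
      county_id = sprintf("c%d", 1 + (seq_len(n_demand) %% 3)),
      population = stats::rpois(n_demand, 800) + 1,
      x_km = stats::runif(n_demand, 0, box_km),
      y_km = stats::runif(n_demand, 0, box_km)
    ))
    fac <- facilities(tibble::tibble(
      id = sprintf("f%02d", seq_len(n_facility)),
      region_id = sample(demand$region_id, n_facility, replace = TRUE),
      county_id = sample(demand$county_id, n_facility, replace = TRUE),
      capacity = sample(1:5, n_facility, replace = TRUE),
      rating = round(stats::runif(n_facility, 1, 5), 1),
      x_km = stats::runif(n_facility, 0, box_km),
      y_km = stats::runif(n_facility, 0, box_km)
    ))
    d <- sqrt(outer(demand$x_km, fac$x_km, `-`)^2 +
                outer(demand$y_km, fac$y_km, `-`)^2) * 1.2
    long <- expand.grid(i = seq_len(n_demand), j = seq_len(n_facility))
    keep <- stats::runif(nrow(long)) > drop_frac
    long <- long[keep, ]
    costs <- travel_costs(
      tibble::tibble(
        demand_id = demand$id[long$i],
        facility_id = fac$id[long$j],
        distance_km = d[cbind(long$i, long$j)]
      ),
      demand_ids = demand$id, facility_ids = fac$id
    )
    list(demand = demand, facilities = fac, costs = costs)
  })
}

# compact landscape used by the randomized property suites
small_landscape_config <- function(seed) {
  landscape_config(
    n_counties = 5, towns_per_county = c(8, 12), n_urban_centers = 2,
    n_facilities = 20, extent_km = c(100, 100), random_seed = seed
  )
}

MODES <- c("capacity", "rating", "capacity_rating")
FCA_METHODS <- c("A1", "A2", "A3", "A4")
method_to_mode <- c(A1 = "none", A2 = "capacity", A3 = "rating",
                    A4 = "capacity_rating")
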