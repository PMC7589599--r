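#' Configuration for the synthetic landscape generator
#'
#' Default values emulate the national aggregates of the motivating setting:
#' 19 counties holding about 349 towns on a roughly 150 x 400 km island,
#' about 658 facilities whose integer capacities sum to roughly 1,140
#' providers, ratings with mean 3.72 and SD 0.66 clipped to \[1, 5\], and
#' route distances exceeding straight-line distances by a scalar detour
#' factor. These are calibration targets for the generator, not
#' reproductions of any real geography.
#'
#' @param n_counties Number of counties.
#' @param towns_per_county Integer range (min, max); each county draws its
#'   town count uniformly from it.
#' @param n_urban_centers Number of urban cluster centers (counties whose
#'   towns are packed tightly and around which facilities concentrate).
#' @param n_facilities Number of facilities to place.
#' @param population_lognormal Named or ordered pair (meanlog, sdlog) of the
#'   base town elderly-population log-normal. Towns in urban counties get a
#'   4x multiplier, concentrating about two thirds of demand in metros; the
#'   defaults give a mean town population of about 10,400, i.e. about 3.6
#'   million elderly over 349 towns.
#' @param facility_intensity_exponent Exponent gamma of the facility
#'   placement intensity: a facility anchors to town t with probability
#'   proportional to (local population density at t)^gamma. gamma = 0 places
#'   facilities uniformly across towns; larger values concentrate supply in
#'   metros.
#' @param capacity_mean Mean providers per facility; capacities are drawn as
#'   1 + Poisson(capacity_mean - 1), so they are integers >= 1.
#' @param rating_mean,rating_sd Normal parameters of the facility rating
#'   before clipping.
#' @param rating_clip Clip bounds for ratings, within \[1, 5\].
#' @param detour_factor Route distance = Euclidean distance x this factor
#'   (>= 1), mimicking road networks.
#' @param extent_km Width and height of the rectangular study area.
#' @param max_store_km Distance cap for stored cost entries; longer pairs
#'   are left absent (unreachable). Must exceed the outermost decay edge.
#' @param random_seed Seed for the fixed generator algorithm
#'   (Mersenne-Twister), making output byte-identical across runs and
#'   platforms.
#' @return A validated list of class `fca_landscape_config`.
#' @export
landscape_config <- function(n_counties = 19,
                             towns_per_county = c(10, 27),
                             n_urban_centers = 6,
                             n_facilities = 658,
                             population_lognormal = c(meanlog = 8.08, sdlog = 1.0),
                             facility_intensity_exponent = 1.5,
                             capacity_mean = 1140 / 658,
                             rating_mean = 3.72,
                             rating_sd = 0.66,
                             rating_clip = c(1, 5),
                             detour_factor = 1.3,
                             extent_km = c(150, 400),
                             max_store_km = 45,
                             random_seed = 1L) {
  cfg <- list(
    n_counties = as.integer(n_counties),
    towns_per_county = as.integer(towns_per_county),
    n_urban_centers = as.integer(n_urban_centers),
    n_facilities = as.integer(n_facilities),
    population_lognormal = as.numeric(population_lognormal),
    facility_intensity_exponent = as.numeric(facility_intensity_exponent),
    capacity_mean = as.numeric(capacity_mean),
    rating_mean = as.numeric(rating_mean),
    rating_sd = as.numeric(rating_sd),
    rating_clip = as.numeric(rating_clip),
    detour_factor = as.numeric(detour_factor),
    extent_km = as.numeric(extent_km),
    max_store_km = as.numeric(max_store_km),
    random_seed = as.integer(random_seed)
  )
  with(cfg, {
    if (n_counties < 1 || n_facilities < 1) {
      stop("counts must be positive", call. = FALSE)
    }
    if (length(towns_per_county) != 2 || any(towns_per_county < 1) ||
        towns_per_county[1] > towns_per_county[2]) {
      stop("`towns_per_county` must be an increasing positive range", call. = FALSE)
    }
    if (n_urban_centers < 1 || n_urban_centers > n_counties) {
      stop("`n_urban_centers` must lie in [1, n_counties]", call. = FALSE)
    }
    if (capacity_mean < 1) stop("`capacity_mean` must be >= 1", call. = FALSE)
    if (rating_sd < 0) stop("`rating_sd` must be >= 0", call. = FALSE)
    if (rating_clip[1] < 1 || rating_clip[2] > 5 || rating_clip[1] >= rating_clip[2]) {
      stop("`rating_clip` must be an increasing range within [1, 5]", call. = FALSE)
    }
    if (detour_factor < 1) stop("`detour_factor` must be >= 1", call. = FALSE)
    if (facility_intensity_exponent < 0) {
      stop("`facility_intensity_exponent` must be >= 0", call. = FALSE)
    }
    if (any(extent_km <= 0)) stop("`extent_km` must be positive", call. = FALSE)
  })
  structure(cfg, class = "fca_landscape_config")
}

#' Generate a synthetic demand/facility landscape
#'
#' Draws a reproducible synthetic study area: county seed points on a
#' rectangle, the first `n_urban_centers` of them acting as urban cluster
#' centers; town centroids scattered around their county seed (tighter
#' around urban centers); log-normal town populations; facilities anchored
#' to towns with probability proportional to the local population
#' density raised to `facility_intensity_exponent`, so supply clusters in
#' metros; integer capacities and clipped-normal ratings; and route
#' distances equal to Euclidean distances times the detour factor, stored
#' sparsely up to `max_store_km`.
#'
#' @param config A [landscape_config()].
#' @return A list with elements `demand` ([demand_points()]),
#'   `facilities` ([facilities()]) and `costs` ([travel_costs()]).
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "fca_landscape_config"))
  withr::with_seed(
    config$random_seed,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection",
    generate_landscape_impl(config)
  )
}

generate_landscape_impl <- function(cfg) {
  W <- cfg$extent_km[1]
  H <- cfg$extent_km[2]
  seeds_x <- stats::runif(cfg$n_counties, 0.1 * W, 0.9 * W)
  seeds_y <- stats::runif(cfg$n_counties, 0.05 * H, 0.95 * H)
  urban <- seq_len(cfg$n_urban_centers)

  n_towns <- sample(seq(cfg$towns_per_county[1], cfg$towns_per_county[2]),
                    cfg$n_counties, replace = TRUE)
  county <- rep(seq_len(cfg$n_counties), n_towns)
  spread <- ifelse(county %in% urban, 6, 18)  # km; urban towns pack tighter
  tx <- stats::rnorm(length(county), seeds_x[county], spread)
  ty <- stats::rnorm(length(county), seeds_y[county], spread)
  pop <- stats::rlnorm(length(county), cfg$population_lognormal[1],
                       cfg$population_lognormal[2])
  # urban towns are more populous; the 4x factor puts ~2/3 of demand in
  # metros while the base meanlog keeps the national total near 3.6M
  pop <- round(pop * ifelse(county %in% urban, 4, 1))

  town_id <- sprintf("T%03d", seq_along(county))
  demand <- demand_points(tibble::tibble(
    id = town_id,
    region_id = town_id,
    county_id = sprintf("C%02d", county),
    population = pop,
    x_km = tx, y_km = ty
  ))

  # local population density at each town (Gaussian kernel, 10 km bandwidth)
  dd <- as.matrix(stats::dist(cbind(tx, ty)))
  dens <- as.numeric(exp(-dd^2 / (2 * 10^2)) %*% pop)
  wgt <- dens^cfg$facility_intensity_exponent
  if (sum(wgt) <= 0) wgt <- rep(1, length(dens))
  anchor <- sample(seq_along(town_id), cfg$n_facilities, replace = TRUE,
                   prob = wgt / sum(wgt))
  fx <- tx[anchor] + stats::rnorm(cfg$n_facilities, 0, 2)
  fy <- ty[anchor] + stats::rnorm(cfg$n_facilities, 0, 2)
  capacity <- 1 + stats::rpois(cfg$n_facilities, cfg$capacity_mean - 1)
  rating <- pmin(pmax(stats::rnorm(cfg$n_facilities, cfg$rating_mean,
                                   cfg$rating_sd),
                      cfg$rating_clip[1]), cfg$rating_clip[2])
  fac_id <- sprintf("F%03d", seq_len(cfg$n_facilities))
  fac <- facilities(tibble::tibble(
    id = fac_id,
    region_id = town_id[anchor],
    county_id = sprintf("C%02d", county[anchor]),
    capacity = capacity,
    rating = round(rating, 2),
    x_km = fx, y_km = fy
  ))

  eu <- sqrt(outer(tx, fx, `-`)^2 + outer(ty, fy, `-`)^2)
  route <- eu * cfg$detour_factor
  keep <- which(route <= cfg$max_store_km, arr.ind = TRUE)
  costs <- travel_costs(
    tibble::tibble(
      demand_id = town_id[keep[, 1]],
      facility_id = fac_id[keep[, 2]],
      distance_km = route[keep]
    ),
    demand_ids = town_id,
    facility_ids = fac_id
  )
  list(demand = demand, facilities = fac, costs = costs)
}

#' Deterministic worked-example fixtures
#'
#' Two tiny hand-checkable instances. `"tiny"` is a one-facility instance
#' (capacity 2; 1,000 people at 2 km and 3,000 at 6 km) whose two-step FCA
#' scores per 10,000 work out to 8.0 and 4.0 by hand. `"small"` is a
#' three-town/three-facility instance with distances on every decay band,
#' one unreachable pair, distinct capacities and ratings; its expected A1-A4
#' scores (computed by the per-definition double loop and frozen) are
#' attached as `expected`, a tibble of per-town scores by method.
#'
#' @param which `"tiny"` or `"small"`.
#' @return A list with `demand`, `facilities`, `costs` and (for both
#'   fixtures) `expected`.
#' @export
worked_example_fixture <- function(which = c("tiny", "small")) {
  which <- match.arg(which)
  if (which == "tiny") {
    demand <- demand_points(tibble::tibble(
      id = c("i1", "i2"), region_id = c("r1", "r2"),
      county_id = c("c1", "c1"), population = c(1000, 3000),
      x_km = c(0, 6), y_km = c(0, 0)
    ))
    fac <- facilities(tibble::tibble(
      id = "j1", region_id = "r1", county_id = "c1",
      capacity = 2, rating = 4, x_km = 2, y_km = 0
    ))
    costs <- travel_costs(
      tibble::tibble(demand_id = c("i1", "i2"), facility_id = c("j1", "j1"),
                     distance_km = c(2, 6)),
      demand_ids = demand$id, facility_ids = fac$id
    )
    expected <- tibble::tibble(
      id = c("i1", "i2"),
      A1 = c(8, 4), A2 = c(8, 4), A3 = c(8, 4), A4 = c(8, 4)
    )
    return(list(demand = demand, facilities = fac, costs = costs,
                expected = expected))
  }
  demand <- demand_points(tibble::tibble(
    id = c("i1", "i2", "i3"),
    region_id = c("r1", "r2", "r3"),
    county_id = c("c1", "c1", "c2"),
    population = c(1000, 2000, 500),
    x_km = 0, y_km = 0
  ))
  fac <- facilities(tibble::tibble(
    id = c("j1", "j2", "j3"),
    region_id = c("r1", "r2", "r3"),
    county_id = c("c1", "c1", "c2"),
    capacity = c(2, 1, 3),
    rating = c(4, 5, 3),
    x_km = 0, y_km = 0
  ))
  costs <- travel_costs(
    tibble::tibble(
      demand_id = c("i1", "i1", "i1", "i2", "i2", "i2", "i3", "i3"),
      facility_id = c("j1", "j2", "j3", "j1", "j2", "j3", "j2", "j3"),
      distance_km = c(2, 6, 40, 10, 3, 20, 30, 12)
    ),
    demand_ids = demand$id, facility_ids = fac$id
  )
  # frozen from the per-definition double-loop computation (see tests)
  expected <- tibble::tibble(
    id = c("i1", "i2", "i3"),
    A1 = c(14.4933554817276, 13.3617109634552, 37.5664451827243),
    A2 = c(16.6267537880126, 7.26687988300671, 57.678972891948),
    A3 = c(17.9547248761567, 6.19641842575119, 59.3048765446819),
    A4 = c(16.917008429418, 6.93679276239309, 58.4188120915917)
  )
  list(demand = demand, facilities = fac, costs = costs, expected = expected)
}
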