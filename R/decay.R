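#' Distance-decay parameters
#'
#' Defines the piecewise distance-decay kernel used by every catchment-based
#' accessibility method in this package. Travel distances are split into
#' bands by `band_edges` (km); within the first band utilization weight is 1,
#' in the second it falls off as `e1 / d`, in the third as `e2 / d^2`, and
#' beyond the outermost edge it is 0. The coefficients are derived from the
#' edges so that the kernel is continuous at the first edge (`e1 / e1 = 1`);
#' the later breaks are discontinuous, as is standard for banded kernels of
#' this family. The defaults (3, 15, 30 km) correspond to roughly an hour on
#' foot, half an hour by car, and an hour by car for an elderly traveller.
#'
#' @param band_edges Strictly increasing positive distances (km) delimiting
#'   the decay bands. Exactly three edges are supported: the kernel family is
#'   constant / `a/d` / `b/d^2` / zero.
#' @return An object of class `fca_decay` holding the validated edges.
#' @examples
#' p <- decay_params()
#' distance_decay(c(2, 6, 20, 31), p)
#' @export
decay_params <- function(band_edges = c(3, 15, 30)) {
  if (!is.numeric(band_edges) || length(band_edges) != 3L ||
      anyNA(band_edges)) {
    stop("`band_edges` must be three non-missing numeric distances", call. = FALSE)
  }
  if (any(band_edges <= 0) || any(diff(band_edges) <= 0)) {
    stop("`band_edges` must be positive and strictly increasing", call. = FALSE)
  }
  structure(list(band_edges = as.numeric(band_edges)), class = "fca_decay")
}

#' @export
print.fca_decay <- function(x, ...) {
  e <- x$band_edges
  cat(sprintf(
    "Distance-decay kernel: 1 (d <= %g km); %g/d (<= %g km); %g/d^2 (<= %g km); 0 beyond\n",
    e[1], e[1], e[2], e[2], e[3]
  ))
  invisible(x)
}

#' Distance-decay kernel
#'
#' Maps route distance to a utilization weight in \[0, 1\]. Under the default
#' bands: 1 for d <= 3 km, 3/d for 3 < d <= 15, 15/d^2 for 15 < d <= 30, and
#' 0 past 30 km. Band membership is closed on the right (`<=`), so a distance
#' exactly on an edge takes the nearer band's formula. Missing distances
#' (`NA`) are treated as unreachable and get weight 0.
#'
#' @param d Numeric vector of route distances in km; must be non-negative.
#' @param params A [decay_params()] object.
#' @return Numeric vector of weights, same length as `d`.
#' @export
distance_decay <- function(d, params = decay_params()) {
  stopifnot(inherits(params, "fca_decay"))
  if (!is.numeric(d)) stop("`d` must be numeric", call. = FALSE)
  if (any(d < 0, na.rm = TRUE)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  e <- params$band_edges
  w <- numeric(length(d))
  known <- !is.na(d)
  b1 <- known & d <= e[1]
  b2 <- known & d > e[1] & d <= e[2]
  b3 <- known & d > e[2] & d <= e[3]
  w[b1] <- 1
  w[b2] <- e[1] / d[b2]
  w[b3] <- e[2] / d[b3]^2
  w
}

#' Facilities within reach of a demand point
#'
#' Returns the ids of facilities whose stored route distance from the given
#' demand point does not exceed the outermost decay band edge (30 km by
#' default). Pairs absent from the distance table are unreachable and never
#' included.
#'
#' @param demand_id A single demand-point id present in `costs`.
#' @param costs A travel-cost table from [travel_costs()].
#' @param params A [decay_params()] object; its last edge is the radius.
#' @return Character vector of facility ids (possibly empty).
#' @export
catchment <- function(demand_id, costs, params = decay_params()) {
  stopifnot(inherits(costs, "fca_costs"))
  if (length(demand_id) != 1L) {
    stop("`demand_id` must be a single id", call. = FALSE)
  }
  demand_id <- as.character(demand_id)
  if (!demand_id %in% attr(costs, "demand_ids")) {
    stop(sprintf("unknown demand id '%s'", demand_id), call. = FALSE)
  }
  radius <- params$band_edges[length(params$band_edges)]
  hit <- costs$demand_id == demand_id & costs$distance_km <= radius
  unique(costs$facility_id[hit])
}
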