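#' Read and write the package's delimited tables
#'
#' CSV dialect: UTF-8, comma-delimited, mandatory header, decimal point.
#' Schemas: demand `id,region_id,county_id,population,x_km,y_km`; facilities
#' `id,region_id,county_id,capacity,rating,x_km,y_km`; distances (sparse
#' long format) `demand_id,facility_id,distance_km` — a missing pair is
#' unreachable. Validation failures name the offending rows.
#'
#' @param path File path.
#' @return The corresponding validated object ([demand_points()],
#'   [facilities()], [travel_costs()]).
#' @name fca_io
NULL

read_table_quiet <- function(path, col_types) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  readr::read_csv(path, col_types = col_types, comment = "#", progress = FALSE)
}

#' @rdname fca_io
#' @export
read_demand <- function(path) {
  demand_points(read_table_quiet(path, readr::cols(
    id = readr::col_character(), region_id = readr::col_character(),
    county_id = readr::col_character(), population = readr::col_double(),
    x_km = readr::col_double(), y_km = readr::col_double()
  )))
}

#' @rdname fca_io
#' @export
read_facilities <- function(path) {
  facilities(read_table_quiet(path, readr::cols(
    id = readr::col_character(), region_id = readr::col_character(),
    county_id = readr::col_character(), capacity = readr::col_double(),
    rating = readr::col_double(),
    x_km = readr::col_double(), y_km = readr::col_double()
  )))
}

#' @rdname fca_io
#' @param demand_ids,facility_ids Optional id universes, see [travel_costs()].
#' @export
read_distances <- function(path, demand_ids = NULL, facility_ids = NULL) {
  travel_costs(read_table_quiet(path, readr::cols(
    demand_id = readr::col_character(), facility_id = readr::col_character(),
    distance_km = readr::col_double()
  )), demand_ids = demand_ids, facility_ids = facility_ids)
}

#' @rdname fca_io
#' @param x Object to write.
#' @export
write_demand <- function(x, path) {
  stopifnot(inherits(x, "fca_demand"))
  readr::write_csv(tibble::as_tibble(unclass_first(x)), path)
  invisible(path)
}

#' @rdname fca_io
#' @export
write_facilities <- function(x, path) {
  stopifnot(inherits(x, "fca_facilities"))
  readr::write_csv(tibble::as_tibble(unclass_first(x)), path)
  invisible(path)
}

#' @rdname fca_io
#' @export
write_distances <- function(x, path) {
  stopifnot(inherits(x, "fca_costs"))
  readr::write_csv(tibble::as_tibble(unclass_first(x)), path)
  invisible(path)
}

unclass_first <- function(x) {
  class(x) <- setdiff(class(x), c("fca_demand", "fca_facilities", "fca_costs",
                                  "fca_access"))
  x
}

#' Write an accessibility result
#'
#' Writes per-demand-point scores as CSV with a header comment carrying the
#' method label and scale factor, so result files are self-describing and
#' re-readable by [read_scores()].
#'
#' @param x An `fca_access` result.
#' @param path Output file.
#' @export
write_scores <- function(x, path) {
  stopifnot(inherits(x, "fca_access"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# method: %s", attr(x, "method")), con)
  writeLines(sprintf("# scale_factor: %s", format(attr(x, "scale_factor"))), con)
  utils::write.csv(as.data.frame(unclass_first(x)), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an accessibility result written by [write_scores()]
#'
#' @param path File path.
#' @return An `fca_access` tibble with `method` and `scale_factor`
#'   attributes restored from the header comments.
#' @export
read_scores <- function(path) {
  hdr <- readLines(path, n = 2)
  method <- sub("^# method: ", "", hdr[1])
  scale_factor <- as.numeric(sub("^# scale_factor: ", "", hdr[2]))
  x <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    id = readr::col_character(), region_id = readr::col_character(),
    county_id = readr::col_character(), population = readr::col_double(),
    score = readr::col_double()
  ), progress = FALSE)
  attr(x, "method") <- method
  attr(x, "scale_factor") <- scale_factor
  class(x) <- c("fca_access", class(x))
  x
}

#' Write points as a GeoJSON FeatureCollection
#'
#' Emits Point features in the planar (km) coordinates of the input table;
#' any columns besides `x_km`/`y_km` become feature properties (e.g. scores
#' and quintile colors). Write-side support only.
#'
#' @param x A data frame with `x_km` and `y_km` columns.
#' @param path Output file.
#' @export
write_geojson <- function(x, path) {
  x <- tibble::as_tibble(unclass_first(x))
  stopifnot(all(c("x_km", "y_km") %in% names(x)))
  props <- setdiff(names(x), c("x_km", "y_km"))
  features <- lapply(seq_len(nrow(x)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(x$x_km[i], x$y_km[i])),
      properties = as.list(x[i, props, drop = FALSE])
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
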