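#' Lorenz curve of accessibility against population
#'
#' Builds the cumulative-share curve underlying the Gini coefficient. Units
#' are sorted ascending by score (ties broken by id so curves are
#' reproducible); the x axis accumulates population shares and the y axis
#' accumulates shares of the resource volume `score * population` — the
#' income-Gini analogy, with the accessibility score playing per-capita
#' income. `weighted = FALSE` gives the unweighted variant: every unit gets
#' equal x weight and y accumulates the raw scores, useful as a sensitivity
#' check.
#'
#' @param scores Numeric vector of non-negative accessibility scores.
#' @param populations Numeric vector of unit populations (same length).
#' @param ids Optional unit ids used only to break score ties; defaults to
#'   input order.
#' @param weighted Population-weighted curve (default) or unweighted.
#' @return A tibble with columns `x`, `y`, starting at (0, 0). When the
#'   total resource volume is zero the curve is degenerate (`y` is 0
#'   throughout).
#' @export
lorenz_points <- function(scores, populations, ids = seq_along(scores),
                          weighted = TRUE) {
  n <- length(scores)
  stopifnot(n >= 1, length(populations) == n, length(ids) == n)
  if (any(scores < 0, na.rm = TRUE) || anyNA(scores)) {
    stop("scores must be non-negative and non-missing", call. = FALSE)
  }
  if (!weighted) populations <- rep(1, n)
  if (sum(populations) <= 0) {
    stop("total population must be positive", call. = FALSE)
  }
  ord <- order(scores, as.character(ids))
  p <- populations[ord]
  v <- scores[ord] * p
  x <- cumsum(p) / sum(p)
  y <- if (sum(v) > 0) cumsum(v) / sum(v) else rep(0, n)
  tibble::tibble(x = c(0, x), y = c(0, y))
}

#' Gini coefficient of accessibility
#'
#' Twice the area between the equality diagonal and the Lorenz curve of
#' [lorenz_points()], with the area evaluated by the trapezoidal rule over
#' the curve's vertices and the result clipped to \[0, 1\]. 0 is complete
#' equality (every unit has the same score); values approach 1 as the entire
#' resource concentrates in a vanishing share of the population. When the
#' total resource volume is zero the coefficient is defined as 0.
#'
#' @inheritParams lorenz_points
#' @return A single number in \[0, 1\].
#' @export
gini <- function(scores, populations, ids = seq_along(scores), weighted = TRUE) {
  lp <- lorenz_points(scores, populations, ids, weighted)
  if (all(lp$y == 0)) return(0)
  area <- sum(diff(lp$x) * (utils::head(lp$y, -1) + utils::tail(lp$y, -1)) / 2)
  min(max(1 - 2 * area, 0), 1)
}

GINI_LEVELS <- c("highly_equitable", "equitable", "bearable",
                 "median_inequality", "high_inequality")

#' Five-level equity category for a Gini coefficient
#'
#' Maps a Gini coefficient to the conventional equity scale: up to 0.2
#' highly equitable, 0.2-0.3 equitable, 0.3-0.4 bearable inequality,
#' 0.4-0.6 median inequality, above 0.6 high inequality. Values exactly on
#' 0.2, 0.3 and 0.4 take the lower category; high inequality starts strictly
#' above 0.6.
#'
#' @param g Numeric vector of Gini coefficients in \[0, 1\].
#' @return Character vector of category labels.
#' @export
gini_category <- function(g) {
  if (anyNA(g) || any(g < 0) || any(g > 1)) {
    stop("Gini coefficients must lie in [0, 1]", call. = FALSE)
  }
  cut(g, breaks = c(-Inf, 0.2, 0.3, 0.4, 0.6, Inf),
      labels = GINI_LEVELS, right = TRUE) |> as.character()
}

#' Per-group summary of accessibility scores
#'
#' Summarizes an accessibility result by group (by default the county):
#' number of units, mean, median, sample standard deviation (n - 1; 0 for a
#' single-unit group), min, max, the median-minus-mean diagnostic (negative
#' values flag groups where more than half the units score below the group
#' average), the Gini coefficient and its equity category. A row labelled
#' `"national"` summarizes all units together.
#'
#' @param scores An `fca_access` result from [accessibility_scores()],
#'   [regional_average()] or [run_all_methods()].
#' @param by Name of the grouping column in `scores` (default
#'   `"county_id"`), or a vector of group labels aligned with its rows.
#' @param weighted Population-weighted Gini (default) or unweighted.
#' @param national Include the all-units `"national"` row (default `TRUE`).
#' @return A tibble with one row per group.
#' @export
summary_stats <- function(scores, by = "county_id", weighted = TRUE,
                          national = TRUE) {
  stopifnot(inherits(scores, "fca_access"))
  group <- if (length(by) == 1L && is.character(by) && by %in% names(scores)) {
    scores[[by]]
  } else if (length(by) == nrow(scores)) {
    as.character(by)
  } else {
    stop("`by` must name a column of `scores` or give one label per row",
         call. = FALSE)
  }
  groups <- unique(group)
  one <- function(label, idx) {
    s <- scores$score[idx]
    p <- scores$population[idx]
    g <- gini(s, p, ids = scores$id[idx], weighted = weighted)
    tibble::tibble(
      group_id = label,
      n_units = length(idx),
      mean = mean(s),
      median = stats::median(s),
      sd = if (length(idx) > 1) stats::sd(s) else 0,
      min = min(s),
      max = max(s),
      median_minus_mean = stats::median(s) - mean(s),
      gini = g,
      gini_category = gini_category(g)
    )
  }
  out <- dplyr::bind_rows(lapply(groups, function(gr) {
    one(gr, which(group == gr))
  }))
  if (national) {
    out <- dplyr::bind_rows(out, one("national", seq_len(nrow(scores))))
  }
  attr(out, "method") <- attr(scores, "method")
  out
}

QUINTILE_COLORS <- c("red", "orange", "green", "lightblue", "darkblue")

#' Quintile map classes
#'
#' Groups scores into quintile classes 1-5 by percentile rank: class k holds
#' the units whose rank percentile falls in ((k-1) x 20%, k x 20%]; tied
#' scores share the class of their common (maximum) rank. The classes carry
#' the conventional choropleth colors red, orange, green, lightblue,
#' darkblue from lowest to highest accessibility. With fewer than five units
#' the classes are simply the ranks; if every score is equal there is
#' nothing to classify — all units get class 1 and a warning is issued.
#'
#' @param scores An `fca_access` result, or a bare numeric vector.
#' @param ids Unit ids (taken from `scores` when it is an `fca_access`).
#' @return A tibble with columns `id`, `score`, `class`, `color`.
#' @export
quintile_classes <- function(scores, ids = NULL) {
  if (inherits(scores, "fca_access")) {
    ids <- scores$id
    scores <- scores$score
  }
  n <- length(scores)
  ids <- ids %||% as.character(seq_len(n))
  stopifnot(n >= 1, length(ids) == n)
  if (n > 1 && max(scores) == min(scores)) {
    warning("all scores are equal; degenerate distribution, every unit in class 1",
            call. = FALSE)
    cls <- rep(1L, n)
  } else if (n < 5) {
    cls <- as.integer(rank(scores, ties.method = "max"))
  } else {
    r <- rank(scores, ties.method = "max")
    cls <- as.integer(ceiling(r * 5 / n))
  }
  tibble::tibble(id = as.character(ids), score = scores, class = cls,
                 color = QUINTILE_COLORS[pmin(cls, 5L)])
}

#' Three-stage prioritization of groups for resource improvement
#'
#' Applies the staged policy rule to per-group summaries (typically per
#' county, computed under one method): stage 1 — negative median-minus-mean
#' and a Gini in the median- or high-inequality category (the most unequal
#' under-served groups); stage 2 — negative median-minus-mean and a group
#' mean below the national mean, excluding stage-1 groups; stage 3 — any
#' remaining group with negative median-minus-mean; all other groups need no
#' action (`"none"`).
#'
#' @param summaries A [summary_stats()] tibble of the groups to stage
#'   (without, or ignoring, the national row).
#' @param national The national summary row (a one-row data frame with a
#'   `mean` column); defaults to the `"national"` row found in `summaries`.
#' @return A tibble with columns `group_id`, `stage` (factor with levels
#'   "1", "2", "3", "none").
#' @export
prioritize <- function(summaries, national = NULL) {
  if (is.null(national)) {
    hit <- summaries$group_id == "national"
    if (!any(hit)) {
      stop("no national row found; pass `national` explicitly", call. = FALSE)
    }
    national <- summaries[hit, , drop = FALSE]
    summaries <- summaries[!hit, , drop = FALSE]
  } else {
    summaries <- summaries[summaries$group_id != "national", , drop = FALSE]
  }
  low <- summaries$median_minus_mean < 0
  unequal <- summaries$gini_category %in% c("median_inequality", "high_inequality")
  below <- summaries$mean < national$mean[1]
  stage <- rep("none", nrow(summaries))
  stage[low] <- "3"
  stage[low & below] <- "2"
  stage[low & unequal] <- "1"
  tibble::tibble(group_id = summaries$group_id,
                 stage = factor(stage, levels = c("1", "2", "3", "none")))
}
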