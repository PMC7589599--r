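test_that("regional average reproduces the national providers-per-10k figure", {
  # one region holding the national totals: 1,140 providers, 3,618,878 elderly
  demand <- demand_points(tibble::tibble(
    id = "i1", region_id = "r1", county_id = "c1",
    population = 3618878, x_km = 0, y_km = 0
  ))
  fac <- facilities(tibble::tibble(
    id = c("j1", "j2"), region_id = "r1", county_id = "c1",
    capacity = c(1000, 140), rating = 4, x_km = 0, y_km = 0
  ))
  res <- regional_average(demand, fac)
  expect_equal(round(res$score, 2), 3.15)
  expect_identical(attr(res, "method"), "A0")
})

test_that("regional average handles empty regions, direct ratios and degenerate populations", {
  demand <- demand_points(tibble::tibble(
    id = c("i1", "i2", "i3"), region_id = c("r1", "r2", "r3"),
    county_id = "c1", population = c(10000, 500, 0), x_km = 0, y_km = 0
  ))
  fac <- facilities(tibble::tibble(
    id = c("j1", "j2"), region_id = c("r1", "r3"), county_id = "c1",
    capacity = c(2, 1), rating = 3, x_km = 0, y_km = 0
  ))
  expect_warning(res <- regional_average(demand, fac), "zero demand population")
  expect_equal(res$score, c(2, 0, 0))  # direct ratio; no facility; undefined -> 0

  orphan <- facilities(tibble::tibble(
    id = "j9", region_id = "elsewhere", county_id = "c9",
    capacity = 5, rating = 3, x_km = 0, y_km = 0
  ))
  expect_warning(regional_average(demand, orphan), "match no demand region")
})

test_that("selection weights normalize decay-weighted multipliers over the catchment", {
  demand <- demand_points(tibble::tibble(
    id = "i1", region_id = "r1", county_id = "c1", population = 100,
    x_km = 0, y_km = 0
  ))
  fac <- facilities(tibble::tibble(
    id = c("j1", "j2"), region_id = "r1", county_id = "c1",
    capacity = c(1, 3), rating = c(5, 2.5), x_km = 0, y_km = 0
  ))
  costs <- travel_costs(
    tibble::tibble(demand_id = "i1", facility_id = c("j1", "j2"),
                   distance_km = c(1, 2)),
    demand_ids = "i1", facility_ids = fac$id
  )
  w_cap <- selection_weights(demand, fac, costs, mode = "capacity")
  expect_equal(as.numeric(w_cap["i1", ]), c(0.25, 0.75))
  w_rat <- selection_weights(demand, fac, costs, mode = "rating")
  expect_equal(as.numeric(w_rat["i1", ]), c(2 / 3, 1 / 3))
  w_both <- selection_weights(demand, fac, costs, mode = "capacity_rating")
  expect_equal(as.numeric(w_both["i1", ]), c(0.4, 0.6))  # (5*1, 2.5*3) normalized

  # single facility in catchment gets weight 1 in every mode
  solo <- travel_costs(
    tibble::tibble(demand_id = "i1", facility_id = "j1", distance_km = 2),
    demand_ids = "i1", facility_ids = fac$id
  )
  for (m in MODES) {
    expect_equal(as.numeric(selection_weights(demand, fac, solo, mode = m)["i1", ]),
                 c(1, 0))
  }
})

test_that("facility service ratio follows the step-one definition and is linear in capacity", {
  fx <- worked_example_fixture("tiny")
  r <- facility_service_ratio(fx$demand, fx$facilities, fx$costs)
  # R = 2 / (1000*1 + 3000*0.5) = 8e-4
  expect_equal(r$ratio, 8e-4)
  expect_false(any(r$flagged))

  fac2 <- fx$facilities
  fac2$capacity <- fac2$capacity * 2
  r2 <- facility_service_ratio(fx$demand, fac2, fx$costs)
  expect_equal(r2$ratio, 2 * r$ratio)

  # facility with no demand within 30 km is flagged
  far <- travel_costs(
    tibble::tibble(demand_id = "i1", facility_id = "j1", distance_km = 31),
    demand_ids = fx$demand$id, facility_ids = "j1"
  )
  expect_warning(rf <- facility_service_ratio(fx$demand, fx$facilities, far),
                 "zero reachable")
  expect_true(rf$flagged)
  expect_true(is.na(rf$ratio))
})

test_that("two-step scores on the tiny worked example are 8.0 and 4.0 per 10,000 and conserve supply", {
  fx <- worked_example_fixture("tiny")
  a1 <- accessibility_scores("A1", fx$demand, fx$facilities, fx$costs)
  expect_equal(a1$score, c(8, 4))
  expect_equal(sum(fx$demand$population * a1$score) / 10000,
               sum(fx$facilities$capacity))
  # single facility: every method coincides
  for (m in c("A2", "A3", "A4")) {
    expect_equal(accessibility_scores(m, fx$demand, fx$facilities, fx$costs)$score,
                 a1$score)
  }
})

test_that("three-town fixture reproduces its frozen hand-computed scores", {
  fx <- worked_example_fixture("small")
  res <- run_all_methods(fx$demand, fx$facilities, fx$costs)
  for (m in FCA_METHODS) {
    expect_equal(res[[m]]$score, fx$expected[[m]], tolerance = 1e-12)
  }
})

test_that("production scores match the per-definition double-loop oracle on random instances", {
  for (seed in 1:8) {
    inst <- random_instance(seed, n_demand = sample(5:20, 1), n_facility = sample(3:10, 1))
    dmat <- oracle_dist_matrix(inst$demand, inst$facilities, inst$costs)
    for (m in FCA_METHODS) {
      got <- suppressWarnings(
        accessibility_scores(m, inst$demand, inst$facilities, inst$costs)
      )$score
      want <- oracle_scores(inst$demand, inst$facilities, dmat, method_to_mode[[m]])
      expect_equal(got, want, tolerance = 1e-9,
                   label = sprintf("seed %d method %s", seed, m))
    }
  }
})

test_that("a demand point out of reach of every facility scores 0 under every method", {
  inst <- random_instance(3)
  # push one demand point 200 km away and rebuild its distances
  demand <- inst$demand
  costs <- tibble::as_tibble(inst$costs)
  costs$distance_km[costs$demand_id == "d01"] <- 200
  costs <- travel_costs(costs, demand_ids = demand$id,
                        facility_ids = inst$facilities$id)
  for (m in FCA_METHODS) {
    sc <- suppressWarnings(accessibility_scores(m, demand, inst$facilities, costs))
    expect_identical(sc$score[sc$id == "d01"], 0)
    expect_true(all(sc$score >= 0))
  }
})

test_that("increasing one facility's capacity never decreases a two-step score", {
  inst <- random_instance(7)
  base <- suppressWarnings(
    accessibility_scores("A1", inst$demand, inst$facilities, inst$costs)
  )$score
  fac2 <- inst$facilities
  fac2$capacity[3] <- fac2$capacity[3] + 5
  bigger <- suppressWarnings(
    accessibility_scores("A1", inst$demand, fac2, inst$costs)
  )$score
  expect_true(all(bigger - base >= -1e-12))
})

test_that("equal ratings collapse A4 to A2, equal capacities collapse A4 to A3", {
  inst <- random_instance(11)
  flat_rating <- inst$facilities
  flat_rating$rating <- 3.7
  r <- suppressWarnings(
    run_all_methods(inst$demand, flat_rating, inst$costs, methods = c("A2", "A4"))
  )
  expect_equal(r$A4$score, r$A2$score, tolerance = 1e-9)

  flat_cap <- inst$facilities
  flat_cap$capacity <- 2
  r <- suppressWarnings(
    run_all_methods(inst$demand, flat_cap, inst$costs, methods = c("A3", "A4"))
  )
  expect_equal(r$A4$score, r$A3$score, tolerance = 1e-9)

  # equal ratings also reduce rating weights to pure distance proportions
  w <- selection_weights(inst$demand, flat_rating, inst$costs, mode = "rating")
  F <- fcaequity:::decay_matrix(inst$demand, flat_rating, inst$costs)
  rs <- rowSums(F)
  pure <- F / ifelse(rs > 0, rs, 1)
  expect_equal(unclass(w), unclass(pure), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("run_all_methods is deterministic and handles an empty facility effect", {
  fx <- worked_example_fixture("small")
  r1 <- run_all_methods(fx$demand, fx$facilities, fx$costs)
  r2 <- run_all_methods(fx$demand, fx$facilities, fx$costs)
  expect_identical(r1, r2)
  expect_named(r1, c("A0", "A1", "A2", "A3", "A4"))

  # all facilities out of range: zero scores everywhere for FCA methods
  far <- travel_costs(
    tibble::tibble(demand_id = fx$demand$id, facility_id = "j1",
                   distance_km = 40),
    demand_ids = fx$demand$id, facility_ids = fx$facilities$id
  )
  res <- suppressWarnings(run_all_methods(fx$demand, fx$facilities, far,
                                          methods = FCA_METHODS))
  for (m in FCA_METHODS) expect_true(all(res[[m]]$score == 0))
  expect_error(accessibility_scores("A9", fx$demand, fx$facilities, fx$costs),
               "unknown method")
})
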