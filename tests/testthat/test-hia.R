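test_that("health impact function evaluates the log-linear form exactly", {
  expect_equal(health_impact(1000, 0.000795, 0), 0)
  expect_equal(health_impact(1000, 0.000795, 5), 3.98291079082,
               tolerance = 1e-10)
  expect_equal(health_impact(100, 0.001, -10), -0.995016625083,
               tolerance = 1e-10)
  expect_error(health_impact(-1, 0.001, 5), "non-negative")
  expect_error(health_impact(10, 0.001, NA), "finite")
})

test_that("health impact is within the Taylor remainder of its linearization", {
  set.seed(31)
  y0 <- runif(200, 0, 1e4)
  beta <- runif(200, 1e-4, 2e-3)
  dx <- runif(200, -8, 8)
  dy <- health_impact(y0, beta, dx)
  bound <- 0.5 * y0 * (beta * dx)^2 * exp(abs(beta * dx))
  expect_true(all(abs(dy - y0 * beta * dx) <= bound + 1e-12))
})

test_that("cell impacts combine rate, population, season and delta", {
  w <- tiny_world(rate = 0.01, persons = 100000, d = 5, beta = 0.000795)
  res <- cell_impacts(w$delta, w$pop, w$weights, w$rates, w$f, w$season)
  expect_equal(res$y0, 0.01 * 100000 * 92 / 365, tolerance = 1e-12)
  expect_equal(res$delta_cases, 1.00391176098, tolerance = 1e-9)

  # zero delta, zero impact
  w0 <- tiny_world(d = 0)
  expect_equal(cell_impacts(w0$delta, w0$pop, w0$weights, w0$rates, w0$f,
                            w0$season)$delta_cases, 0)

  # doubling population doubles the impact exactly
  w2 <- tiny_world(persons = 200000)
  res2 <- cell_impacts(w2$delta, w2$pop, w2$weights, w2$rates, w2$f, w2$season)
  expect_equal(res2$delta_cases, 2 * res$delta_cases, tolerance = 1e-12)
})

test_that("daily application of the seasonal mean equals one seasonal evaluation", {
  w <- tiny_world()
  res <- cell_impacts(w$delta, w$pop, w$weights, w$rates, w$f, w$season)
  # per-day baseline incidence, summed over the 92 days
  daily_y0 <- 0.01 * 100000 / 365
  daily_sum <- 92 * health_impact(daily_y0, w$f$beta, w$delta$delta)
  expect_equal(res$delta_cases, daily_sum, tolerance = 1e-12)
})

test_that("C-R age ranges restrict the exposed population", {
  w <- tiny_world()
  w$pop <- tibble::tibble(county_id = 1, age_lo = c(0, 65),
                          age_hi = c(65, Inf), count = c(80000, 20000))
  w$rates <- tibble::tibble(endpoint = "nonaccidental mortality",
                            location_id = 1, age_lo = c(0, 65),
                            age_hi = c(65, Inf), rate = c(0.002, 0.04))
  f65 <- crf("fixture", "nonaccidental mortality", "MDA8", 0.000795, 1e-4,
             age_lo = 65, age_hi = Inf)
  res <- cell_impacts(w$delta, w$pop, w$weights, w$rates, f65, w$season)
  expect_equal(res$y0, 0.04 * 20000 * 92 / 365, tolerance = 1e-12)
  # missing rate coverage is rejected with the county named
  expect_error(
    cell_impacts(w$delta, w$pop, w$weights, w$rates[2, ],
                 crf("fixture", "nonaccidental mortality", "MDA8",
                     0.000795, 1e-4), w$season),
    "county: 1")
})

test_that("aggregation is exact, order-independent, and additive over regions", {
  cells <- tibble::tibble(cell_id = 1:3, delta_cases = c(-275, 369, 54))
  regions <- tibble::tibble(cell_id = 1:3,
                            region = c("Northeast", "Southeast", "West"))
  agg <- aggregate_impacts(cells, regions)
  expect_equal(agg$delta_cases[agg$region == "National"], 148)
  expect_equal(sum(agg$delta_cases[agg$region != "National"]),
               agg$delta_cases[agg$region == "National"])
  # permutation invariance
  perm <- aggregate_impacts(cells[c(3, 1, 2), ], regions)
  expect_equal(agg[order(agg$region), ], perm[order(perm$region), ])
  # all impact in one region leaves the others absent/zero
  one <- aggregate_impacts(tibble::tibble(cell_id = 1, delta_cases = 5), regions)
  expect_equal(one$delta_cases[one$region == "National"], 5)
  expect_error(aggregate_impacts(tibble::tibble(cell_id = 9, delta_cases = 1),
                                 regions), "not covered")
})

test_that("national total equals the cell sum on a synthetic multi-cell run", {
  grid <- make_grid(6, 4)
  regions <- assign_regions(grid)
  gen <- generate_population(5e6, 0.2, grid, seed = 2)
  inc <- generate_incidence(grid$cell_id, seed = 3)
  profile <- default_system_profiles()[1, ]
  delta <- generate_exposure(profile, grid, seed = 4)
  res <- cell_impacts(delta, gen$projection, gen$weights, inc$rates,
                      default_crf_fixtures()[1, ])
  agg <- aggregate_impacts(res, regions)
  expect_equal(agg$delta_cases[agg$region == "National"],
               sum(res$delta_cases), tolerance = 1e-8)
})

test_that("reported values round to the nearest 10, halves away from zero", {
  expect_equal(round_report(148), 150)
  expect_equal(round_report(-275), -280)
  expect_equal(round_report(-274), -270)
  expect_equal(round_report(275), 280)
  expect_equal(round_report(0.4), 0)
  expect_equal(round_report(c(-5, 5, 14.9)), c(-10, 10, 10))
})

test_that("tidy and glance summarize a cell-level result", {
  w <- tiny_world()
  res <- cell_impacts(w$delta, w$pop, w$weights, w$rates, w$f, w$season)
  td <- generics::tidy(res)
  expect_named(td, c("cell_id", "delta", "y0", "delta_cases"))
  gl <- generics::glance(res)
  expect_equal(gl$national, sum(res$delta_cases))
  expect_equal(gl$endpoint, "nonaccidental mortality")
})
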