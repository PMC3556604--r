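small_scenario <- function(seed = 12) {
  grid <- make_grid(6, 4)
  profiles <- default_system_profiles()[c(1, 5), ]
  pops <- default_population_scenarios()[c(1, 5), ]
  pops$total <- pops$total / 100   # keep the fixture light
  simulate_scenario(nx = 6, ny = 4, seed = seed, profiles = profiles,
                    pop_scenarios = pops,
                    crfs = default_crf_fixtures()[1:2, ])
}

test_that("a 1x1x1 factorial equals a direct engine call", {
  sc <- small_scenario()
  ens <- run_factorial(sc$systems[1], sc$populations[1], sc$crfs[1, ],
                       sc$rates, sc$season)
  direct <- cell_impacts(sc$systems[[1]], sc$populations[[1]]$projection,
                         sc$populations[[1]]$weights, sc$rates,
                         sc$crfs[1, ], sc$season)
  expect_equal(nrow(ens), 1)
  expect_equal(ens$deaths, sum(direct$delta_cases), tolerance = 1e-12)
})

test_that("the factorial is complete, balanced, and duplicates systems faithfully", {
  sc <- small_scenario()
  ens <- run_factorial(sc$systems, sc$populations, sc$crfs, sc$rates, sc$season)
  expect_equal(nrow(ens), 2 * 2 * 2)
  expect_equal(anyDuplicated(ens[c("system", "study", "population")]), 0L)
  # a system listed twice under two names gives identical rows per (study, pop)
  twice <- run_factorial(list(a = sc$systems[[1]], b = sc$systems[[1]]),
                         sc$populations, sc$crfs, sc$rates, sc$season)
  wide <- tidyr::pivot_wider(twice, names_from = "system",
                             values_from = "deaths")
  expect_equal(wide$a, wide$b, tolerance = 1e-12)
})

test_that("ANOVA decomposition matches the brute-force oracle on random tables", {
  set.seed(77)
  for (i in 1:10) {
    tab <- random_ensemble(3, 3, 3)
    dec <- anova_decompose(tab)
    oracle <- anova_bruteforce(tab)
    for (src in dec$source) {
      expect_equal(dec$sumsq[dec$source == src], unname(oracle[src]),
                   tolerance = 1e-8)
    }
    expect_equal(sum(dec$sumsq), unname(oracle["total"]), tolerance = 1e-8)
    expect_equal(sum(dec$df), nrow(tab) - 1)
    expect_equal(sum(dec$percent), 100, tolerance = 1e-8)
  }
})

test_that("purely additive effects produce zero interaction sums of squares", {
  tab <- tidyr::expand_grid(system = c("s1", "s2"), study = c("t1", "t2"),
                            population = c("p1", "p2"))
  eff <- c(s1 = 0, s2 = 10, t1 = 0, t2 = 3, p1 = 0, p2 = 1)
  tab$deaths <- eff[tab$system] + eff[tab$study] + eff[tab$population]
  dec <- anova_decompose(tab)
  inter <- dec$sumsq[grepl(" x ", dec$source)]
  expect_length(inter, 4)  # three two-way terms plus the three-way term
  expect_equal(inter, rep(0, 4), tolerance = 1e-10)
})

test_that("ANOVA input validation and degenerate tables", {
  tab <- random_ensemble(2, 2, 2)
  expect_error(anova_decompose(tab[-1, ]), "balanced")
  same <- tab; same$deaths <- 7
  expect_warning(dec <- anova_decompose(same), "percentages reported as 0")
  expect_equal(dec$percent, rep(0, 7))
})

test_that("ANOVA decomposition is invariant to factor-level permutation", {
  set.seed(41)
  tab <- random_ensemble(3, 2, 4)
  a <- anova_decompose(tab)
  b <- anova_decompose(tab[sample(nrow(tab)), ])
  expect_equal(a$sumsq, b$sumsq, tolerance = 1e-10)
})

test_that("range summary finds extrema with labels, permutation-invariant", {
  tab <- random_ensemble(3, 3, 3)
  r1 <- summarize_range(tab)
  r2 <- summarize_range(tab[sample(nrow(tab)), ])
  expect_equal(r1$deaths, r2$deaths)
  expect_equal(r1$system, r2$system)
  single <- tab[5, ]
  rs <- summarize_range(single)
  expect_equal(rs$deaths[1], rs$deaths[2])
})

test_that("population-weighted CDF weights cells by persons", {
  d <- tibble::tibble(cell_id = 1:2, delta = c(-1, 1))
  p <- tibble::tibble(cell_id = 1:2, value = c(100, 300))
  cdf <- population_weighted_cdf(d, p)
  expect_equal(cdf$cum_fraction[cdf$delta == -1], 0.25)
  expect_equal(attr(cdf, "fraction_increase"), 0.75)

  # all-increase field
  dall <- tibble::tibble(cell_id = 1:3, delta = 1)
  pall <- tibble::tibble(cell_id = 1:3, value = c(1, 2, 3))
  expect_equal(attr(population_weighted_cdf(dall, pall), "fraction_increase"), 1)

  # uniform weights reduce to the unweighted empirical CDF
  set.seed(8)
  du <- tibble::tibble(cell_id = 1:50, delta = rnorm(50))
  pu <- tibble::tibble(cell_id = 1:50, value = 2)
  cdfu <- population_weighted_cdf(du, pu)
  expect_equal(cdfu$cum_fraction,
               stats::ecdf(du$delta)(sort(du$delta)))

  # invariant to rescaling the weights
  cdfs <- population_weighted_cdf(du, dplyr::mutate(pu, value = value * 1e6))
  expect_equal(cdfu$cum_fraction, cdfs$cum_fraction)
  expect_error(population_weighted_cdf(du, dplyr::mutate(pu, value = 0)),
               "must be > 0")
})

test_that("CDF is nondecreasing and ends at one", {
  sc <- small_scenario()
  popf <- allocate_to_grid(sc$populations[[1]]$projection,
                           sc$populations[[1]]$weights)
  cdf <- population_weighted_cdf(sc$systems[[1]], popf)
  expect_true(all(diff(cdf$cum_fraction) >= -1e-12))
  expect_equal(cdf$cum_fraction[nrow(cdf)], 1, tolerance = 1e-12)
})

test_that("the published ensemble table loads with its documented shape", {
  pub <- national_mortality_ensemble()
  expect_equal(nrow(pub), 105)
  expect_equal(dplyr::n_distinct(pub$system), 7)
  expect_equal(dplyr::n_distinct(pub$study), 3)
  expect_equal(dplyr::n_distinct(pub$population), 5)
  expect_true(all(pub$deaths %% 10 == 0))
})

test_that("autoplot methods return ggplot objects", {
  sc <- small_scenario()
  dec <- anova_decompose(run_factorial(sc$systems, sc$populations, sc$crfs,
                                       sc$rates, sc$season))
  expect_s3_class(ggplot2::autoplot(dec), "ggplot")
  popf <- allocate_to_grid(sc$populations[[1]]$projection,
                           sc$populations[[1]]$weights)
  expect_s3_class(ggplot2::autoplot(population_weighted_cdf(sc$systems[[1]],
                                                            popf)), "ggplot")
  res <- cell_impacts(sc$systems[[1]], sc$populations[[1]]$projection,
                      sc$populations[[1]]$weights, sc$rates, sc$crfs[1, ])
  expect_s3_class(ggplot2::autoplot(res, sc$grid), "ggplot")
})
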