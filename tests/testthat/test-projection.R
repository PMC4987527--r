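test_that("zero incidence yields zero cases regardless of inputs", {
  pr <- project_cases(list(male = toy_rates()),
                      toy_pyramid(fill = 1e5), duration = 10)
  expect_equal(pr$total, 0)
  expect_true(all(pr$cases == 0))
})

test_that("a single stratum reproduces the direct product", {
  # 2.0 per 100,000 x 100,000 persons x 3.0 years = 6.0 cases
  pr <- project_cases(list(male = toy_rates(list(`60-64` = 2))),
                      toy_pyramid(list(`60-64` = 1e5)),
                      duration = 3)
  expect_equal(pr$total, 6.0)
  expect_equal(unname(pr$cases["60-64", "male"]), 6.0)
})

test_that("multi-band totals match the hand-summed oracle", {
  # (4/1e5 * 2.5e5 + 10/1e5 * 5e4) * 2.5 = 37.5
  pr <- project_cases(
    list(male = toy_rates(list(`60-64` = 4, `65-69` = 10))),
    toy_pyramid(list(`60-64` = 2.5e5, `65-69` = 5e4)),
    duration = 2.5)
  expect_equal(pr$total, 37.5)
  expect_equal(unname(pr$cases_by_sex["male"]), 37.5)
})

test_that("sex totals equal band sums and projections are linear", {
  set.seed(505)
  for (rep in 1:5) {
    vals_r <- stats::setNames(as.list(round(stats::runif(21, 0, 10), 3)),
                              grid_labels)
    vals_p <- stats::setNames(as.list(round(stats::runif(21, 0, 1e6))),
                              grid_labels)
    rates <- list(male = toy_rates(vals_r),
                  female = toy_rates(vals_r, sex = "female"))
    pyr <- toy_pyramid(vals_p, sexes = c("male", "female"))
    D <- stats::runif(1, 1, 5)
    pr <- project_cases(rates, pyr, D)
    expect_equal(pr$cases_by_sex, colSums(pr$cases), tolerance = 1e-12)
    expect_equal(pr$total, sum(pr$cases), tolerance = 1e-12)
    # doubling duration doubles every count
    pr2 <- project_cases(rates, pyr, 2 * D)
    expect_equal(pr2$cases, 2 * pr$cases, tolerance = 1e-12)
    # scaling the population by c scales totals by c
    pyr_c <- population_pyramid(pyr$region, pyr$year, 3 * pyr$counts)
    pr3 <- project_cases(rates, pyr_c, D)
    expect_equal(pr3$total, 3 * pr$total, tolerance = 1e-9)
  }
})

test_that("raising any single rate or population entry never lowers totals", {
  set.seed(606)
  base_r <- stats::setNames(as.list(stats::runif(21, 0, 5)), grid_labels)
  base_p <- stats::setNames(as.list(stats::runif(21, 0, 1e5)), grid_labels)
  pr0 <- project_cases(list(male = toy_rates(base_r)),
                       toy_pyramid(base_p), 3)
  for (b in sample(grid_labels, 5)) {
    bumped <- base_r; bumped[[b]] <- bumped[[b]] + 1
    pr1 <- project_cases(list(male = toy_rates(bumped)),
                         toy_pyramid(base_p), 3)
    expect_gte(pr1$total, pr0$total)
    bumped_p <- base_p; bumped_p[[b]] <- bumped_p[[b]] + 1e4
    pr2 <- project_cases(list(male = toy_rates(base_r)),
                         toy_pyramid(bumped_p), 3)
    expect_gte(pr2$total, pr0$total)
  }
})

test_that("region mismatches are configuration errors", {
  expect_error(
    project_cases(list(male = toy_rates(region = "A")),
                  toy_pyramid(region = "B"), 3),
    class = "alscast_config_error")
  expect_error(
    project_cases(list(male = toy_rates()), toy_pyramid(),
                  duration_model("Elsewhere", 3)),
    class = "alscast_config_error")
  expect_error(
    project_cases(list(female = toy_rates(sex = "female")),
                  toy_pyramid(sexes = "male"), 3),
    class = "alscast_config_error")
})

test_that("percent change matches its definition and display rounding", {
  expect_equal(percent_change(222801, 376674), 69.06298,
               tolerance = 1e-6)
  expect_equal(round_half_away(percent_change(222801, 376674)), 69)
  expect_equal(percent_change(42, 42), 0)
  expect_equal(percent_change(100, 250), 150)
  expect_error(percent_change(0, 5), class = "alscast_domain_error")
  expect_error(percent_change(-3, 5), class = "alscast_domain_error")
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5, -2.5)),
               c(1, 2, 3, -1, -3))
  expect_equal(round_half_away(2.345, 2), 2.35)
})

test_that("aggregation conserves totals and shares sum to one", {
  set.seed(707)
  regions <- sprintf("r%02d", 1:8)
  tab <- expand.grid(region = regions, year = c(2015, 2040),
                     sex = c("male", "female"),
                     stringsAsFactors = FALSE)
  tab$cases <- stats::runif(nrow(tab), 10, 1e4)
  hier <- region_hierarchy(data.frame(
    region = regions,
    continent = rep(c("Asia", "Europe", "Africa", "Oceania"), 2),
    development = sample(c("developed", "developing"), 8, replace = TRUE)))
  for (by in c("development", "continent", "all")) {
    agg <- aggregate_cases(tab, hier, by = by)
    for (y in c(2015, 2040)) {
      expect_equal(sum(agg$cases[agg$year == y]),
                   sum(tab$cases[tab$year == y]), tolerance = 1e-9)
      expect_equal(sum(agg$share[agg$year == y]), 1, tolerance = 1e-9)
    }
  }
  expect_error(
    aggregate_cases(tab, hier[hier$region != "r03", ], by = "all"),
    regexp = "r03", class = "alscast_config_error")
})

test_that("median population age interpolates within the median band", {
  m <- median_population_age(toy_pyramid(list(`40-44` = 1000)))
  expect_gte(m, 40); expect_lt(m, 45)
  # equal mass in the extreme bands: the half-count is reached exactly at
  # the end of the first band, so interpolation gives 0 + 5 * 1 = 5
  expect_equal(
    median_population_age(toy_pyramid(list(`0-4` = 500, `100+` = 500))),
    5)
  # symmetric pyramid: median at the midpoint of the centre band (50-54)
  sym <- stats::setNames(as.list(c(1:10, 11, 10:1)), grid_labels)
  expect_equal(median_population_age(toy_pyramid(sym)), 52.5)
  expect_error(median_population_age(toy_pyramid()),
               class = "alscast_domain_error")
})

test_that("ageing correlation matches the closed-form Pearson formula", {
  x <- c(a = 10, b = 20, c = 30, d = 40)
  expect_equal(ageing_correlation(x, 2 * x + 5), 1.0)
  expect_equal(ageing_correlation(x, -x), -1.0)
  set.seed(808)
  cx <- stats::setNames(stats::rnorm(12, 30, 10), sprintf("r%02d", 1:12))
  cy <- 0.6 * cx + stats::setNames(stats::rnorm(12, 0, 5), names(cx))
  manual <- sum((cx - mean(cx)) * (cy - mean(cy))) /
    sqrt(sum((cx - mean(cx))^2) * sum((cy - mean(cy))^2))
  expect_equal(ageing_correlation(cx, cy), manual, tolerance = 1e-12)
  expect_error(ageing_correlation(x[1:2], x[1:2]),
               class = "alscast_domain_error")
  expect_error(ageing_correlation(c(a = 1, b = 1, c = 1), x[1:3]),
               class = "alscast_domain_error")
})
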