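# Small in-code builders used across the suite.

grid_labels <- standard_age_grid()$label

# harmonized rates with a handful of non-zero bands
toy_rates <- function(values = list(), region = "Toy", sex = "male",
                      study_population = 1e6) {
  r <- stats::setNames(numeric(21), grid_labels)
  for (b in names(values)) r[b] <- values[[b]]
  harmonized_rates(region, sex, r, study_population = study_population)
}

# pyramid with given band counts (same counts for every listed sex)
toy_pyramid <- function(values = list(), region = "Toy", year = 2015,
                        sexes = "male", fill = 0) {
  m <- matrix(fill, 21, length(sexes),
              dimnames = list(grid_labels, sexes))
  for (b in names(values)) m[b, ] <- values[[b]]
  population_pyramid(region, year, m)
}

# pyramid uniform in single years of age within every band
uniform_pyramid <- function(per_year = 100, region = "Toy", year = 2015,
                            sexes = "male") {
  toy_pyramid(region = region, year = year, sexes = sexes,
              fill = 5 * per_year)
}

# random valid schedule: contiguous 5-year-aligned bands, maybe open-ended
random_schedule <- function(region, sex) {
  k <- sample(1:5, 1)
  brks <- sort(sample(seq(0, 100, by = 5), k + 1))
  lo <- brks[-(k + 1)]
  hi <- brks[-1] - 1
  if (stats::runif(1) < 0.5) hi[k] <- NA
  incidence_schedule(
    region, sex,
    data.frame(age_lo = lo, age_hi = hi,
               rate = round(stats::runif(k, 0, 12), 3)),
    study_population = sample(1e5:1e7, 1),
    case_definition = sample(c("ALS", "MND"), 1),
    study_period = "2000-2010")
}

# compare two schedules field-by-field
expect_same_schedule <- function(a, b) {
  expect_equal(a$region, b$region)
  expect_equal(a$sex, b$sex)
  expect_equal(a$case_definition, b$case_definition)
  expect_equal(a$study_population, b$study_population)
  expect_equal(as.numeric(a$bands$age_lo), as.numeric(b$bands$age_lo))
  expect_equal(as.numeric(a$bands$age_hi), as.numeric(b$bands$age_hi))
  expect_equal(a$bands$rate, b$bands$rate)
}

write_csv_text <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
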