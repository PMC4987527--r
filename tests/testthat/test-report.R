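synth_inputs <- function(seed = 31, n_regions = 4, dir = tempfile("inputs")) {
  world <- generate_world(synthetic_world_spec(n_regions = n_regions,
                                               seed = seed))
  paths <- write_world(world, dir)
  list(world = world, paths = paths, dir = dir)
}

test_that("cmd_project reproduces the synthetic world's embedded truth", {
  inp <- synth_inputs()
  out_dir <- tempfile("out")
  cfg <- run_config(incidence = inp$paths[["incidence"]],
                    durations = inp$paths[["durations"]],
                    population = inp$paths[["population"]],
                    hierarchy = inp$paths[["hierarchy"]],
                    out_dir = out_dir, quiet = TRUE)
  res <- cmd_project(cfg)
  merged <- merge(res$table, inp$world$truth,
                  by = c("region", "year", "sex"),
                  suffixes = c("", ".truth"))
  expect_equal(nrow(merged), nrow(inp$world$truth))
  expect_equal(merged$cases, merged$cases.truth, tolerance = 1e-9)
  expect_true(all(file.exists(res$files)))
  # machine layer is unrounded; totals in the summary match the table
  expect_equal(sum(res$summary$totals$cases), sum(res$table$cases),
               tolerance = 1e-9)
  # development shares per year sum to one
  dev <- res$summary$development
  for (y in unique(dev$year)) {
    expect_equal(sum(dev$share[dev$year == y]), 1, tolerance = 1e-9)
  }
})

test_that("identical inputs and config give byte-identical outputs", {
  inp <- synth_inputs(seed = 77)
  run_once <- function(out_dir) {
    cfg <- run_config(incidence = inp$paths[["incidence"]],
                      durations = inp$paths[["durations"]],
                      population = inp$paths[["population"]],
                      hierarchy = inp$paths[["hierarchy"]],
                      out_dir = out_dir, quiet = TRUE)
    cmd_project(cfg)$files
  }
  f1 <- run_once(tempfile("o1"))
  f2 <- run_once(tempfile("o2"))
  for (k in c("cases", "table")) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
  # summary.json differs only in out_dir-independent content
  expect_identical(readLines(f1[["summary"]]), readLines(f2[["summary"]]))
})

test_that("reports embed provenance: digests, vintage, software, config hash", {
  inp <- synth_inputs(seed = 78)
  cfg <- run_config(incidence = inp$paths[["incidence"]],
                    durations = inp$paths[["durations"]],
                    population = inp$paths[["population"]],
                    hierarchy = inp$paths[["hierarchy"]],
                    out_dir = tempfile("out"), quiet = TRUE)
  s <- cmd_project(cfg)$summary
  expect_named(s$provenance$input_md5,
               c("incidence", "durations", "population", "hierarchy"))
  expect_match(s$provenance$software, "^alscast ")
  # plain CSV inputs carry no vintage metadata (only fetch_idb caches do)
  expect_equal(s$provenance$population_vintage, "unknown")
  expect_match(s$provenance$config_hash, "^[0-9a-f]{32}$")
})

test_that("an empty incidence file aborts with a validation error", {
  inp <- synth_inputs(seed = 79)
  empty <- tempfile(fileext = ".csv")
  write_incidence_table(list(), empty)
  cfg <- run_config(incidence = empty,
                    durations = inp$paths[["durations"]],
                    population = inp$paths[["population"]],
                    hierarchy = inp$paths[["hierarchy"]],
                    out_dir = tempfile("out"), quiet = TRUE)
  expect_error(cmd_project(cfg), class = "alscast_validation_error")
})

test_that("cmd_validate counts parsed objects and propagates errors", {
  inp <- synth_inputs(seed = 80, n_regions = 3)
  cfg <- run_config(incidence = inp$paths[["incidence"]],
                    durations = inp$paths[["durations"]],
                    population = inp$paths[["population"]],
                    hierarchy = inp$paths[["hierarchy"]],
                    quiet = TRUE)
  out <- cmd_validate(cfg)
  expect_equal(out$schedules, 6L)   # 3 regions x 2 sexes
  expect_equal(out$durations, 3L)
  expect_equal(out$pyramids, 6L)    # 3 regions x 2 epochs
  cfg$incidence <- tempfile()       # nonexistent
  expect_error(cmd_validate(cfg), class = "alscast_config_error")
})

test_that("cmd_global combines assigned and pooled continents correctly", {
  world <- generate_world(synthetic_world_spec(n_regions = 3, seed = 55))
  dir <- tempfile("glob")
  paths <- write_world(world, dir)
  # continent pyramids: scaled-up copies of two region pyramids
  cont_pyrs <- list()
  for (y in world$spec$years) {
    p1 <- world$pyramids[[paste("region01", y, sep = ".")]]
    p2 <- world$pyramids[[paste("region02", y, sep = ".")]]
    cont_pyrs[[paste("NorthAmerica", y)]] <-
      population_pyramid("NorthAmerica", y, p1$counts * 4)
    cont_pyrs[[paste("Asia", y)]] <-
      population_pyramid("Asia", y, p2$counts * 9)
  }
  pop_path <- file.path(dir, "continents.csv")
  write_idb_csv(cont_pyrs, pop_path)
  assign_path <- write_csv_text(c("continent,source_region",
                                  "NorthAmerica,region01"))
  member_path <- write_csv_text(c("continent,member_region",
                                  "Asia,region02", "Asia,region03"))
  cfg <- run_config(incidence = paths[["incidence"]],
                    durations = paths[["durations"]],
                    population = pop_path,
                    assignment = assign_path, membership = member_path,
                    out_dir = tempfile("gout"), quiet = TRUE)
  res <- cmd_global(cfg)
  # oracle: rebuild both sources by hand and project directly
  regions <- vapply(world$schedules, `[[`, character(1), "region")
  hr <- lapply(world$schedules, harmonize)
  dl <- stats::setNames(
    vapply(world$durations, `[[`, numeric(1), "median_duration"),
    vapply(world$durations, `[[`, character(1), "region"))
  na_src <- rate_source(
    stats::setNames(hr[regions == "region01"],
                    vapply(hr[regions == "region01"], `[[`, character(1),
                           "sex")),
    dl[["region01"]], "NorthAmerica")
  asia_src <- pool_schedules(hr[regions %in% c("region02", "region03")],
                             world$durations, "Asia")
  expected <- vapply(world$spec$years, function(y) {
    project_cases(na_src$rates, cont_pyrs[[paste("NorthAmerica", y)]],
                  na_src$duration)$total +
      project_cases(asia_src$rates, cont_pyrs[[paste("Asia", y)]],
                    asia_src$duration)$total
  }, numeric(1))
  expect_equal(res$world$cases[order(res$world$year)], expected,
               tolerance = 1e-9)
})

test_that("reference aggregation reproduces the published development split", {
  dev <- aggregate_cases(reference_case_table(), reference_hierarchy(),
                         by = "development")
  s15 <- dev$share[dev$group == "developed" & dev$year == 2015]
  s40 <- dev$share[dev$group == "developed" & dev$year == 2040]
  expect_equal(round_half_away(100 * s15), 71)
  expect_equal(round_half_away(100 * s40), 67)
})
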