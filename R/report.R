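#' Assemble a run configuration
#'
#' Bundles input paths and engine switches for the report commands.
#' Referenced files are checked when a command runs, not here, so a
#' config can be built before its inputs exist.
#'
#' @param incidence,durations,population,hierarchy Input CSV paths (see
#'   [read_incidence_table()], [read_durations()], [read_idb_csv()],
#'   [read_hierarchy()]).
#' @param assignment,membership For [cmd_global()]: CSV paths mapping
#'   `continent,source_region` (single-study continents) and
#'   `continent,member_region` (pooled continents).
#' @param years Calendar years to project (default 2015 and 2040).
#' @param overlap,extend_oldest Harmonization switches, see
#'   [harmonize()].
#' @param out_dir Output directory for report files.
#' @param seed Seed for synthetic subcommands.
#' @param quiet Suppress progress messages.
#' @return A `run_config` list.
#' @export
run_config <- function(incidence = NULL, durations = NULL,
                       population = NULL, hierarchy = NULL,
                       assignment = NULL, membership = NULL,
                       years = c(2015L, 2040L),
                       overlap = c("proportional", "full"),
                       extend_oldest = FALSE,
                       out_dir = ".", seed = 1L, quiet = FALSE) {
  if (length(years) == 0L) abort_config("years must be non-empty")
  structure(
    list(incidence = incidence, durations = durations,
         population = population, hierarchy = hierarchy,
         assignment = assignment, membership = membership,
         years = as.integer(years), overlap = match.arg(overlap),
         extend_oldest = isTRUE(extend_oldest),
         out_dir = out_dir, seed = as.integer(seed), quiet = isTRUE(quiet)),
    class = "run_config"
  )
}

require_files <- function(config, fields) {
  for (f in fields) {
    p <- config[[f]]
    if (is.null(p)) abort_config(sprintf("config is missing the '%s' path", f))
    if (!file.exists(p)) {
      abort_config(sprintf("%s file not found: %s", f, p))
    }
  }
}

say <- function(config, fmt, ...) {
  if (!config$quiet) message(sprintf(fmt, ...))
}

# provenance block embedded in every machine-readable report
provenance <- function(config, pyramids) {
  inputs <- Filter(Negate(is.null),
                   config[c("incidence", "durations", "population",
                            "hierarchy", "assignment", "membership")])
  digests <- vapply(inputs, function(p) unname(tools::md5sum(p)),
                    character(1))
  cfg <- config[c("years", "overlap", "extend_oldest")]
  cfg_hash <- unname(tools::md5sum(
    local({ f <- tempfile(); writeLines(deparse(cfg), f); f })))
  vintages <- unique(stats::na.omit(
    vapply(pyramids, `[[`, character(1), "vintage")))
  list(software = sprintf("alscast %s",
                          as.character(utils::packageVersion("alscast"))),
       input_md5 = as.list(digests),
       config = cfg, config_hash = cfg_hash,
       population_vintage = if (length(vintages)) vintages else "unknown")
}

# harmonize + project every (region in schedules) x (year in config$years)
project_all <- function(schedules, durations, pyramids, config) {
  if (length(schedules) == 0L) {
    abort_validation("no incidence schedules in input")
  }
  dl <- duration_lookup(durations)
  regions <- unique(vapply(schedules, `[[`, character(1), "region"))
  rates <- lapply(stats::setNames(regions, regions), function(reg) {
    sch <- Filter(function(s) s$region == reg, schedules)
    stats::setNames(
      lapply(sch, harmonize, overlap = config$overlap,
             extend_oldest = config$extend_oldest),
      vapply(sch, `[[`, character(1), "sex"))
  })
  projections <- list()
  for (p in pyramids) {
    if (!p$region %in% regions || !p$year %in% config$years) next
    if (!p$region %in% names(dl)) {
      abort_config(sprintf("no median duration for region '%s'", p$region))
    }
    projections[[paste(p$region, p$year, sep = ".")]] <-
      project_cases(rates[[p$region]], p, dl[[p$region]])
  }
  if (length(projections) == 0L) {
    abort_config("no (region, year) overlap between schedules, pyramids and config$years")
  }
  projections
}

# human-readable country x year table, display-rounded with separators
format_case_lines <- function(tab, years) {
  fmt <- function(x) format(round_half_away(x), big.mark = ",",
                            scientific = FALSE, trim = TRUE)
  regions <- unique(tab$region)
  header <- c(sprintf("%-16s %s", "region",
                      paste(vapply(years, function(y)
                        sprintf("%10s %10s", paste0(y, " M"), paste0(y, " F")),
                        character(1)), collapse = " ")))
  body <- vapply(regions, function(r) {
    cells <- unlist(lapply(years, function(y) {
      m <- tab$cases[tab$region == r & tab$year == y & tab$sex == "male"]
      f <- tab$cases[tab$region == r & tab$year == y & tab$sex == "female"]
      c(if (length(m)) fmt(m) else "-", if (length(f)) fmt(f) else "-")
    }))
    sprintf("%-16s %s", r, paste(sprintf("%10s", cells), collapse = " "))
  }, character(1))
  tot <- vapply(years, function(y) {
    m <- sum(tab$cases[tab$year == y & tab$sex == "male"])
    f <- sum(tab$cases[tab$year == y & tab$sex == "female"])
    sprintf("%10s %10s", fmt(m), fmt(f))
  }, character(1))
  c(header, body,
    sprintf("%-16s %s", "total by sex", paste(tot, collapse = " ")),
    sprintf("%-16s %s", "overall total",
            paste(vapply(years, function(y)
              sprintf("%21s", fmt(sum(tab$cases[tab$year == y]))),
              character(1)), collapse = " ")))
}

# shared summary block: totals, development shares, percent changes
summarise_projection <- function(tab, hierarchy, years) {
  totals <- stats::aggregate(tab$cases, by = list(year = tab$year), sum)
  names(totals)[2L] <- "cases"
  sex_totals <- stats::aggregate(
    tab$cases, by = list(year = tab$year, sex = tab$sex), sum)
  names(sex_totals)[3L] <- "cases"
  out <- list(
    totals = totals,
    sex_totals = sex_totals)
  if (length(years) >= 2L) {
    y0 <- min(years); y1 <- max(years)
    pc <- percent_change(totals$cases[totals$year == y0],
                         totals$cases[totals$year == y1])
    out$percent_change <- list(from = y0, to = y1, raw = pc,
                               display = round_half_away(pc))
  }
  if (!is.null(hierarchy)) {
    dev <- aggregate_cases(tab, hierarchy, by = "development")
    dev$share_pct_display <- round_half_away(100 * dev$share)
    out$development <- dev
    if (length(years) >= 2L) {
      y0 <- min(years); y1 <- max(years)
      out$development_change <- lapply(
        stats::setNames(unique(dev$group), unique(dev$group)),
        function(g) {
          pc <- percent_change(dev$cases[dev$group == g & dev$year == y0],
                               dev$cases[dev$group == g & dev$year == y1])
          list(raw = pc, display = round_half_away(pc))
        })
    }
  }
  out
}

#' Run the per-region projection report
#'
#' Reads every input named in the config, harmonizes each region's
#' schedules, projects case counts for the configured years, and
#' writes three artefacts into `out_dir`: `cases.csv` (region, year,
#' sex, unrounded cases — the machine-readable layer), `summary.json`
#' (totals, development shares, percent changes, provenance) and
#' `case_table.txt` (the display-rounded human table).
#'
#' @param config A [run_config()] with `incidence`, `durations`,
#'   `population` and `hierarchy` paths.
#' @return Invisibly, a list with `projections`, `table`, `summary`
#'   and `files`.
#' @export
cmd_project <- function(config) {
  require_files(config, c("incidence", "durations", "population",
                          "hierarchy"))
  schedules <- read_incidence_table(config$incidence)
  durations <- read_durations(config$durations)
  pyramids <- read_idb_csv(config$population)
  hierarchy <- read_hierarchy(config$hierarchy)
  projections <- project_all(schedules, durations, pyramids, config)
  tab <- projection_table(projections)
  summary <- summarise_projection(tab, hierarchy, config$years)
  summary$provenance <- provenance(config, pyramids)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  files <- c(cases = file.path(config$out_dir, "cases.csv"),
             summary = file.path(config$out_dir, "summary.json"),
             table = file.path(config$out_dir, "case_table.txt"))
  utils::write.csv(tab, files[["cases"]], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(format_case_lines(tab, config$years), files[["table"]])
  say(config, "projected %d region-years -> %s",
      length(projections), config$out_dir)
  invisible(list(projections = projections, table = tab,
                 summary = summary, files = files))
}

#' Run the continental / global extrapolation report
#'
#' Builds one rate source per continent — a single study region's
#' harmonized schedule (assignment table) or a study-size-weighted
#' pool of several regions (membership table) — applies it to the
#' continent-level pyramids in the population input, and writes
#' `continent_cases.csv`, `global_summary.json` (world totals and
#' percent changes with provenance) and `continent_table.txt`.
#'
#' @param config A [run_config()] with `incidence`, `durations`,
#'   `population`, `assignment` and (if any continent is pooled)
#'   `membership` paths.  The population file must hold continent-level
#'   pyramids keyed by continent id.
#' @return Invisibly, a list with `projections`, `world`, `summary`
#'   and `files`.
#' @export
cmd_global <- function(config) {
  require_files(config, c("incidence", "durations", "population",
                          "assignment"))
  schedules <- read_incidence_table(config$incidence)
  durations <- read_durations(config$durations)
  pyramids <- read_idb_csv(config$population)
  assignment <- utils::read.csv(config$assignment, stringsAsFactors = FALSE)
  if (!all(c("continent", "source_region") %in% names(assignment))) {
    abort_format("assignment CSV needs columns continent,source_region")
  }
  membership <- if (!is.null(config$membership)) {
    require_files(config, "membership")
    m <- utils::read.csv(config$membership, stringsAsFactors = FALSE)
    if (!all(c("continent", "member_region") %in% names(m))) {
      abort_format("membership CSV needs columns continent,member_region")
    }
    m
  }
  overlap_cont <- intersect(assignment$continent,
                            if (is.null(membership)) character(0)
                            else membership$continent)
  if (length(overlap_cont)) {
    abort_config(sprintf(
      "continent(s) both assigned and pooled: %s",
      paste(overlap_cont, collapse = ", ")))
  }
  dl <- duration_lookup(durations)
  harmonized <- lapply(schedules, harmonize, overlap = config$overlap,
                       extend_oldest = config$extend_oldest)
  regions_of <- vapply(harmonized, `[[`, character(1), "region")
  sources <- list()
  for (i in seq_len(nrow(assignment))) {
    cont <- assignment$continent[i]; src <- assignment$source_region[i]
    hr <- harmonized[regions_of == src]
    if (length(hr) == 0L) {
      abort_config(sprintf("assignment source region '%s' has no schedule",
                           src))
    }
    if (!src %in% names(dl)) {
      abort_config(sprintf("no median duration for source region '%s'", src))
    }
    sources[[cont]] <- rate_source(
      stats::setNames(hr, vapply(hr, `[[`, character(1), "sex")),
      dl[[src]], cont)
  }
  if (!is.null(membership)) {
    for (cont in unique(membership$continent)) {
      members <- membership$member_region[membership$continent == cont]
      hr <- harmonized[regions_of %in% members]
      if (length(hr) == 0L) {
        abort_config(sprintf("pooled continent '%s' has no member schedules",
                             cont))
      }
      sources[[cont]] <- pool_schedules(hr, durations, cont)
    }
  }
  keep <- Filter(function(p) p$year %in% config$years, pyramids)
  global <- extrapolate_global(sources, keep)
  tab <- projection_table(global$projections)
  summary <- summarise_projection(tab, NULL, config$years)
  summary$world <- global$world
  summary$provenance <- provenance(config, pyramids)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  files <- c(cases = file.path(config$out_dir, "continent_cases.csv"),
             summary = file.path(config$out_dir, "global_summary.json"),
             table = file.path(config$out_dir, "continent_table.txt"))
  utils::write.csv(tab, files[["cases"]], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(format_case_lines(tab, config$years), files[["table"]])
  say(config, "extrapolated %d continent-years; world totals: %s",
      length(global$projections),
      paste(sprintf("%d: %.0f", global$world$year, global$world$cases),
            collapse = ", "))
  invisible(list(projections = global$projections, world = global$world,
                 summary = summary, files = files))
}

#' Validate inputs without computing anything
#'
#' Runs every reader named in the config and reports what was parsed;
#' any malformed input raises its typed error.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of parsed-object counts.
#' @export
cmd_validate <- function(config) {
  out <- list()
  if (!is.null(config$incidence)) {
    require_files(config, "incidence")
    out$schedules <- length(read_incidence_table(config$incidence))
  }
  if (!is.null(config$durations)) {
    require_files(config, "durations")
    out$durations <- length(read_durations(config$durations))
  }
  if (!is.null(config$population)) {
    require_files(config, "population")
    out$pyramids <- length(read_idb_csv(config$population))
  }
  if (!is.null(config$hierarchy)) {
    require_files(config, "hierarchy")
    out$regions <- nrow(read_hierarchy(config$hierarchy))
  }
  say(config, "inputs valid: %s",
      paste(sprintf("%s=%d", names(out), unlist(out)), collapse = ", "))
  invisible(out)
}

#' Generate and persist a synthetic world
#'
#' Convenience wrapper: builds a [synthetic_world_spec()] from the
#' config seed (other parameters at their defaults unless supplied),
#' generates the world and writes its four input CSVs plus the
#' embedded truth table into `out_dir`.
#'
#' @param config A [run_config()]; `seed` and `out_dir` are used.
#' @param ... Passed to [synthetic_world_spec()].
#' @return Invisibly, the [generate_world()] result with a `files`
#'   element added.
#' @export
cmd_synth <- function(config, ...) {
  world <- generate_world(synthetic_world_spec(seed = config$seed, ...))
  paths <- write_world(world, config$out_dir)
  truth_path <- file.path(config$out_dir, "truth.csv")
  utils::write.csv(world$truth, truth_path, row.names = FALSE, quote = FALSE)
  world$files <- c(paths, truth = truth_path)
  say(config, "synthetic world (seed %d) written to %s",
      config$seed, config$out_dir)
  invisible(world)
}
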