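#' Pool harmonized incidence schedules by study size
#'
#' When several studies represent one continent, their rates are
#' combined as a convex mixture weighted by catchment population:
#' `weight_i = study_population_i / sum(study_population)`, pooled band
#' rate = `sum(weight_i * rate_i)` per sex, and the pooled median
#' duration uses the same weights.  Every pooled band rate therefore
#' lies between the smallest and largest component rate for that band,
#' and rescaling all catchments by a constant leaves the pool
#' unchanged.
#'
#' @param schedules List of [harmonized_rates()] objects (both sexes;
#'   each region must appear with the same sexes and carry a positive
#'   `study_population`).
#' @param durations List of [duration_model()]s covering every pooled
#'   region.
#' @param continent Identifier for the pooled schedule.
#' @return A `pooled_schedule`: `continent`, `rates` (named list of
#'   `harmonized_rates` per sex, region set to `continent`), `weights`
#'   (data frame `region`, `weight`, summing to 1), `duration` (pooled
#'   years) and `study_population` (total catchment).
#' @examples
#' # two studies, rates 1 and 3 per 100k, catchments 1e6 and 3e6 -> 2.5
#' @export
pool_schedules <- function(schedules, durations, continent) {
  if (length(schedules) == 0L) abort_config("no schedules to pool")
  regions <- vapply(schedules, `[[`, character(1), "region")
  sexes <- vapply(schedules, `[[`, character(1), "sex")
  sp <- vapply(schedules, `[[`, numeric(1), "study_population")
  reg_sp <- tapply(sp, regions, unique, simplify = FALSE)
  if (any(lengths(reg_sp) != 1L)) {
    abort_config("inconsistent study_population within a region")
  }
  reg_sp <- vapply(reg_sp, `[[`, numeric(1), 1L)
  if (any(!is.finite(reg_sp)) || any(reg_sp <= 0)) {
    abort_config("every pooled schedule needs a positive study_population")
  }
  by_sex <- split(seq_along(schedules), sexes)
  reg_sets <- lapply(by_sex, function(i) sort(regions[i]))
  if (length(unique(reg_sets)) != 1L) {
    abort_config("each sex must be supplied by the same set of regions")
  }
  w <- reg_sp / sum(reg_sp)
  dl <- duration_lookup(durations)
  missing_d <- setdiff(names(w), names(dl))
  if (length(missing_d)) {
    abort_config(sprintf("no duration for pooled region(s): %s",
                         paste(missing_d, collapse = ", ")))
  }
  pooled_rates <- lapply(by_sex, function(i) {
    r <- vapply(schedules[i], `[[`, numeric(21), "rates")  # 21 x n
    harmonized_rates(continent, sexes[i[1L]],
                     drop(r %*% w[regions[i]]),
                     study_population = sum(reg_sp))
  })
  structure(
    list(continent = as.character(continent),
         rates = pooled_rates,
         weights = data.frame(region = names(w), weight = unname(w)),
         duration = sum(w * dl[names(w)]),
         study_population = sum(reg_sp)),
    class = "pooled_schedule"
  )
}

#' @export
print.pooled_schedule <- function(x, ...) {
  cat(sprintf("<pooled_schedule> %s: %d component(s), pooled duration %.2f y\n",
              x$continent, nrow(x$weights), x$duration))
  print(x$weights)
  invisible(x)
}

#' Bundle single-region rates as a continental rate source
#'
#' Wraps one region's harmonized rates and duration in the same shape
#' as a [pool_schedules()] result, relabelled to the continent, so
#' [extrapolate_global()] treats pooled and single-study continents
#' uniformly.
#'
#' @param rates Named list of [harmonized_rates()] per sex.
#' @param duration A [duration_model()] or bare years.
#' @param continent Continent identifier.
#' @return A `pooled_schedule` with one component of weight 1.
#' @export
rate_source <- function(rates, duration, continent) {
  D <- if (inherits(duration, "duration_model")) duration$median_duration
       else as.numeric(duration)
  if (!is.finite(D) || D <= 0) abort_config("duration must be > 0")
  region <- rates[[1L]]$region
  relabelled <- lapply(rates, function(hr) {
    harmonized_rates(continent, hr$sex, hr$rates,
                     study_population = hr$study_population)
  })
  structure(
    list(continent = as.character(continent), rates = relabelled,
         weights = data.frame(region = region, weight = 1),
         duration = D,
         study_population = rates[[1L]]$study_population),
    class = "pooled_schedule"
  )
}

#' Extrapolate case numbers to continents and the globe
#'
#' Applies each continent's assigned rate source (a single study
#' region's schedule, or a study-size-weighted pool) to that
#' continent's population pyramids, and sums the per-continent
#' projections into world totals per year.
#'
#' @param rate_sources Named list, continent id -> `pooled_schedule`
#'   (from [pool_schedules()] or [rate_source()]).
#' @param pyramids List of continent-level [population_pyramid()]s
#'   (several years per continent allowed).  Every pyramid's region
#'   must have a rate source.
#' @return List with `projections` (list of `case_projection`, one per
#'   pyramid) and `world` (data frame `year`, `cases`).
#' @export
extrapolate_global <- function(rate_sources, pyramids) {
  projections <- lapply(pyramids, function(p) {
    src <- rate_sources[[p$region]]
    if (is.null(src)) {
      abort_config(sprintf("no rate source assigned to continent '%s'",
                           p$region))
    }
    project_cases(src$rates, p, src$duration)
  })
  tab <- projection_table(projections)
  world <- stats::aggregate(tab$cases, by = list(year = tab$year), FUN = sum)
  names(world)[2L] <- "cases"
  list(projections = projections, world = world)
}
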