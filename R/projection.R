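#' Project expected case counts for one region-year
#'
#' The central computation: under the stationary approximation, point
#' prevalence in an age/sex stratum is incidence x median disease
#' duration, so the expected case count in grid band b for sex s is
#'
#'   cases(s, b) = rate(s, b) / 100000 x population(s, b) x D
#'
#' with D the region's median duration in years.  No rounding is
#' applied anywhere in the engine; rounding is a display concern (see
#' [round_half_away()] and the report layer), because rounded cells do
#' not in general sum to rounded totals.
#'
#' @param rates Named list of [harmonized_rates()] objects, one per sex
#'   present in `pyramid` (names `"male"`, `"female"`).
#' @param pyramid A [population_pyramid()] for the same region.
#' @param duration A [duration_model()] for the same region, or a bare
#'   positive number of years.
#' @return A `case_projection`: region, year, `cases` (21 x sexes
#'   matrix), `cases_by_sex` (column sums) and `total`.
#' @examples
#' grid <- standard_age_grid()
#' pop <- matrix(0, 21, 1, dimnames = list(grid$label, "male"))
#' pop["60-64", ] <- 1e5
#' pyr <- population_pyramid("Toy", 2015, pop)
#' r <- stats::setNames(numeric(21), grid$label); r["60-64"] <- 2
#' project_cases(list(male = harmonized_rates("Toy", "male", r)), pyr, 3)
#' @export
project_cases <- function(rates, pyramid, duration) {
  sexes <- colnames(pyramid$counts)
  if (!all(sexes %in% names(rates))) {
    abort_config(sprintf(
      "region '%s': no harmonized rates supplied for sex(es): %s",
      pyramid$region,
      paste(setdiff(sexes, names(rates)), collapse = ", ")))
  }
  if (inherits(duration, "duration_model")) {
    if (!identical(duration$region, pyramid$region)) {
      abort_config(sprintf(
        "duration region '%s' does not match pyramid region '%s'",
        duration$region, pyramid$region))
    }
    D <- duration$median_duration
  } else {
    D <- as.numeric(duration)
    if (!is.finite(D) || D <= 0) abort_config("duration must be > 0")
  }
  cases <- vapply(sexes, function(s) {
    hr <- rates[[s]]
    if (!identical(hr$region, pyramid$region)) {
      abort_config(sprintf(
        "rates region '%s' does not match pyramid region '%s'",
        hr$region, pyramid$region))
    }
    if (!identical(hr$sex, s)) {
      abort_config(sprintf(
        "region '%s': rates object for sex '%s' is labelled '%s'",
        pyramid$region, s, hr$sex))
    }
    hr$rates / 1e5 * pyramid$counts[, s] * D
  }, numeric(nrow(pyramid$counts)))
  cases <- matrix(cases, nrow = nrow(pyramid$counts),
                  dimnames = list(rownames(pyramid$counts), sexes))
  structure(
    list(region = pyramid$region, year = pyramid$year,
         cases = cases, cases_by_sex = colSums(cases),
         total = sum(cases)),
    class = "case_projection"
  )
}

#' @export
print.case_projection <- function(x, ...) {
  cat(sprintf("<case_projection> %s, %d: %s cases (%s)\n",
              x$region, x$year,
              format(round(x$total, 1), big.mark = ","),
              paste(sprintf("%s %.1f", names(x$cases_by_sex),
                            x$cases_by_sex), collapse = ", ")))
  invisible(x)
}

#' Tidy a list of case projections
#'
#' @param projections A `case_projection` or list of them.
#' @return Data frame with columns `region`, `year`, `sex`, `cases`
#'   (unrounded), one row per region-year-sex.
#' @export
projection_table <- function(projections) {
  if (inherits(projections, "case_projection")) {
    projections <- list(projections)
  }
  do.call(rbind, lapply(projections, function(p) {
    data.frame(region = p$region, year = p$year,
               sex = names(p$cases_by_sex),
               cases = unname(p$cases_by_sex),
               stringsAsFactors = FALSE)
  }))
}

#' Percent change
#'
#' `100 * (after - before) / before`.  The engine keeps full precision;
#' reports round to the nearest integer percent, half away from zero.
#'
#' @param before Baseline value(s), all > 0.
#' @param after Comparison value(s), >= 0.
#' @return Percent change, unrounded.
#' @examples
#' percent_change(222801, 376674)  # 69.06...
#' @export
percent_change <- function(before, after) {
  before <- as.numeric(before); after <- as.numeric(after)
  if (any(!is.finite(before)) || any(before <= 0)) {
    abort_domain("percent_change: 'before' must be > 0")
  }
  100 * (after - before) / before
}

#' Round half away from zero
#'
#' Display rounding used in report tables (0.5 -> 1, -0.5 -> -1),
#' unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits (default 0).
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Construct a region hierarchy
#'
#' Classifies every projected region into a continent and a
#' developed/developing stratum; each region must be classified exactly
#' once.
#'
#' @param df Data frame with columns `region`, `continent` (one of
#'   Africa, NorthAmerica, SouthAmerica, Asia, Europe, Oceania) and
#'   `development` (`developed` / `developing`).
#' @return A validated `region_hierarchy` (the data frame, classed).
#' @export
region_hierarchy <- function(df) {
  need <- c("region", "continent", "development")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort_format(sprintf("missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$region)) {
    abort_validation(sprintf(
      "region(s) classified more than once: %s",
      paste(unique(df$region[duplicated(df$region)]), collapse = ", ")))
  }
  continents <- c("Africa", "NorthAmerica", "SouthAmerica", "Asia",
                  "Europe", "Oceania")
  bad <- setdiff(df$continent, continents)
  if (length(bad)) {
    abort_validation(sprintf("unknown continent(s): %s",
                             paste(bad, collapse = ", ")))
  }
  bad <- setdiff(df$development, c("developed", "developing"))
  if (length(bad)) {
    abort_validation(sprintf("unknown development label(s): %s",
                             paste(bad, collapse = ", ")))
  }
  structure(df[, need], class = c("region_hierarchy", "data.frame"))
}

#' Read a region-classification CSV
#'
#' @param path CSV with header `region,continent,development`.
#' @return A [region_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  region_hierarchy(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Aggregate case counts by development stratum, continent, or overall
#'
#' Sums unrounded per-region cases within each group and year and
#' attaches each group's share of the all-group total for that year.
#'
#' @param cases Either a list of `case_projection` objects or a tidy
#'   data frame with columns `region`, `year`, `cases` (a `sex` column,
#'   if present, is summed over) — so published case tables can be fed
#'   through the same aggregation path as model output.
#' @param hierarchy A [region_hierarchy()] classifying every region.
#' @param by `"development"`, `"continent"` or `"all"`.
#' @return Data frame `group`, `year`, `cases`, `share` (shares sum to
#'   1 per year).
#' @export
aggregate_cases <- function(cases, hierarchy,
                            by = c("development", "continent", "all")) {
  by <- match.arg(by)
  if (!is.data.frame(cases)) cases <- projection_table(cases)
  unclassified <- setdiff(unique(cases$region), hierarchy$region)
  if (length(unclassified)) {
    abort_config(sprintf("unclassified region(s): %s",
                         paste(unclassified, collapse = ", ")))
  }
  group <- if (by == "all") rep("all", nrow(cases)) else
    hierarchy[[by]][match(cases$region, hierarchy$region)]
  agg <- stats::aggregate(cases$cases,
                          by = list(group = group, year = cases$year),
                          FUN = sum)
  names(agg)[3L] <- "cases"
  totals <- stats::ave(agg$cases, agg$year, FUN = sum)
  agg$share <- agg$cases / totals
  agg[order(agg$year, agg$group), ]
}

#' Median population age of a pyramid
#'
#' Linearly interpolated within the 5-year band containing the 50th
#' percentile, assuming a uniform age distribution within bands; the
#' open 100+ band is treated as width 5 for interpolation.
#'
#' @param pyramid A [population_pyramid()]; sexes are combined.
#' @return Median age in years.
#' @export
median_population_age <- function(pyramid) {
  counts <- rowSums(pyramid$counts)
  total <- sum(counts)
  if (!is.finite(total) || total <= 0) {
    abort_domain(sprintf("region '%s', year %s: empty pyramid",
                         pyramid$region, pyramid$year))
  }
  grid <- standard_age_grid()
  cum <- cumsum(counts)
  half <- total / 2
  k <- which(cum >= half)[1L]
  before <- if (k == 1L) 0 else cum[k - 1L]
  unname(grid$age_lo[k] + 5 * (half - before) / counts[k])
}

#' Correlation between case growth and population ageing
#'
#' Pearson correlation across regions of the percent increase in
#' projected cases against the percent increase in median population
#' age over the same horizon.
#'
#' @param case_changes,age_changes Named numeric vectors of percent
#'   changes; names are region ids and are matched (>= 3 regions must
#'   carry both values).
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
ageing_correlation <- function(case_changes, age_changes) {
  common <- intersect(names(case_changes), names(age_changes))
  if (length(common) < 3L) {
    abort_domain("need at least 3 regions with both percent changes")
  }
  x <- case_changes[common]; y <- age_changes[common]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort_domain("zero variance in percent changes; correlation undefined")
  }
  stats::cor(x, y)
}
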