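#' Bundled reference estimates of projected ALS case numbers
#'
#' Published reference estimates of projected ALS case numbers by
#' country, year (2015 and 2040) and sex for the ten regions with
#' usable incidence studies, together with the reported sex and
#' overall totals (ten-region and global).  These are display-rounded
#' integers as printed in the source summary table, so per-cell sums
#' can differ from the reported totals by a few cases; the package's
#' aggregation layer is exercised against both.
#'
#' @return `reference_case_table()`: data frame `region`, `year`,
#'   `sex`, `cases`.  `reference_totals()`: data frame `scope`
#'   (`ten_region`/`global`), `year`, `group` (`male`/`female`/
#'   `total`), `cases`.  `reference_hierarchy()`: the matching
#'   [region_hierarchy()] (continent and developed/developing labels).
#' @examples
#' tab <- reference_case_table()
#' aggregate_cases(tab, reference_hierarchy(), by = "development")
#' @export
reference_case_table <- function() {
  utils::read.csv(
    system.file("extdata", "als_projected_cases_2015_2040.csv",
                package = "alscast", mustWork = TRUE),
    stringsAsFactors = FALSE)
}

#' @rdname reference_case_table
#' @export
reference_totals <- function() {
  utils::read.csv(
    system.file("extdata", "als_reported_totals.csv",
                package = "alscast", mustWork = TRUE),
    stringsAsFactors = FALSE)
}

#' @rdname reference_case_table
#' @export
reference_hierarchy <- function() {
  read_hierarchy(
    system.file("extdata", "region_classification.csv",
                package = "alscast", mustWork = TRUE))
}

#' Default continental rate-source tables
#'
#' The standard assignment of study regions to continents for the
#' global extrapolation: single-study continents (United States to
#' North America, Uruguay to South America, Libya to Africa, New
#' Zealand to Oceania, the EU28 pooled schedule alone to Europe —
#' Serbia is carried in the ten-region analysis but not in the
#' continental extrapolation) and the pooled Asia membership (China,
#' Japan, Taiwan, Iran, weighted by study catchment).  Both are plain
#' CSVs, so alternative assignments — e.g. moving Central America out
#' of North America, or adding Serbia to Europe — are one edit away.
#'
#' @param which `"assignment"` (continent, source_region) or
#'   `"pooling"` (continent, member_region).
#' @return The file path of the bundled CSV, suitable for
#'   [run_config()]'s `assignment`/`membership` fields.
#' @export
default_continent_table <- function(which = c("assignment", "pooling")) {
  which <- match.arg(which)
  system.file("extdata", paste0("continent_", which, ".csv"),
              package = "alscast", mustWork = TRUE)
}
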