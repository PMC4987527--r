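#' Harmonize a study incidence schedule onto the standard 5-year grid
#'
#' Published incidence studies rarely report on the demographic 5-year
#' grid; a study band such as 18-24 straddles the grid bands 15-19 and
#' 20-24.  Harmonization produces an effective rate for every standard
#' band so the projection can multiply rates against IDB pyramids
#' band-by-band.
#'
#' Under the default `overlap = "proportional"` rule a standard band
#' fully inside one study band inherits that band's rate; a partially
#' overlapped standard band gets `rate * overlap_years / 5`, assuming a
#' uniform age distribution within the band (ages are integer years;
#' the open 100+ band is treated as 100-104).  `overlap = "full"`
#' instead carries the full rate of the study band covering the most
#' years of the standard band (ties go to the younger study band), a
#' sensitivity-check variant.  Standard bands touched by no study band
#' get rate 0, so ages younger than the youngest study band contribute
#' no cases; an open-ended study band covers every older standard band
#' including 100+.
#'
#' @param schedule An [incidence_schedule()].
#' @param overlap `"proportional"` (default) or `"full"`.
#' @param extend_oldest If `TRUE` and the oldest study band is bounded,
#'   its rate is carried upward to all older standard bands (elderly
#'   incidence is under-ascertained in most registries; this switch
#'   quantifies the impact of assuming the terminal rate persists).
#' @return A `harmonized_rates` object: region, sex, the study
#'   catchment size, and a 21-vector of effective rates per 100,000
#'   person-years named by grid band label.
#' @examples
#' s <- incidence_schedule("Toy", "male",
#'   data.frame(age_lo = 18, age_hi = 24, rate = 5), 1e6)
#' harmonize(s)$rates[c("15-19", "20-24")]
#' @export
harmonize <- function(schedule,
                      overlap = c("proportional", "full"),
                      extend_oldest = FALSE) {
  overlap <- match.arg(overlap)
  validate_incidence_schedule(schedule)
  grid <- standard_age_grid()
  sb <- schedule$bands
  s_lo <- sb$age_lo
  s_hi <- ifelse(is.na(sb$age_hi), Inf, sb$age_hi)
  if (extend_oldest && is.finite(s_hi[length(s_hi)])) {
    s_hi[length(s_hi)] <- Inf
  }
  g_lo <- grid$age_lo
  g_hi <- ifelse(is.na(grid$age_hi), grid$age_lo + 4, grid$age_hi)
  rates <- vapply(seq_len(nrow(grid)), function(g) {
    ov <- pmax(0, pmin(s_hi, g_hi[g]) - pmax(s_lo, g_lo[g]) + 1)
    if (all(ov == 0)) return(0)
    if (overlap == "proportional") {
      sum(sb$rate * ov) / (g_hi[g] - g_lo[g] + 1)
    } else {
      sb$rate[which.max(ov)]
    }
  }, numeric(1))
  harmonized_rates(schedule$region, schedule$sex,
                   stats::setNames(rates, grid$label),
                   study_population = schedule$study_population)
}

#' Construct harmonized rates directly
#'
#' @param region,sex As in [incidence_schedule()].
#' @param rates Numeric 21-vector of effective rates per 100,000
#'   person-years, named by [standard_age_grid()] labels, all >= 0.
#' @param study_population Catchment size carried along for pooling.
#' @return A `harmonized_rates` object.
#' @export
harmonized_rates <- function(region, sex, rates, study_population = NA_real_) {
  grid <- standard_age_grid()
  if (is.null(names(rates)) || !setequal(names(rates), grid$label)) {
    abort_validation(sprintf(
      "region '%s', sex '%s': rates must be named by the standard grid",
      region, sex))
  }
  rates <- rates[grid$label]
  if (any(!is.finite(rates)) || any(rates < 0)) {
    abort_validation(sprintf(
      "region '%s', sex '%s': negative or non-finite harmonized rate",
      region, sex))
  }
  structure(
    list(region = as.character(region), sex = as.character(sex),
         rates = rates, study_population = as.numeric(study_population)),
    class = "harmonized_rates"
  )
}

#' @export
print.harmonized_rates <- function(x, ...) {
  cat(sprintf("<harmonized_rates> %s / %s\n", x$region, x$sex))
  nz <- x$rates[x$rates > 0]
  if (length(nz)) print(round(nz, 4)) else cat("  (all zero)\n")
  invisible(x)
}
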