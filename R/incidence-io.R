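#' Construct an incidence schedule
#'
#' An incidence schedule holds the age-specific incidence rates of one
#' study region for one sex, together with the study metadata needed
#' downstream: the catchment population (used as the pooling weight when
#' several studies represent one continent) and the case definition
#' (ALS, or the broader motor neuron disease class used by some older
#' studies; carried as metadata only, never used to adjust rates).
#'
#' @param region Region identifier (character scalar).
#' @param sex `"male"` or `"female"`.  Combined-sex schedules are
#'   rejected: the projection is sex-specific throughout.
#' @param bands Data frame with columns `age_lo`, `age_hi` (`NA` for an
#'   open-ended oldest band such as 75+) and `rate` (new cases per
#'   100,000 person-years).
#' @param study_population Persons covered by the source study (> 0).
#' @param case_definition `"ALS"` or `"MND"`.
#' @param study_period Free-text year range of the source study.
#' @return An object of class `incidence_schedule`.
#' @examples
#' incidence_schedule("Toy", "male",
#'   data.frame(age_lo = 60, age_hi = 69, rate = 8),
#'   study_population = 1e6)
#' @export
incidence_schedule <- function(region, sex, bands, study_population,
                               case_definition = "ALS",
                               study_period = NA_character_) {
  obj <- structure(
    list(
      region = as.character(region),
      sex = as.character(sex),
      bands = bands[order(bands$age_lo), c("age_lo", "age_hi", "rate"),
                    drop = FALSE],
      study_population = as.numeric(study_population),
      case_definition = as.character(case_definition),
      study_period = as.character(study_period)
    ),
    class = "incidence_schedule"
  )
  rownames(obj$bands) <- NULL
  validate_incidence_schedule(obj)
  obj
}

#' Validate an incidence schedule
#'
#' Checks every type invariant: sex strictly male/female, rates
#' non-negative, bands sorted and pairwise non-overlapping, at most one
#' open-ended band and only as the oldest, positive catchment size.
#'
#' @param x An `incidence_schedule`.
#' @return `x`, invisibly, if valid; otherwise a classed validation
#'   error naming the offending region/sex/band.
#' @export
validate_incidence_schedule <- function(x) {
  who <- sprintf("region '%s', sex '%s'", x$region, x$sex)
  if (!x$sex %in% c("male", "female")) {
    abort_validation(sprintf(
      "%s: sex must be 'male' or 'female' (combined-sex rows are not accepted)",
      who))
  }
  if (!x$case_definition %in% c("ALS", "MND")) {
    abort_validation(sprintf("%s: case_definition must be 'ALS' or 'MND'", who))
  }
  if (!is.finite(x$study_population) || x$study_population <= 0) {
    abort_validation(sprintf("%s: study_population must be > 0", who))
  }
  b <- x$bands
  if (nrow(b) == 0L) abort_validation(sprintf("%s: no age bands", who))
  if (any(!is.finite(b$rate) | b$rate < 0)) {
    abort_validation(sprintf("%s: negative or non-finite rate in band %s",
                             who, band_label(b$age_lo, b$age_hi)[
                               which(!is.finite(b$rate) | b$rate < 0)[1L]]))
  }
  if (any(b$age_lo < 0)) abort_validation(sprintf("%s: age_lo < 0", who))
  open <- is.na(b$age_hi)
  if (sum(open) > 1L) {
    abort_validation(sprintf("%s: more than one open-ended band", who))
  }
  if (any(open) && which(open) != nrow(b)) {
    abort_validation(sprintf("%s: open-ended band must be the oldest", who))
  }
  if (any(!open & b$age_hi < b$age_lo)) {
    abort_validation(sprintf("%s: band with age_hi < age_lo", who))
  }
  if (nrow(b) > 1L) {
    # bands are closed integer intervals; adjacent bands must not share years
    hi <- b$age_hi[-nrow(b)]
    lo <- b$age_lo[-1L]
    if (any(is.na(hi)) || any(lo <= hi)) {
      k <- if (any(is.na(hi))) which(is.na(hi))[1L] else which(lo <= hi)[1L]
      abort_validation(sprintf(
        "%s: overlapping age bands %s and %s", who,
        band_label(b$age_lo[k], b$age_hi[k]),
        band_label(b$age_lo[k + 1L], b$age_hi[k + 1L])))
    }
  }
  invisible(x)
}

#' @export
print.incidence_schedule <- function(x, ...) {
  cat(sprintf("<incidence_schedule> %s / %s (%s, catchment %s)\n",
              x$region, x$sex, x$case_definition,
              format(x$study_population, big.mark = ",")))
  print(transform(x$bands, band = band_label(age_lo, age_hi))[
    , c("band", "rate")])
  invisible(x)
}

incidence_columns <- c("region", "sex", "age_lo", "age_hi",
                       "rate_per_100k", "study_population",
                       "case_definition")

#' Read an incidence-schedule CSV
#'
#' Expects the header
#' `region,sex,age_lo,age_hi,rate_per_100k,study_population,case_definition`
#' (optionally `study_period`), one row per age band, `age_hi` blank or
#' `"+"`-suffixed for an open-ended band.  Rows are grouped into one
#' schedule per (region, sex) and fully validated.
#'
#' @param path CSV file path.
#' @return A list of [incidence_schedule()] objects.
#' @seealso [write_incidence_table()] for the exact inverse.
#' @export
read_incidence_table <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(incidence_columns, names(df))
  if (length(missing)) {
    abort_format(sprintf("missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) return(list())
  df$age_lo <- suppressWarnings(as.numeric(df$age_lo))
  df$age_hi <- parse_age_hi(df$age_hi)
  df$rate <- suppressWarnings(as.numeric(df$rate_per_100k))
  df$study_population <- suppressWarnings(as.numeric(df$study_population))
  if (any(is.na(df$age_lo))) abort_format("unparseable age_lo value")
  if (any(is.na(df$rate))) abort_format("unparseable rate_per_100k value")
  if (!"study_period" %in% names(df)) df$study_period <- NA_character_
  key <- paste(df$region, df$sex, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    incidence_schedule(
      region = g$region[1L], sex = g$sex[1L],
      bands = data.frame(age_lo = g$age_lo, age_hi = g$age_hi,
                         rate = g$rate),
      study_population = g$study_population[1L],
      case_definition = g$case_definition[1L],
      study_period = g$study_period[1L]
    )
  }) |> unname()
}

#' Write incidence schedules to CSV
#'
#' Emits the dialect that [read_incidence_table()] inverts exactly; an
#' empty schedule list produces a header-only file.
#'
#' @param schedules List of `incidence_schedule` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_incidence_table <- function(schedules, path) {
  rows <- lapply(schedules, function(s) {
    validate_incidence_schedule(s)
    data.frame(
      region = s$region, sex = s$sex,
      age_lo = s$bands$age_lo,
      age_hi = ifelse(is.na(s$bands$age_hi), "",
                      as.character(s$bands$age_hi)),
      rate_per_100k = s$bands$rate,
      study_population = s$study_population,
      case_definition = s$case_definition,
      study_period = s$study_period,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(
      rep(list(character(0)), length(incidence_columns) + 1L),
      c(incidence_columns, "study_period")))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a median-duration model
#'
#' @param region Region identifier.
#' @param median_duration Median disease duration in years (> 0, finite).
#' @return A `duration_model` object.
#' @export
duration_model <- function(region, median_duration) {
  median_duration <- as.numeric(median_duration)
  if (length(median_duration) != 1L || !is.finite(median_duration) ||
      median_duration <= 0) {
    abort_validation(sprintf(
      "region '%s': median_duration must be a finite value > 0", region))
  }
  structure(list(region = as.character(region),
                 median_duration = median_duration),
            class = "duration_model")
}

#' Read a median-duration CSV
#'
#' Expects header `region,median_duration_years`, one row per region.
#'
#' @param path CSV file path.
#' @return A list of [duration_model()] objects.
#' @export
read_durations <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("region", "median_duration_years"), names(df))
  if (length(missing)) {
    abort_format(sprintf("missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  Map(duration_model, df$region, df$median_duration_years) |> unname()
}

#' Write a median-duration CSV
#'
#' @param durations List of `duration_model` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_durations <- function(durations, path) {
  out <- data.frame(
    region = vapply(durations, `[[`, character(1), "region"),
    median_duration_years = vapply(durations, `[[`, numeric(1),
                                   "median_duration")
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# durations list -> named numeric lookup
duration_lookup <- function(durations) {
  stats::setNames(
    vapply(durations, `[[`, numeric(1), "median_duration"),
    vapply(durations, `[[`, character(1), "region")
  )
}
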