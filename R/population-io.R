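#' Construct a population pyramid
#'
#' Population counts for one region-year on the standard 5-year grid
#' (see [standard_age_grid()]).  Counts may be real-valued: official
#' International Data Base (IDB) exports supply integers, synthetic
#' pyramids need not.
#'
#' @param region Region identifier.
#' @param year Calendar year.
#' @param counts Numeric matrix, 21 rows (named by grid band label) and
#'   one column per sex present (`"male"`, `"female"`), all entries >= 0.
#' @param vintage Optional data-vintage string (e.g. IDB release date);
#'   propagated into reports.
#' @return A `population_pyramid` object.
#' @export
population_pyramid <- function(region, year, counts, vintage = NA_character_) {
  grid <- standard_age_grid()
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || !identical(rownames(counts), grid$label)) {
    # accept any row order but require exactly the standard band set
    if (is.null(rownames(counts)) ||
        !setequal(rownames(counts), grid$label) ||
        anyDuplicated(rownames(counts))) {
      missing <- setdiff(grid$label, rownames(counts))
      abort_validation(sprintf(
        "region '%s', year %s: counts must cover exactly the standard grid%s",
        region, year,
        if (length(missing)) paste0("; missing band(s): ",
                                    paste(missing, collapse = ", ")) else ""))
    }
    counts <- counts[grid$label, , drop = FALSE]
  }
  bad_sex <- setdiff(colnames(counts), c("male", "female"))
  if (length(bad_sex) || is.null(colnames(counts))) {
    abort_validation(sprintf("region '%s', year %s: unknown sex column(s): %s",
                             region, year, paste(bad_sex, collapse = ", ")))
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort_validation(sprintf(
      "region '%s', year %s: negative or non-finite population count",
      region, year))
  }
  structure(
    list(region = as.character(region), year = as.integer(year),
         counts = counts, vintage = as.character(vintage)),
    class = "population_pyramid"
  )
}

#' @export
print.population_pyramid <- function(x, ...) {
  cat(sprintf("<population_pyramid> %s, %d (total %s)\n",
              x$region, x$year, format(round(sum(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Read an IDB-style population CSV
#'
#' Accepts two dialects: `country,year,sex,age_lo,age_hi,population`
#' with `age_hi` blank for the open 100+ band, or the export dialect
#' with a single `GROUP` label column (`"0-4"`, ..., `"100+"`).  Each
#' (country, year) must supply the complete 21-band grid for every sex
#' present; gaps are an error, never imputed.
#'
#' @param path CSV file path.
#' @param vintage Optional vintage string attached to every pyramid.
#' @return A list of [population_pyramid()] objects, one per
#'   (country, year).
#' @export
read_idb_csv <- function(path, vintage = NA_character_) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  base_cols <- c("country", "year", "sex", "population")
  missing <- setdiff(base_cols, names(df))
  if (length(missing)) {
    abort_format(sprintf("missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if ("GROUP" %in% names(df)) {
    bounds <- parse_band_label(df$GROUP)
    df$age_lo <- bounds$age_lo
    df$age_hi <- bounds$age_hi
  } else if (all(c("age_lo", "age_hi") %in% names(df))) {
    df$age_lo <- suppressWarnings(as.numeric(df$age_lo))
    df$age_hi <- parse_age_hi(df$age_hi)
    if (any(is.na(df$age_lo))) abort_format("unparseable age_lo value")
  } else {
    abort_format("need either age_lo/age_hi columns or a GROUP label column")
  }
  df$population <- suppressWarnings(as.numeric(df$population))
  if (any(is.na(df$population))) abort_format("unparseable population value")
  if (any(df$population < 0)) {
    abort_validation("negative population count")
  }
  grid <- standard_age_grid()
  df$label <- band_label(df$age_lo, df$age_hi)
  bad <- setdiff(unique(df$label), grid$label)
  if (length(bad)) {
    abort_format(sprintf("non-standard age band(s): %s",
                         paste(bad, collapse = ", ")))
  }
  key <- paste(df$country, df$year, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    sexes <- unique(g$sex)
    counts <- vapply(sexes, function(s) {
      gs <- g[g$sex == s, ]
      missing <- setdiff(grid$label, gs$label)
      if (length(missing) || anyDuplicated(gs$label)) {
        abort_format(sprintf(
          "country '%s', year %s, sex '%s': %s",
          g$country[1L], g$year[1L], s,
          if (length(missing))
            paste0("missing band(s): ", paste(missing, collapse = ", "))
          else "duplicated band rows"))
      }
      stats::setNames(gs$population, gs$label)[grid$label]
    }, numeric(nrow(grid)))
    rownames(counts) <- grid$label
    population_pyramid(g$country[1L], as.integer(g$year[1L]), counts,
                       vintage = vintage)
  }) |> unname()
}

#' Write population pyramids to an IDB-style CSV
#'
#' Emits the `country,year,sex,age_lo,age_hi,population` dialect that
#' [read_idb_csv()] inverts exactly.
#'
#' @param pyramids List of `population_pyramid` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_idb_csv <- function(pyramids, path) {
  grid <- standard_age_grid()
  rows <- lapply(pyramids, function(p) {
    do.call(rbind, lapply(colnames(p$counts), function(s) {
      data.frame(country = p$region, year = p$year, sex = s,
                 age_lo = grid$age_lo,
                 age_hi = ifelse(is.na(grid$age_hi), "",
                                 as.character(grid$age_hi)),
                 population = unname(p$counts[, s]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(country = character(0), year = integer(0), sex = character(0),
               age_lo = numeric(0), age_hi = character(0),
               population = numeric(0))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

idb_cache_path <- function(cache_dir, countries, years) {
  file.path(cache_dir, sprintf(
    "idb_%s_%s.json",
    paste(sort(countries), collapse = "-"),
    paste(range(years), collapse = "-")))
}

#' Fetch population pyramids from the Census IDB, with caching
#'
#' Retrieves 5-year-band population projections for the requested
#' countries and years from the United States Census Bureau
#' International Data Base.  The raw payload (an IDB-style CSV plus
#' retrieval metadata: timestamp, source URL, vintage) is cached as one
#' JSON file per request under `cache_dir`; warm-cache calls touch no
#' network, so offline reruns are reproducible and reports can print
#' the vintage actually used.
#'
#' @param countries Character vector of country identifiers.
#' @param years Integer vector of calendar years.
#' @param cache_dir Writable cache directory.
#' @param base_url API endpoint (overridable for testing/mirrors).
#' @return A list of [population_pyramid()] objects, identical to
#'   [read_idb_csv()] applied to the cached payload.
#' @export
fetch_idb <- function(countries, years, cache_dir,
                      base_url = "https://api.census.gov/data/timeseries/idb/5year") {
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  cache <- idb_cache_path(cache_dir, countries, years)
  if (!file.exists(cache)) {
    url <- sprintf("%s?get=POP,AGE_LO,AGE_HI,SEX&GENC=%s&YR=%s",
                   base_url, paste(countries, collapse = ","),
                   paste(years, collapse = ","))
    tmp <- tempfile(fileext = ".json")
    ok <- tryCatch(
      utils::download.file(url, tmp, quiet = TRUE) == 0L,
      error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) {
      abort_retrieval(sprintf(
        "could not retrieve IDB data for %s (%s) and no cached payload at %s",
        paste(countries, collapse = ", "),
        paste(years, collapse = ", "), cache))
    }
    payload <- idb_json_to_csv(tmp, countries, years)
    jsonlite::write_json(
      list(payload = payload,
           retrieved = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
           url = url, vintage = format(Sys.Date(), "%Y")),
      cache, auto_unbox = TRUE)
  }
  rec <- jsonlite::read_json(cache, simplifyVector = TRUE)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  writeLines(rec$payload, tmp)
  read_idb_csv(tmp, vintage = rec$vintage %||% NA_character_)
}

# Census API answers a JSON array-of-arrays; convert to the package's
# IDB CSV dialect so the cache is self-describing.
idb_json_to_csv <- function(json_path, countries, years) {
  raw <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  header <- raw[1L, ]
  body <- as.data.frame(raw[-1L, , drop = FALSE], stringsAsFactors = FALSE)
  names(body) <- header
  sex_map <- c(`1` = "male", `2` = "female")
  out <- data.frame(
    country = body$GENC, year = body$YR,
    sex = sex_map[as.character(body$SEX)],
    age_lo = body$AGE_LO,
    age_hi = ifelse(as.numeric(body$AGE_LO) >= 100, "", body$AGE_HI),
    population = body$POP, stringsAsFactors = FALSE)
  out <- out[!is.na(out$sex), ]
  c("country,year,sex,age_lo,age_hi,population",
    do.call(paste, c(out, sep = ",")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
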