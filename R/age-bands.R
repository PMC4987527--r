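#' Standard demographic 5-year age grid
#'
#' The 21-band grid used by International Data Base style population
#' tables: 0-4, 5-9, ..., 95-99, 100+.  Bands are closed integer-year
#' intervals `[lo, hi]`; the terminal band is open-ended (`age_hi` is
#' `NA`) but is treated as 100-104 (width 5) wherever a finite width is
#' needed (median-age interpolation, overlap fractions).
#'
#' @return A data frame with columns `age_lo`, `age_hi` (`NA` for the
#'   open band) and `label` (e.g. `"15-19"`, `"100+"`).
#' @examples
#' standard_age_grid()
#' @export
standard_age_grid <- function() {
  lo <- seq(0L, 100L, by = 5L)
  hi <- c(seq(4L, 99L, by = 5L), NA_integer_)
  data.frame(
    age_lo = lo,
    age_hi = hi,
    label = band_label(lo, hi),
    stringsAsFactors = FALSE
  )
}

#' Format an age band label
#'
#' @param lo,hi Integer band bounds; `hi = NA` marks an open-ended band.
#' @return Character labels like `"60-64"` or `"80+"`.
#' @export
band_label <- function(lo, hi) {
  ifelse(is.na(hi), paste0(lo, "+"), paste0(lo, "-", hi))
}

# Parse age_hi as written in CSVs: blank / NA / "+"-suffixed -> open band.
# Returns NA for open, integer otherwise; non-numeric junk -> NA with attr.
parse_age_hi <- function(x) {
  x <- trimws(as.character(x))
  open <- is.na(x) | x == "" | grepl("\\+$", x)
  out <- suppressWarnings(as.numeric(x))
  out[open] <- NA_real_
  bad <- !open & is.na(out)
  if (any(bad)) {
    abort_format(sprintf(
      "unparseable age_hi value(s): %s",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  out
}

# Parse a GROUP-style band label ("0-4", "100+") into lo/hi.
parse_band_label <- function(label) {
  label <- trimws(as.character(label))
  open <- grepl("\\+$", label)
  lo <- suppressWarnings(as.numeric(sub("[-+].*$", "", label)))
  hi <- rep(NA_real_, length(label))
  bounded <- !open
  hi[bounded] <- suppressWarnings(as.numeric(sub("^[0-9]+-", "", label[bounded])))
  bad <- is.na(lo) | (bounded & is.na(hi))
  if (any(bad)) {
    abort_format(sprintf(
      "non-standard age band label(s): %s",
      paste(unique(label[bad]), collapse = ", ")
    ))
  }
  data.frame(age_lo = lo, age_hi = hi)
}

# --- typed conditions -------------------------------------------------------
# Every malformed input raises a classed condition; callers and tests can
# distinguish format errors (file shape), validation errors (values) and
# configuration errors (mismatched pieces).

abort_typed <- function(class, msg) {
  stop(structure(
    class = c(class, "alscast_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_format     <- function(msg) abort_typed("alscast_format_error", msg)
abort_validation <- function(msg) abort_typed("alscast_validation_error", msg)
abort_config     <- function(msg) abort_typed("alscast_config_error", msg)
abort_domain     <- function(msg) abort_typed("alscast_domain_error", msg)
abort_retrieval  <- function(msg) abort_typed("alscast_retrieval_error", msg)
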