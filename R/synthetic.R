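#' Specify a synthetic world
#'
#' Parameters for a seeded generator producing inputs with the
#' statistical structure the projection assumes: ageing population
#' pyramids for a baseline and a horizon epoch, incidence schedules
#' peaking at ages 60-79 (where observed ALS incidence peaks), region
#' median durations in the 2-4 year range typical of ALS survival, and
#' study catchment sizes for pooling weights.
#'
#' @param n_regions Number of regions (default 10).
#' @param seed Integer seed fixing every draw.
#' @param total_population Mean region population (persons; default
#'   5e7; region totals are lognormal around this).
#' @param ageing_index Non-negative index controlling how much mass
#'   shifts into the 60+ bands between epochs and how much totals grow;
#'   0 gives identical pyramids in both epochs.
#' @param peak_rate Peak incidence, new cases per 100,000 person-years
#'   (default 6, the order observed at the ALS incidence peak).
#' @param peak_lo,peak_hi Age range of the incidence plateau (60, 79).
#' @param decay_young,decay_old Exponential decay per decade of the
#'   rate below/above the plateau.
#' @param duration_range Range (years) for region median durations,
#'   default `c(2, 4)`.
#' @param catchment_range Range of the study catchment as a fraction of
#'   the region population, default `c(0.05, 1)`.
#' @param years The two epochs, default `c(2015, 2040)`.
#' @return A validated `synthetic_world_spec`.
#' @export
synthetic_world_spec <- function(n_regions = 10, seed = 1,
                                 total_population = 5e7,
                                 ageing_index = 0.5,
                                 peak_rate = 6, peak_lo = 60, peak_hi = 79,
                                 decay_young = 0.7, decay_old = 0.5,
                                 duration_range = c(2, 4),
                                 catchment_range = c(0.05, 1),
                                 years = c(2015, 2040)) {
  spec <- list(n_regions = as.integer(n_regions), seed = as.integer(seed),
               total_population = total_population,
               ageing_index = ageing_index,
               peak_rate = peak_rate, peak_lo = peak_lo, peak_hi = peak_hi,
               decay_young = decay_young, decay_old = decay_old,
               duration_range = duration_range,
               catchment_range = catchment_range,
               years = as.integer(years))
  scalars <- c(spec$n_regions, spec$total_population, spec$peak_rate,
               spec$decay_young, spec$decay_old, spec$duration_range,
               spec$catchment_range)
  if (any(!is.finite(scalars)) || any(scalars <= 0)) {
    abort_domain("all synthetic scale parameters must be > 0")
  }
  if (!is.finite(spec$ageing_index) || spec$ageing_index < 0) {
    abort_domain("ageing_index must be >= 0")
  }
  if (length(spec$years) != 2L) abort_domain("exactly two epochs required")
  structure(spec, class = "synthetic_world_spec")
}

# plateau shape: 1 inside [peak_lo, peak_hi], exponential decay outside
incidence_shape <- function(mid, spec) {
  ifelse(mid < spec$peak_lo,
         exp(-spec$decay_young * (spec$peak_lo - mid) / 10),
         ifelse(mid > spec$peak_hi,
                exp(-spec$decay_old * (mid - spec$peak_hi) / 10),
                1))
}

#' Generate a synthetic world with embedded closed-form truth
#'
#' Draws, deterministically under the spec's seed, a set of regions
#' with baseline and horizon population pyramids, sex-specific
#' incidence schedules on 5-year study bands from age 20 with an
#' open-ended 80+ band, region median durations, study catchments and
#' a continent/development classification.  Alongside the data it
#' returns the expected case counts computed by direct band-wise
#' arithmetic — independent of the harmonization/projection code paths
#' — to serve as ground truth in recovery tests.
#'
#' Pyramids age between epochs by tilting band weights with
#' `exp(ageing_index * a_i * mid / 100)` and growing totals by
#' `1 + ageing_index * g_i`; with `ageing_index = 0` the two epochs are
#' identical.  Schedule rates are the plateau shape scaled by a region
#' level and a sex factor (male rates ~1.4x female, matching the
#' observed ALS sex ratio).
#'
#' @param spec A [synthetic_world_spec()].
#' @return List with `spec`, `pyramids` (one per region-epoch),
#'   `schedules` (one [incidence_schedule()] per region-sex),
#'   `durations` (list of [duration_model()]), `hierarchy`
#'   ([region_hierarchy()]) and `truth` (data frame `region`, `year`,
#'   `sex`, `cases`, computed independently).
#' @export
generate_world <- function(spec) {
  stopifnot(inherits(spec, "synthetic_world_spec"))
  set.seed(spec$seed)
  grid <- standard_age_grid()
  mid <- grid$age_lo + 2
  sex_factor <- c(male = 1.15, female = 0.85)
  regions <- sprintf("region%02d", seq_len(spec$n_regions))
  continents <- c("Africa", "NorthAmerica", "SouthAmerica", "Asia",
                  "Europe", "Oceania")

  pyramids <- list(); schedules <- list(); durations <- list()
  truth <- list()
  for (i in seq_len(spec$n_regions)) {
    reg <- regions[i]
    total0 <- stats::rlnorm(1, log(spec$total_population), 0.5)
    scale <- stats::runif(1, 25, 45)
    w0 <- exp(-mid / scale)
    tilt <- stats::runif(1, 0.5, 1.5)
    growth <- 1 + spec$ageing_index * stats::runif(1, 0.1, 0.5)
    w1 <- w0 * exp(spec$ageing_index * tilt * mid / 100)
    fem <- 0.49 + 0.06 * mid / 104   # slight female excess at old ages

    counts <- list(
      stats::setNames(list(total0 * w0 / sum(w0)), as.character(spec$years[1L])),
      stats::setNames(list(total0 * growth * w1 / sum(w1)),
                      as.character(spec$years[2L]))
    )
    for (k in 1:2) {
      band_tot <- counts[[k]][[1L]]
      m <- cbind(male = band_tot * (1 - fem), female = band_tot * fem)
      rownames(m) <- grid$label
      pyramids[[paste(reg, spec$years[k], sep = ".")]] <-
        population_pyramid(reg, spec$years[k], m, vintage = "synthetic")
    }

    level <- spec$peak_rate * stats::runif(1, 0.6, 1.4)
    study_lo <- seq(20, 80, by = 5)
    study_hi <- c(seq(24, 79, by = 5), NA)           # 80+ open-ended
    study_mid <- study_lo + 2
    catchment <- stats::runif(1, spec$catchment_range[1L],
                              spec$catchment_range[2L]) * total0
    D <- stats::runif(1, spec$duration_range[1L], spec$duration_range[2L])
    durations[[reg]] <- duration_model(reg, D)

    for (s in c("male", "female")) {
      rate <- level * sex_factor[[s]] * incidence_shape(study_mid, spec)
      schedules[[paste(reg, s, sep = ".")]] <- incidence_schedule(
        reg, s, data.frame(age_lo = study_lo, age_hi = study_hi, rate = rate),
        study_population = catchment,
        study_period = paste(spec$years[1L] - 5, spec$years[1L], sep = "-"))
      # ---- independent truth: direct arithmetic, no package code paths ----
      # grid bands below 20 contribute nothing; 20-79 map 1:1 onto study
      # bands; 80+ grid bands all carry the open study band's rate
      grid_rate <- numeric(nrow(grid))
      for (g in seq_len(nrow(grid))) {
        lo <- grid$age_lo[g]
        if (lo >= 80) grid_rate[g] <- rate[length(rate)]
        else if (lo >= 20) grid_rate[g] <- rate[match(lo, study_lo)]
      }
      for (k in 1:2) {
        p <- pyramids[[paste(reg, spec$years[k], sep = ".")]]
        truth[[length(truth) + 1L]] <- data.frame(
          region = reg, year = spec$years[k], sex = s,
          cases = sum(grid_rate / 1e5 * p$counts[, s] * D),
          stringsAsFactors = FALSE)
      }
    }
  }
  hierarchy <- region_hierarchy(data.frame(
    region = regions,
    continent = rep_len(continents, spec$n_regions),
    development = rep_len(c("developed", "developing"), spec$n_regions),
    stringsAsFactors = FALSE))
  list(spec = spec, pyramids = pyramids, schedules = unname(schedules),
       durations = unname(durations), hierarchy = hierarchy,
       truth = do.call(rbind, truth))
}

#' Persist a synthetic world in the package's CSV dialects
#'
#' Writes the incidence, duration, population and hierarchy tables of a
#' [generate_world()] result into `dir`, in exactly the formats the
#' readers invert, so synthetic fixtures double as format tests.
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(incidence = file.path(dir, "incidence.csv"),
             durations = file.path(dir, "durations.csv"),
             population = file.path(dir, "population.csv"),
             hierarchy = file.path(dir, "hierarchy.csv"))
  write_incidence_table(world$schedules, paths[["incidence"]])
  write_durations(world$durations, paths[["durations"]])
  write_idb_csv(world$pyramids, paths[["population"]])
  utils::write.csv(as.data.frame(world$hierarchy), paths[["hierarchy"]],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Illness-death microsimulation of point prevalence
#'
#' An independent stochastic oracle for the stationary product
#' approximation.  Per grid band, disease onsets arise as a Poisson
#' process at the band's rate over the band population's person-time;
#' each case persists for a duration with the stated median — fixed at
#' the median by default (the projection multiplies by the median, not
#' the mean), or exponential with that median (`rate = log(2)/median`,
#' so the mean is `median/log 2` and prevalence is correspondingly
#' higher).  Point prevalence is counted at a census instant in the
#' stationary regime and summarised over replicates.
#'
#' @param rates A [harmonized_rates()] for one sex.
#' @param pyramid A [population_pyramid()] containing that sex.
#' @param duration A [duration_model()] or bare median years.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @param duration_dist `"fixed"` (default) or `"exponential"`.
#' @return List: `mean` prevalence count, `se` (Monte-Carlo standard
#'   error of the mean), `reps` (per-replicate counts).
#' @export
microsim_prevalence <- function(rates, pyramid, duration, n_reps, seed,
                                duration_dist = c("fixed", "exponential")) {
  duration_dist <- match.arg(duration_dist)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) abort_domain("n_reps must be >= 1")
  D <- if (inherits(duration, "duration_model")) duration$median_duration
       else as.numeric(duration)
  if (!is.finite(D) || D <= 0) abort_domain("duration must be > 0")
  s <- rates$sex
  if (!s %in% colnames(pyramid$counts)) {
    abort_config(sprintf("pyramid has no counts for sex '%s'", s))
  }
  lambda <- rates$rates / 1e5 * pyramid$counts[, s]   # onsets per year
  set.seed(seed)
  if (duration_dist == "fixed") {
    # with onset window = D every onset is alive at census:
    # occupancy is exactly Poisson(lambda * D) per band
    reps <- vapply(seq_len(n_reps), function(r) {
      sum(stats::rpois(length(lambda), lambda * D))
    }, numeric(1))
  } else {
    exp_rate <- log(2) / D          # median of Exp(rate) = log(2)/rate
    Tw <- 12 * (1 / exp_rate)       # residual survivor mass < 1e-5
    active <- which(lambda > 0)
    reps <- vapply(seq_len(n_reps), function(r) {
      n_band <- stats::rpois(length(active), lambda[active] * Tw)
      n <- sum(n_band)
      if (n == 0L) return(0)
      onset <- stats::runif(n, -Tw, 0)
      dur <- stats::rexp(n, exp_rate)
      sum(onset + dur > 0)
    }, numeric(1))
  }
  list(mean = mean(reps),
       se = if (n_reps > 1L) stats::sd(reps) / sqrt(n_reps) else 0,
       reps = reps)
}
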