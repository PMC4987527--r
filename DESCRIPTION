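Package: alscast
Title: Projection of ALS Case Numbers from Incidence, Population
    Structure and Disease Duration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Projects expected amyotrophic lateral sclerosis (ALS) case
    numbers by region, calendar year and sex under the stationary
    prevalence approximation (point prevalence = incidence x median
    disease duration), applied band-wise to age/sex-stratified incidence
    schedules and 5-year population pyramids.  Provides readers and
    writers for incidence schedules, median-duration tables and
    International Data Base style population projections; harmonization
    of study age bands onto the demographic 5-year grid; study-size
    weighted pooling of incidence to continents with global
    extrapolation; change and population-ageing analytics; a seeded
    synthetic-world generator with embedded closed-form truth; and an
    illness-death microsimulation used as an independent oracle for the
    prevalence approximation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
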