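#!/usr/bin/env Rscript
# Thin command-line wrapper over the alscast package.
#   alscast project  --incidence F --durations F --population F --hierarchy F --out-dir D
#   alscast global   --incidence F --durations F --population F --assignment F [--membership F] --out-dir D
#   alscast synth    --seed N --out-dir D
#   alscast validate [input flags]
# A key=value config file (--config F) supplies defaults; command-line
# flags override it.  Errors exit non-zero with a named cause.

suppressPackageStartupMessages({
  library(alscast)
  library(optparse)
})

usage <- function() {
  cat("usage: alscast <project|global|synth|validate> [options]\n")
  quit(status = 2)
}
args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) usage()
cmd <- args[1L]
rest <- args[-1L]

opts <- list(
  make_option("--config", type = "character", default = NULL,
              help = "key=value config file"),
  make_option("--incidence", type = "character", default = NULL),
  make_option("--durations", type = "character", default = NULL),
  make_option("--population", type = "character", default = NULL),
  make_option("--hierarchy", type = "character", default = NULL),
  make_option("--assignment", type = "character", default = NULL),
  make_option("--membership", type = "character", default = NULL),
  make_option("--years", type = "character", default = "2015,2040"),
  make_option("--overlap", type = "character", default = "proportional",
              help = "proportional | full"),
  make_option("--extend-oldest", action = "store_true", default = FALSE,
              dest = "extend_oldest"),
  make_option("--out-dir", type = "character", default = ".",
              dest = "out_dir"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--quiet", action = "store_true", default = FALSE))
parsed <- parse_args(OptionParser(option_list = opts), args = rest)

# config file supplies defaults; explicit flags win
if (!is.null(parsed$config)) {
  kv <- read.dcf(textConnection(gsub("=", ": ", readLines(parsed$config))))
  for (key in colnames(kv)) {
    if (key %in% names(parsed) && identical(parsed[[key]],
                                            formals(run_config)[[key]])) next
    if (is.null(parsed[[key]])) parsed[[key]] <- kv[1L, key]
  }
}

cfg <- run_config(
  incidence = parsed$incidence, durations = parsed$durations,
  population = parsed$population, hierarchy = parsed$hierarchy,
  assignment = parsed$assignment, membership = parsed$membership,
  years = as.integer(strsplit(parsed$years, ",")[[1L]]),
  overlap = parsed$overlap, extend_oldest = parsed$extend_oldest,
  out_dir = parsed$out_dir, seed = parsed$seed, quiet = parsed$quiet)

status <- tryCatch({
  switch(cmd,
         project = cmd_project(cfg),
         global = cmd_global(cfg),
         synth = cmd_synth(cfg),
         validate = cmd_validate(cfg),
         usage())
  0L
}, error = function(e) {
  message(sprintf("alscast %s failed [%s]: %s", cmd,
                  class(e)[1L], conditionMessage(e)))
  1L
})
quit(status = status)
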