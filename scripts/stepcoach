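#!/usr/bin/env Rscript

# Thin shell entry point over the stepcoach package.
#   stepcoach simulate --out DIR [--n 30] [--weeks 24] [--seed 1] [--config sim.yaml]
#   stepcoach coach    --data DIR [--out DIR] [--seed 1]
#   stepcoach evaluate --data DIR [--out DIR]
#   stepcoach power    [--dz 0.556] [--power 0.8] [--alpha 0.05]
# Logs go to stderr, results to files; exit 2 on bad input.

suppressPackageStartupMessages(library(stepcoach))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  message("usage: stepcoach <simulate|coach|evaluate|power> [options]")
  quit(status = 2)
}
cmd <- args[1]
opts <- args[-1]
get_opt <- function(flag, default = NULL) {
  i <- which(opts == flag)
  if (length(i) == 1 && i < length(opts)) opts[i + 1] else default
}

run <- function(expr) {
  tryCatch(expr, error = function(e) {
    message("error: ", conditionMessage(e))
    quit(status = 2)
  })
}

switch(cmd,
  simulate = run({
    out <- get_opt("--out")
    if (is.null(out)) stop("simulate requires --out DIR")
    cfg_path <- get_opt("--config")
    cfg <- if (is.null(cfg_path)) sim_config() else load_sim_config(cfg_path)
    files <- cmd_simulate(out,
      n = as.integer(get_opt("--n", "30")),
      weeks = as.integer(get_opt("--weeks", "24")),
      seed = as.integer(get_opt("--seed", "1")),
      config = cfg
    )
    message("wrote: ", paste(files, collapse = ", "))
  }),
  coach = run({
    data <- get_opt("--data")
    if (is.null(data)) stop("coach requires --data DIR")
    files <- cmd_coach(data,
      out_dir = get_opt("--out", data),
      seed = as.integer(get_opt("--seed", "1"))
    )
    message("wrote: ", paste(files, collapse = ", "))
  }),
  evaluate = run({
    data <- get_opt("--data")
    if (is.null(data)) stop("evaluate requires --data DIR")
    files <- cmd_evaluate(data, out_dir = get_opt("--out", data))
    message("wrote: ", paste(files, collapse = ", "))
  }),
  power = run({
    dz <- get_opt("--dz")
    res <- cmd_power(
      effect_size_dz = if (is.null(dz)) NULL else as.numeric(dz),
      power = as.numeric(get_opt("--power", "0.8")),
      alpha = as.numeric(get_opt("--alpha", "0.05"))
    )
    cat(jsonlite::toJSON(res, auto_unbox = TRUE, digits = NA), "\n")
  }),
  {
    message("unknown command: ", cmd)
    quit(status = 2)
  }
)
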