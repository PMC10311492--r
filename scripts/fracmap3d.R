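#!/usr/bin/env Rscript
# Thin command-line wrapper over the fracmap3d pipeline functions.
#
#   Rscript scripts/fracmap3d.R simulate --out DIR [--config cfg.yaml] [--seed N]
#   Rscript scripts/fracmap3d.R map      --out DIR [--config cfg.yaml]
#   Rscript scripts/fracmap3d.R stats    --out DIR [--config cfg.yaml]
#   Rscript scripts/fracmap3d.R report   --out DIR [--config cfg.yaml] [--seed N]
#
# --config points at a YAML written by write_config(); --out and --seed
# override its out_dir and seed.

suppressPackageStartupMessages({
  library(optparse)
  library(fracmap3d)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("simulate", "map", "stats", "report")) {
  message("usage: fracmap3d.R <simulate|map|stats|report> [--config path.yaml] [--out dir] [--seed n]")
  quit(status = 2)
}
cmd <- args[1]
opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--out", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL))),
  args = args[-1])

config <- if (!is.null(opts$config)) read_config(opts$config) else pipeline_config()
if (!is.null(opts$out)) config$out_dir <- opts$out
if (!is.null(opts$seed)) config$seed <- opts$seed

switch(cmd,
       simulate = cmd_simulate(config),
       map = cmd_map(config),
       stats = cmd_stats(config),
       report = cmd_report(config))
invisible(NULL)
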