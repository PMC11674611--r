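#!/usr/bin/env Rscript
# Thin command-line wrapper over the hbnet pipeline stages.
#
#   Rscript scripts/hbnet.R simulate --config cfg.yaml --out data/
#   Rscript scripts/hbnet.R networks --config cfg.yaml --dataset data/ --out nets/
#   Rscript scripts/hbnet.R evaluate --config cfg.yaml --networks nets/ --out report
#   Rscript scripts/hbnet.R all      --config cfg.yaml --out run/
#
# --seed overrides the config's seed; --verbose logs per-stage progress.

suppressMessages({
  library(optparse)
  library(hbnet)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || !args[1] %in% c("simulate", "networks", "evaluate", "all")) {
  cat("usage: hbnet.R <simulate|networks|evaluate|all> [--config FILE] [--seed N]\n",
      "               [--dataset DIR] [--networks DIR] --out PATH [--verbose]\n")
  quit(status = 2L)
}
cmd <- args[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--dataset", type = "character", default = NULL),
  make_option("--networks", type = "character", default = NULL),
  make_option("--out", type = "character", default = "hbnet_out"),
  make_option("--verbose", action = "store_true", default = FALSE)
)), args = args[-1])

cfg <- pipeline_config(opts$config)
if (!is.null(opts$seed)) cfg$seed <- opts$seed

switch(cmd,
  simulate = run_simulate(cfg, opts$out, verbose = opts$verbose),
  networks = {
    if (is.null(opts$dataset)) stop("--dataset required")
    run_networks(cfg, opts$dataset, opts$out, verbose = opts$verbose)
  },
  evaluate = {
    if (is.null(opts$networks)) stop("--networks required")
    rep <- run_evaluate(cfg, opts$networks, report_path = opts$out,
                        verbose = opts$verbose)
    print(rep$table)
  },
  all = {
    rep <- run_all(cfg, opts$out, verbose = opts$verbose)
    print(rep$table)
  })
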