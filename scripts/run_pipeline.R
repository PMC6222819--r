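#!/usr/bin/env Rscript
# Thin command-line wrapper over specbind::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R --config <yaml> [--out-dir <dir>] [--seed <int>]

suppressPackageStartupMessages({
  library(optparse)
  library(specbind)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character"),
  make_option("--out-dir", type = "character", default = NULL,
              dest = "out_dir"),
  make_option("--seed", type = "integer", default = NULL)
)))
if (is.null(opts$config)) stop("--config <yaml> is required", call. = FALSE)

cfg <- read_run_config(opts$config)
if (!is.null(opts$out_dir)) cfg$out_dir <- opts$out_dir
if (!is.null(opts$seed)) cfg$seed <- opts$seed

res <- tryCatch(run_pipeline(cfg), error = function(e) {
  message(conditionMessage(e))
  quit(status = 1L)
})
cat(res$log, sep = "\n")
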