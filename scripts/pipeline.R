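#!/usr/bin/env Rscript
# Thin shell wrapper over carbonscape::run_pipeline(). Usage:
#   Rscript scripts/pipeline.R --config run.yaml [--seed 1]
#     [--scenario nes|eps|eds|pds] [--output-dir DIR] [--block-km 3]

suppressPackageStartupMessages(library(carbonscape))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}

config_path <- get_arg("--config")
if (is.null(config_path)) stop("--config <file> is required")
cfg <- yaml::read_yaml(config_path)
if (!is.null(get_arg("--seed"))) cfg$seed <- as.integer(get_arg("--seed"))
if (!is.null(get_arg("--scenario"))) cfg$scenario <- get_arg("--scenario")
if (!is.null(get_arg("--output-dir"))) cfg$output_dir <- get_arg("--output-dir")
if (!is.null(get_arg("--block-km")))
  cfg$block <- 1000 * as.numeric(get_arg("--block-km"))

res <- run_pipeline(cfg)
cat("pipeline complete; artifacts under", res$output_dir, "\n")
print(res$manifest)
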