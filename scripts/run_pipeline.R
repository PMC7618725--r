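#!/usr/bin/env Rscript
# Thin command-line wrapper around gaspread::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --out <dir> [--config <yaml>] [--seed <int>]
#
# The YAML config (optional) holds overrides for gas_config()/sim_config();
# --seed overrides the config seed.

suppressPackageStartupMessages(library(gaspread))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

out <- get_arg("--out")
if (is.null(out)) stop("--out <dir> is required", call. = FALSE)
cfg_path <- get_arg("--config")
cfg <- if (is.null(cfg_path)) gas_config() else gas_config_yaml(cfg_path)
seed <- get_arg("--seed")
if (!is.null(seed)) {
  cfg$seed <- as.integer(seed)
  cfg$sim$seed <- as.integer(seed)
}

res <- run_pipeline(cfg, out)
message("GAS per participant:")
print(res$gas)
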