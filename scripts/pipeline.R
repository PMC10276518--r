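#!/usr/bin/env Rscript
# Thin command-line wrapper over methcascade::run_pipeline():
#   Rscript scripts/pipeline.R --config cfg.yaml [--seed N] [--out dir/]
# Flags override the YAML; with no --config the package defaults run.

suppressPackageStartupMessages(library(methcascade))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

cfg_path <- get_arg("--config")
cfg <- if (is.null(cfg_path)) pipeline_config() else
  read_pipeline_config(cfg_path)
seed <- get_arg("--seed")
if (!is.null(seed)) {
  cfg <- pipeline_config(sim = cfg$sim, min_coverage = cfg$min_coverage,
                         top_k = cfg$top_k, p_max = cfg$p_max,
                         max_healthy_background = cfg$max_healthy_background,
                         allowlist = cfg$allowlist, cv = cfg$cv,
                         s_target = cfg$s_target, d_target = cfg$d_target,
                         prevalence = cfg$prevalence, n_boot = cfg$n_boot,
                         out_dir = cfg$out_dir, seed = as.integer(seed))
}
out <- get_arg("--out")
if (!is.null(out)) cfg$out_dir <- out

report <- run_pipeline(cfg)
print(report)
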