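#!/usr/bin/env Rscript

# Thin command-line wrapper over the apoenet package.
#
#   Rscript scripts/apoenet.R synth   --out <dir> [--seed N] [--n-proteins N]
#   Rscript scripts/apoenet.R run-all --config <yaml>
#   Rscript scripts/apoenet.R run-all --abundance a.tsv --meta m.tsv \
#           [--markers-dir d] [--peptides p.tsv] --out <dir> [--seed N]
#   Rscript scripts/apoenet.R report  --run <dir>

suppressPackageStartupMessages(library(apoenet))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) stop("usage: apoenet.R <synth|run-all|report> [options]")
cmd <- args[1]
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}

if (cmd == "synth") {
  design <- cohort_design(
    n_proteins = as.integer(opt("--n-proteins", "3000")),
    seed = as.integer(opt("--seed", "1")))
  dir <- opt("--out", "synthetic_cohort")
  write_cohort(generate_cohort(design), dir)
  cat("synthetic cohort written to", dir, "\n")
} else if (cmd == "run-all") {
  cfg <- if (!is.null(opt("--config"))) {
    load_pipeline_config(opt("--config"))
  } else {
    pipeline_config(abundance = opt("--abundance"),
                    meta = opt("--meta"),
                    markers_dir = opt("--markers-dir"),
                    peptides = opt("--peptides"),
                    out = opt("--out", "apoenet_run"),
                    seed = as.integer(opt("--seed", "1")))
  }
  run_pipeline(cfg)
  make_report(cfg$out)
  cat("pipeline run written to", cfg$out, "\n")
} else if (cmd == "report") {
  path <- make_report(opt("--run", "apoenet_run"))
  cat("report written to", path, "\n")
} else {
  stop("unknown command: ", cmd)
}
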