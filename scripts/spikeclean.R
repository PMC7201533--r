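#!/usr/bin/env Rscript
# Thin command-line wrapper over the installed spikeclean package.
#
#   Rscript scripts/spikeclean.R simulate --out DIR [--seed N]
#   Rscript scripts/spikeclean.R run --out DIR [--seed N] [--cap 0.2]
#                                [--sample DIR --combined DIR --markers FILE]
#
# `simulate` writes a ground-truthed two-species fixture (MTX triplets +
# truth tables); `run` executes the full pipeline (on the bundled simulator
# by default, or on MTX triplets given via --sample/--combined) and writes
# per-cell tables plus a JSON run report.

suppressPackageStartupMessages(library(spikeclean))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: spikeclean.R <simulate|run> [options]")
cmd <- args[[1]]
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(opt("--seed", "1"))
out <- opt("--out", "spikeclean_out")

if (cmd == "simulate") {
  sim <- simulate_sample(sim_config(seed = seed))
  write_fixture(sim, out)
  cat("wrote fixture to", out, "\n")
} else if (cmd == "run") {
  sample_dir <- opt("--sample")
  combined_dir <- opt("--combined")
  markers_file <- opt("--markers")
  cfg <- if (is.null(sample_dir)) {
    run_config(sim = sim_config(seed = seed),
               fc_cap = as.numeric(opt("--cap", "0.2")),
               out_dir = out, seed = seed)
  } else {
    run_config(sample_dir = sample_dir, combined_dir = combined_dir,
               marker_file = markers_file,
               fc_cap = as.numeric(opt("--cap", "0.1")),
               out_dir = out, seed = seed)
  }
  res <- suppressWarnings(run_pipeline(cfg))
  cat("pipeline complete:", res$report$n_stages, "stages; outputs in",
      out, "\n")
} else {
  stop("unknown command: ", cmd)
}
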