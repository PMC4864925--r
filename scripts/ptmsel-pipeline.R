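#!/usr/bin/env Rscript
# Thin command-line wrapper around ptmsel::runPipeline().
#   Rscript scripts/ptmsel-pipeline.R <subcommand> --in <bundle-dir> \
#     --out <dir> [--seed N] [--shuffles N] [--network-permutations N] \
#     [--fdr-alpha A] [--hypermutation-rule mad|none]
# Subcommands: simulate map select-stats drivers pathways modules all

suppressPackageStartupMessages(library(ptmsel))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: ptmsel-pipeline.R <subcommand> --out <dir> [--in <dir>] ...")
subcommand <- args[1L]
rest <- args[-1L]
getArg <- function(flag, default) {
  i <- which(rest == flag)
  if (length(i) == 1L && i < length(rest)) rest[i + 1L] else default
}

seed <- as.integer(getArg("--seed", "1"))
cfg <- analysisConfig(
  nShuffles = as.integer(getArg("--shuffles", "100000")),
  nNetworkPermutations = as.integer(getArg("--network-permutations",
                                           "100")),
  fdrAlpha = as.numeric(getArg("--fdr-alpha", "0.05")),
  hypermutationRule = getArg("--hypermutation-rule", "mad"),
  seed = seed)
simCfg <- simConfig(seed = seed)

runPipeline(subcommand,
            inputDir = getArg("--in", NULL),
            outDir = getArg("--out", "ptmsel-results"),
            config = cfg, simCfg = simCfg)
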