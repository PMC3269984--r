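#!/usr/bin/env Rscript
# Thin command-line entry point over mlncTools::runPipeline().
#
#   Rscript scripts/run_pipeline.R --config config.yaml

suppressPackageStartupMessages({
  library(optparse)
  library(mlncTools)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character",
              help = "YAML run configuration (see ?readRunConfig)"))))
if (is.null(opts$config)) stop("--config is required")
runPipeline(opts$config)
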