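#!/usr/bin/env Rscript

# Thin command-line wrapper over atriskimmune::run_all(): runs the full
# synthetic-to-report pipeline from a YAML config.
#
# Usage: Rscript scripts/run_pipeline.R --config cfg.yaml [--seed 1]
#        [--out out_dir]

suppressMessages({
  library(optparse)
  library(atriskimmune)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML config; defaults to the built-in defaults"),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = NULL)
)))

cfg <- if (is.null(opts$config)) run_config() else
  read_run_config(opts$config)
if (!is.null(opts$seed)) {
  cfg$seed <- opts$seed
  cfg$synth$seed <- opts$seed
}
if (!is.null(opts$out)) cfg$out_dir <- opts$out

res <- run_all(cfg)
print(res)
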