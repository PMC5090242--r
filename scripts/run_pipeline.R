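#!/usr/bin/env Rscript
# Thin command-line wrapper around snpmetrics::run_full_study().
#
#   Rscript scripts/run_pipeline.R --config cfg.yaml --out results/ [--seed 1]
#
# The YAML config sections (simulate/qc/selection/model/matching) are
# documented in ?read_run_config. --seed overrides the config seed.

suppressPackageStartupMessages({
  library(optparse)
  library(snpmetrics)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run configuration"),
  make_option("--out", type = "character", default = "snpmetrics_run",
              help = "output directory [default %default]"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the configuration seed"),
  make_option("--k", type = "integer", default = NULL,
              help = "override the number of SNPs selected in stage 1")
)))

rc <- if (is.null(opts$config)) {
  list(config = simulation_config(), thresholds = qc_thresholds(),
       criteria = match_criteria(), k = 5, group_cuts = c(7, 12))
} else read_run_config(opts$config)

if (!is.null(opts$seed)) rc$config$seed <- opts$seed
if (!is.null(opts$k)) rc$k <- opts$k

message("seed: ", rc$config$seed, "; SNPs: ", rc$config$m_snps,
        "; output: ", opts$out)
res <- run_full_study(rc$config, k = rc$k, thresholds = rc$thresholds,
                      criteria = rc$criteria, group_cuts = rc$group_cuts,
                      out_dir = opts$out)
message("stage-1 selection (metric rule): ",
        paste(res$stage1$selection_metric$selected, collapse = ", "))
message("stage-2 best SNP: ", res$stage2$best_snp,
        "; apparent AUC ", sprintf("%.3f", res$stage2$auc$auc),
        "; optimism-corrected AUC ", sprintf("%.3f", res$stage2$cv$corrected))
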