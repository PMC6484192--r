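#!/usr/bin/env Rscript
# Run the response-classification pipeline over the simulated cohorts:
# 60-s PSTHs, baseline mean/SD over the 15 pre-injection bins, the
# 2-SD / 3-consecutive-bin band rule, onset latency and percent change,
# with the pyramidal (<= 8 spikes/s) inclusion filter.
#
# Requires analysis/01_simulate_cohorts.R to have produced the manifest.

library(spikepharm)

manifest_path <- "scratch/cohorts/manifest.tsv"
if (!file.exists(manifest_path)) {
  stop("run analysis/01_simulate_cohorts.R first")
}
manifest <- read.delim(manifest_path)

res <- run_pipeline(manifest, pipeline_config(), out_dir = "results/analysis")

units <- merge(res$units,
               manifest[, c("unit_id", "true_label", "true_onset_min")],
               by = "unit_id")
agreement <- mean(units$label == units$true_label)
resp <- units[units$true_label != "unaffected" & !units$excluded, ]
sign_ok <- mean(resp$label == resp$true_label)

cat(sprintf("classified %d units; per-unit label agreement %.1f%%\n",
            nrow(units), 100 * agreement))
cat(sprintf("truly responsive units called with correct sign: %.1f%% (%d/%d)\n",
            100 * sign_ok, sum(resp$label == resp$true_label), nrow(resp)))
called <- units[units$label != "unaffected", ]
cat(sprintf("onset latencies of called units: %.0f-%.0f min post-injection\n",
            min(called$onset_min), max(called$onset_min)))
cat(sprintf("percent changes: %+.0f%% to %+.0f%%\n",
            min(called$percent_change), max(called$percent_change)))
cat("per-unit table: results/analysis/classifications.tsv\n")
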