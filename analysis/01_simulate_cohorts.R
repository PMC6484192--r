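#!/usr/bin/env Rscript
# Simulate the four treatment-group cohorts (saline control and three
# donepezil dose groups) with their reported response structure: per-group
# neuron counts, effect-magnitude ranges, onset windows, a 15-min baseline
# and a 105-min post-injection window per 7200-s session.
#
# Spike-timestamp files and the session manifest go to scratch/cohorts/
# (bulky, regenerable); a small ground-truth summary goes to results/.

library(spikepharm)

seed <- 20260924L
out_data <- "scratch/cohorts"
dir.create(out_data, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

presets <- c("saline", "don5", "don10", "don15")
cohort <- generate_cohort(lapply(presets, cohort_preset), seed = seed)

manifest <- do.call(rbind, lapply(names(cohort), function(id) {
  tr <- cohort[[id]]
  path <- file.path(out_data, paste0(id, ".txt"))
  write_spike_times(tr, path)
  gt <- tr$ground_truth
  data.frame(unit_id = id, group = tr$group, spike_file = path,
             injection_time = tr$injection_time, duration = tr$duration,
             true_label = ground_truth_label(tr),
             true_multiplier = gt$effect_multiplier,
             true_onset_min = gt$onset_time / 60,
             true_baseline_hz = gt$baseline_rate)
}))
write.table(manifest, file.path(out_data, "manifest.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

truth <- do.call(rbind, lapply(split(manifest, manifest$group), function(m) {
  data.frame(group = m$group[1], n = nrow(m),
             excitatory = sum(m$true_label == "excitatory"),
             inhibitory = sum(m$true_label == "inhibitory"),
             unaffected = sum(m$true_label == "unaffected"))
}))
write.table(truth, "results/cohort_ground_truth.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("simulated %d units across %d groups (seed %d)\n",
            nrow(manifest), length(presets), seed))
print(truth, row.names = FALSE)
cat(sprintf("spike files and manifest under %s\n", out_data))
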