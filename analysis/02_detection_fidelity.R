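#!/usr/bin/env Rscript
# Validate the spike-detection stage on synthetic voltage traces: biphasic
# waveforms at constructed SNR 5 on white Gaussian noise, threshold
# detection plus spike-height window discrimination, scored against the
# known spike times with +/- 1 ms tolerance.

library(spikepharm)

seed <- 20260924L
dir.create("results", showWarnings = FALSE)

snr_levels <- c(3, 4, 5, 8)
rows <- lapply(snr_levels, function(snr) {
  tot <- c(matched = 0, true = 0, det = 0)
  for (s in 1:50) {
    tr <- simulate_homogeneous_train(5, 10, seed = seed + s,
                                     injection_time = 5)
    v <- synthesize_voltage(tr, peak_amplitude = snr, waveform_width = 0.001,
                            noise_sd = 1, sampling_rate = 20000,
                            seed = seed + 1000 + s)
    u <- discriminate_unit(detect_spikes(v), c(0.85, 1.6) * snr,
                           duration = 10, injection_time = 5)
    p <- detection_performance(tr$times, u$times)
    tot <- tot + c(p$n_matched, p$n_true, p$n_detected)
  }
  data.frame(constructed_snr = snr, n_true = tot[["true"]],
             recall = tot[["matched"]] / tot[["true"]],
             precision = tot[["matched"]] / tot[["det"]])
})
fidelity <- do.call(rbind, rows)
write.table(fidelity, "results/detection_fidelity.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("detection fidelity by constructed SNR (50 traces each):\n")
print(fidelity, row.names = FALSE, digits = 4)
cat("units are retained downstream only when measured SNR > 2\n")
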