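make_noise_trace <- function(n, sd, fs = 20000, seed = 1) {
  set.seed(seed)
  voltage_trace(stats::rnorm(n, 0, sd), fs)
}

test_that("noise SD estimation is calibrated, scale-equivariant and robust", {
  ests <- vapply(1:20, function(s) {
    estimate_noise_sd(make_noise_trace(1e5, 1, seed = s))
  }, numeric(1))
  expect_true(all(ests > 0.95 & ests < 1.05))

  # doubling the noise doubles the estimate for the same stream
  e1 <- estimate_noise_sd(make_noise_trace(1e5, 1, seed = 3))
  e2 <- estimate_noise_sd(make_noise_trace(1e5, 2, seed = 3))
  expect_equal(e2, 2 * e1, tolerance = 1e-12)

  expect_equal(estimate_noise_sd(voltage_trace(numeric(100), 1000)), 0)
  expect_error(estimate_noise_sd(voltage_trace(numeric(0), 1000)), "empty")

  # spikes at pyramidal rates barely perturb the estimate
  tr <- simulate_homogeneous_train(8, 10, seed = 5, injection_time = 5)
  v <- synthesize_voltage(tr, 5, 0.001, 1, 20000, seed = 6)
  expect_lt(abs(estimate_noise_sd(v) - 1), 0.05)
})

test_that("voltage synthesis constructs the advertised signal", {
  # empty train: pure noise with the requested SD
  empty <- spike_train(numeric(0), duration = 5, injection_time = 2)
  v0 <- synthesize_voltage(empty, 5, 0.001, 1, 20000, seed = 2)
  expect_lt(abs(stats::sd(v0$samples) - 1) / 1, 0.05)
  expect_length(v0$true_spike_times, 0)

  # single noiseless spike: suprathreshold peak of exactly the set height
  one <- spike_train(10, duration = 20, injection_time = 5)
  v1 <- synthesize_voltage(one, 5, 0.001, 0, 20000, seed = 3)
  i_pk <- which.max(abs(v1$samples))
  expect_equal(max(v1$samples), 5)
  expect_lt(abs((i_pk - 1) / 20000 - 10), 1 / 20000 + 1e-12)

  expect_error(synthesize_voltage(one, 5, 0.001, 1, 5000), "under-sampled")
})

test_that("detection handles noiseless and empty cases", {
  one <- spike_train(10, duration = 20, injection_time = 5)
  v1 <- synthesize_voltage(one, 5, 0.001, 0, 20000, seed = 1)
  ev <- detect_spikes(v1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_height, 5)
  expect_lt(abs(ev$time - 10), 1 / 20000 + 1e-12)

  # all samples below threshold: no events
  quiet <- make_noise_trace(20000, 1e-6, seed = 4)
  quiet$samples <- quiet$samples * 0
  expect_equal(nrow(detect_spikes(quiet)), 0)
})

test_that("excursions within the dead time collapse to one event", {
  # two noiseless templates 0.5 ms apart, the first larger
  fs <- 20000
  t1 <- spike_train(c(10), duration = 20, injection_time = 5)
  v <- synthesize_voltage(t1, 5, 0.001, 0, fs, seed = 1)
  t2 <- spike_train(c(10.0005), duration = 20, injection_time = 5)
  v2 <- synthesize_voltage(t2, 3, 0.001, 0, fs, seed = 1)
  v$samples <- v$samples + v2$samples
  ev <- detect_spikes(v)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$time - 10), 0.0005 + 1e-9)
  expect_gt(ev$peak_height, 5)  # superposed peak at least the larger spike
})

test_that("raising the threshold never increases the event count", {
  tr <- simulate_homogeneous_train(6, 5, seed = 8, injection_time = 2)
  v <- synthesize_voltage(tr, 5, 0.001, 1, 20000, seed = 9)
  counts <- vapply(c(2, 3, 4, 5, 6), function(k) {
    nrow(detect_spikes(v, detection_config(threshold_k = k)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the window discriminator is a pure filter", {
  ev <- data.frame(time = c(1, 2, 3), peak_height = c(5, 10, 8))
  out <- discriminate_unit(ev, c(8, 12), duration = 10, injection_time = 5)
  expect_equal(out$times, c(2, 3))
  # identity window
  all_of <- discriminate_unit(ev, c(0, Inf), duration = 10,
                              injection_time = 5)
  expect_equal(all_of$times, ev$time)
  # empty input
  none <- discriminate_unit(ev[0, ], c(0, Inf), duration = 10,
                            injection_time = 5)
  expect_length(none$times, 0)
  expect_error(discriminate_unit(ev, c(12, 8), duration = 10), "window")

  # subset property on a real trace
  tr <- simulate_homogeneous_train(5, 5, seed = 12, injection_time = 2)
  v <- synthesize_voltage(tr, 5, 0.001, 1, 20000, seed = 13)
  evr <- detect_spikes(v)
  sub <- discriminate_unit(evr, c(4.5, 6), duration = 5, injection_time = 2)
  expect_true(all(sub$times %in% evr$time))
})

test_that("unit SNR implements the inclusion criterion", {
  ev <- data.frame(time = 1:3, peak_height = c(5, 5, 5))
  expect_equal(unit_snr(ev, 1), 5)
  low <- data.frame(time = 1:3, peak_height = c(1.8, 1.8, 1.8))
  snr <- unit_snr(low, 1)
  expect_equal(snr, 1.8)
  expect_false(snr > 2)  # excluded under the strict > 2 criterion
  expect_true(is.na(unit_snr(ev[0, ], 1)))
  expect_error(unit_snr(ev, 0), "noise_sd")
})

test_that("detection recovers synthetic spikes at high SNR", {
  # short version of the fidelity study (full scale in the acceptance run)
  tot <- c(matched = 0, true = 0, det = 0)
  for (s in 1:10) {
    tr <- simulate_homogeneous_train(5, 10, seed = 600 + s,
                                     injection_time = 5)
    v <- synthesize_voltage(tr, 5, 0.001, 1, 20000, seed = 700 + s)
    u <- discriminate_unit(detect_spikes(v), c(0.85, 1.6) * 5,
                           duration = 10, injection_time = 5)
    p <- detection_performance(tr$times, u$times)
    tot <- tot + c(p$n_matched, p$n_true, p$n_detected)
  }
  # the 0.99 fidelity bound is asserted at full scale (100 traces) in
  # the acceptance suite; this 10-trace smoke check allows sampling noise
  expect_gte(tot[["matched"]] / tot[["true"]], 0.98)
  expect_gte(tot[["matched"]] / tot[["det"]], 0.98)
})
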