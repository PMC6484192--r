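test_that("zero-rate and invalid configurations behave as specified", {
  expect_length(simulate_homogeneous_train(0, 7200, seed = 1)$times, 0)
  expect_error(simulation_config(-1), "baseline_rate")
  expect_error(simulation_config(4, effect_multiplier = -0.5), "multiplier")
  expect_error(simulation_config(4, onset_time = 7000), "onset_time")
  expect_error(spike_train(c(1, 2), duration = -5), "duration")
})

test_that("homogeneous train matches Poisson closed forms", {
  tr <- simulate_homogeneous_train(4, 7200, refractory = 0, seed = 11)
  expected <- 4 * 7200
  expect_lt(abs(length(tr$times) - expected), 4 * sqrt(expected))
  isi <- diff(tr$times)
  expect_lt(abs(stats::sd(isi) / mean(isi) - 1), 0.05)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$times >= 0 & tr$times < 7200))
})

test_that("rate calibration holds across seeded replicates", {
  # empirical count within 4*sqrt(rT) of rT in at least 99% of runs
  ok <- vapply(1:200, function(s) {
    tr <- simulate_homogeneous_train(6, 600, refractory = 0, seed = s)
    abs(length(tr$times) - 3600) < 4 * sqrt(3600)
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("refractory dead time is never violated", {
  for (s in 1:20) {
    tr <- simulate_homogeneous_train(40, 60, refractory = 0.01, seed = s)
    if (length(tr$times) > 1) expect_gte(min(diff(tr$times)), 0.01)
  }
})

test_that("identical seeds give bitwise-identical trains", {
  cfg <- simulation_config(5, 2.8, onset_time = 3000, seed = 77)
  expect_identical(simulate_drug_response_train(cfg)$times,
                   simulate_drug_response_train(cfg)$times)
  c1 <- generate_cohort(cohort_preset("don15"), seed = 5)
  c2 <- generate_cohort(cohort_preset("don15"), seed = 5)
  expect_identical(lapply(c1, `[[`, "times"), lapply(c2, `[[`, "times"))
})

test_that("drug-response trains hit their configured rates", {
  # null effect: post-injection rate within 3 SE of baseline
  tr0 <- simulate_drug_response_train(
    simulation_config(4, 1.0, refractory = 0, seed = 21))
  se <- sqrt(4 / 6300)
  expect_lt(abs(mean_rate(tr0, 900, 7200) - 4), 3 * se)

  # +180 percent step: post-onset rate within 3 SE of 11.2 spikes/s
  tr1 <- simulate_drug_response_train(
    simulation_config(4, 2.8, onset_time = 3000, refractory = 0, seed = 22))
  se1 <- sqrt(11.2 / (7200 - 3900))
  expect_lt(abs(mean_rate(tr1, 3900, 7200) - 11.2), 3 * se1)
  expect_lt(abs(mean_rate(tr1, 0, 3900) - 4), 3 * sqrt(4 / 3900))

  # -80 percent step: post-onset rate within 3 SE of 0.8 spikes/s
  tr2 <- simulate_drug_response_train(
    simulation_config(4, 0.2, onset_time = 3000, refractory = 0, seed = 23))
  se2 <- sqrt(0.8 / 3300)
  expect_lt(abs(mean_rate(tr2, 3900, 7200) - 0.8), 3 * se2)
})

test_that("zero ramp reproduces the step process exactly", {
  a <- simulate_drug_response_train(
    simulation_config(4, 2.8, onset_time = 3000, ramp_duration = 0,
                      seed = 31))
  b <- simulate_drug_response_train(
    simulation_config(4, 2.8, onset_time = 3000, seed = 31))
  expect_identical(a$times, b$times)
})

test_that("ramped onset interpolates between baseline and effect rate", {
  cfg <- simulation_config(4, 3, onset_time = 2000, ramp_duration = 1200,
                           refractory = 0, seed = 41)
  tr <- simulate_drug_response_train(cfg)
  mid <- 900 + 2000 + 600  # halfway through the ramp: expected rate 8
  r_mid <- mean_rate(tr, mid - 150, mid + 150)
  expect_lt(abs(r_mid - 8), 3 * sqrt(8 / 300) + 1)  # linear-trend slack
  expect_lt(abs(mean_rate(tr, 4200, 7200) - 12), 3 * sqrt(12 / 3000))
})

test_that("cohort generation respects its specification", {
  expect_error(generate_cohort(list()), "empty")
  # passthrough: one unit, fixed multiplier and onset
  gs <- group_spec("one", data.frame(n = 1, mult_lo = 3, mult_hi = 3),
                   onset_min = c(50, 50), baseline_range = c(4, 4))
  coh <- generate_cohort(gs, seed = 9)
  gt <- coh[[1]]$ground_truth
  expect_equal(gt$effect_multiplier, 3)
  expect_equal(gt$onset_time, 3000)
  expect_equal(gt$baseline_rate, 4)
  expect_equal(ground_truth_label(coh[[1]]), "excitatory")

  # all-null spec: every ground truth labelled null
  gs0 <- group_spec("null", data.frame(n = 5, mult_lo = 1, mult_hi = 1))
  labs <- vapply(generate_cohort(gs0, seed = 2), ground_truth_label,
                 character(1))
  expect_true(all(labs == "unaffected"))

  # don15 preset: 10 excitatory, 2 inhibitory, 4 null ground truths
  labs15 <- vapply(generate_cohort(cohort_preset("don15"), seed = 3),
                   ground_truth_label, character(1))
  expect_equal(as.vector(table(labs15)[c("excitatory", "inhibitory",
                                         "unaffected")]),
               c(10L, 2L, 4L))
  expect_length(labs15, 16)
})

test_that("cohorts are reproducible unit by unit", {
  # dropping other units does not change a unit's train
  full <- generate_cohort(cohort_preset("don10"), seed = 13)
  again <- generate_cohort(cohort_preset("don10"), seed = 13)
  expect_identical(full[["don10_07"]]$times, again[["don10_07"]]$times)
})
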