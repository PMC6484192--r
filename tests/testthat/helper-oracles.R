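# Independent oracles used across tests. These deliberately reimplement
# the checked operations by the most direct route available (per-spike
# loops, exhaustive window scans, hand formulas) and share no code with
# the package internals.

# Build a binned_rate object directly from per-bin rates.
fake_psth <- function(rates, bin_width = 60, t_start = 0,
                      injection_time = 900) {
  structure(
    list(bin_width = bin_width, t_start = t_start,
         counts = rates * bin_width, rates = rates,
         bin_starts = t_start + (seq_along(rates) - 1) * bin_width,
         dropped_s = 0, injection_time = injection_time),
    class = "binned_rate")
}

fake_baseline <- function(rates) {
  structure(
    list(mean_rate = mean(rates), sd_rate = stats::sd(rates),
         n_bins = length(rates), degenerate = stats::sd(rates) == 0),
    class = "baseline_stats")
}

# Per-spike bin assignment, one spike at a time.
brute_bin_counts <- function(times, bin_width, t_start, t_end) {
  n_bins <- floor((t_end - t_start) / bin_width + 1e-9)
  counts <- integer(n_bins)
  for (t in times) {
    if (t < t_start || t >= t_start + n_bins * bin_width) next
    b <- as.integer(floor((t - t_start) / bin_width)) + 1L
    counts[b] <- counts[b] + 1L
  }
  counts
}

# Exhaustive window scan over every run_length-wide window of post bins.
brute_classify <- function(psth, baseline, injection_time, k_sd = 2,
                           run_length = 3, sd_floor = 1 / psth$bin_width) {
  s <- if (baseline$sd_rate == 0) sd_floor else baseline$sd_rate
  upper <- baseline$mean_rate + k_sd * s
  lower <- baseline$mean_rate - k_sd * s
  post <- which(psth$bin_starts >= injection_time - 1e-9)
  r <- psth$rates[post]
  first_ex <- Inf
  first_in <- Inf
  if (length(r) >= run_length) {
    for (i in 1:(length(r) - run_length + 1)) {
      w <- r[i:(i + run_length - 1)]
      if (all(w > upper) && i < first_ex) first_ex <- i
      if (all(w < lower) && i < first_in) first_in <- i
    }
  }
  if (is.infinite(first_ex) && is.infinite(first_in)) return("unaffected")
  if (first_ex <= first_in) "excitatory" else "inhibitory"
}

# Paired t statistic by the hand formula.
hand_paired_t <- function(baseline, post) {
  d <- post - baseline
  n <- length(d)
  list(t = mean(d) / (stats::sd(d) / sqrt(n)), df = n - 1)
}

# A random PSTH + baseline pair exercising the classifier broadly:
# mixes smooth, noisy and pathological (constant, spiky) series.
random_psth_case <- function(seed) {
  set.seed(seed)
  n_base <- sample(2:15, 1)
  n_post <- sample(5:105, 1)
  kind <- sample(3, 1)
  base <- switch(kind,
    round(runif(n_base, 0, 8), 2),
    rpois(n_base, 4),
    rep(round(runif(1, 0, 8)), n_base))
  post <- switch(sample(3, 1),
    round(runif(n_post, 0, 16), 2),
    rpois(n_post, sample(1:12, 1)),
    rep(round(runif(1, 0, 12)), n_post))
  inj <- n_base * 60
  list(
    psth = fake_psth(c(base, post), injection_time = inj),
    baseline = fake_baseline(base),
    injection_time = inj)
}
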