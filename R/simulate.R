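#' Simulation configuration for a drug-response session
#'
#' Describes one simulated single-unit session: a homogeneous baseline
#' discharge, an injection at `injection_time`, and a multiplicative rate
#' change that takes effect `onset_time` seconds after the injection
#' (optionally ramping in linearly over `ramp_duration`).
#'
#' The defaults encode a 7200-s session with a 15-min baseline followed by
#' a 105-min post-injection window, and a pyramidal-range baseline rate
#' (at most 8 spikes/s).
#'
#' @param baseline_rate Baseline firing rate in spikes/s (> 0).
#' @param effect_multiplier Post-onset rate factor: 1 is a null effect,
#'   2.8 is a +180 percent increase, 0.2 an 80 percent reduction.
#' @param onset_time Effect onset in seconds after the injection.
#' @param ramp_duration Seconds over which the rate ramps linearly from
#'   baseline to its post-onset value; 0 gives a step change.
#' @param refractory Absolute refractory period in seconds (dead time
#'   enforced on the simulated train). Default 2 ms, a physiological floor.
#' @param injection_time Injection time in seconds from recording start.
#' @param session_duration Total session length in seconds.
#' @param seed Integer seed; identical configurations and seeds give
#'   bitwise-identical trains.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(baseline_rate,
                              effect_multiplier = 1,
                              onset_time = 0,
                              ramp_duration = 0,
                              refractory = 0.002,
                              injection_time = 900,
                              session_duration = 7200,
                              seed = 1L) {
  if (!is.finite(baseline_rate) || baseline_rate < 0) {
    stop("baseline_rate must be >= 0", call. = FALSE)
  }
  if (!is.finite(effect_multiplier) || effect_multiplier < 0) {
    stop("effect_multiplier must be >= 0", call. = FALSE)
  }
  if (!is.finite(session_duration) || session_duration <= 0) {
    stop("session_duration must be > 0", call. = FALSE)
  }
  if (injection_time < 0 || injection_time > session_duration) {
    stop("injection_time must lie within the session", call. = FALSE)
  }
  if (onset_time < 0 || onset_time > session_duration - injection_time) {
    stop("onset_time must lie within the post-injection window",
         call. = FALSE)
  }
  if (ramp_duration < 0) stop("ramp_duration must be >= 0", call. = FALSE)
  if (refractory < 0) stop("refractory must be >= 0", call. = FALSE)
  structure(
    list(baseline_rate = baseline_rate,
         effect_multiplier = effect_multiplier,
         onset_time = onset_time,
         ramp_duration = ramp_duration,
         refractory = refractory,
         injection_time = injection_time,
         session_duration = session_duration,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Instantaneous rate (spikes/s) of the configured piecewise-linear profile.
rate_profile <- function(config, t) {
  r0 <- config$baseline_rate
  r1 <- config$baseline_rate * config$effect_multiplier
  t_on <- config$injection_time + config$onset_time
  out <- rep(r0, length(t))
  if (config$ramp_duration > 0) {
    in_ramp <- t >= t_on & t < t_on + config$ramp_duration
    out[in_ramp] <- r0 + (r1 - r0) * (t[in_ramp] - t_on) / config$ramp_duration
    out[t >= t_on + config$ramp_duration] <- r1
  } else {
    out[t >= t_on] <- r1
  }
  out
}

# Greedy left-to-right dead-time enforcement: a spike closer than
# `refractory` to the last retained spike is deleted. Vectorised passes;
# deleting the first offender of each violation run never creates new
# violations to its left, so the loop converges in a few passes.
enforce_refractory <- function(times, refractory) {
  if (refractory <= 0 || length(times) < 2) return(times)
  repeat {
    bad <- which(diff(times) < refractory)
    if (!length(bad)) return(times)
    first_in_run <- bad[c(TRUE, diff(bad) > 1L)]
    times <- times[-(first_in_run + 1L)]
  }
}

#' Simulate a homogeneous Poisson spike train with dead time
#'
#' Draws a homogeneous Poisson process on `[0, duration)` and enforces an
#' absolute refractory period by greedy deletion. Serves as the null model
#' for baseline activity.
#'
#' @param rate Firing rate in spikes/s (>= 0).
#' @param duration Session length in seconds (> 0).
#' @param refractory Dead time in seconds (default 2 ms).
#' @param seed Integer seed.
#' @param injection_time Injection time stored on the train (default 900 s).
#' @param unit_id Unit label.
#'
#' @return A [spike_train()].
#' @export
simulate_homogeneous_train <- function(rate, duration, refractory = 0.002,
                                       seed = 1L, injection_time = 900,
                                       unit_id = "sim") {
  config <- simulation_config(
    baseline_rate = rate, effect_multiplier = 1, onset_time = 0,
    refractory = refractory, injection_time = min(injection_time, duration),
    session_duration = duration, seed = seed)
  simulate_drug_response_train(config, unit_id = unit_id)
}

#' Simulate a drug-response spike train
#'
#' Simulates an inhomogeneous Poisson process whose rate follows the
#' configured baseline / onset / post-onset profile, by thinning a
#' dominating homogeneous process at the profile's maximum rate and then
#' enforcing the refractory period by deletion. Exact for the
#' piecewise-linear rate profiles used here. The configuration is attached
#' to the train as `ground_truth`.
#'
#' @param config A [simulation_config()].
#' @param unit_id Unit label.
#' @return A [spike_train()] with `ground_truth` set.
#' @export
simulate_drug_response_train <- function(config, unit_id = "sim") {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a simulation_config", call. = FALSE)
  }
  d <- config$session_duration
  max_rate <- config$baseline_rate * max(1, config$effect_multiplier)
  set.seed(config$seed)
  if (max_rate == 0) {
    times <- numeric(0)
  } else {
    n <- stats::rpois(1L, max_rate * d)
    t_cand <- stats::runif(n, 0, d)
    u <- stats::runif(n)
    ord <- order(t_cand)
    t_cand <- t_cand[ord]
    u <- u[ord]
    keep <- u < rate_profile(config, t_cand) / max_rate
    times <- enforce_refractory(t_cand[keep], config$refractory)
  }
  spike_train(times, duration = d, injection_time = config$injection_time,
              unit_id = unit_id, ground_truth = config)
}
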