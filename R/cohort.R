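#' Group specification for cohort simulation
#'
#' Describes one treatment group as a set of response classes, each with a
#' neuron count and a multiplier range (1 for null units). Per-neuron
#' multipliers, baseline rates and onsets are drawn uniformly on their
#' ranges when a cohort is generated.
#'
#' @param label Group label.
#' @param effects A data.frame with columns `n` (neurons) and `mult_lo`,
#'   `mult_hi` (effect-multiplier range; `1, 1` for null units).
#' @param onset_min Numeric `c(lo, hi)` onset window in minutes after
#'   injection.
#' @param baseline_range Numeric `c(lo, hi)` baseline-rate range in
#'   spikes/s (pyramidal range by default).
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(label, effects, onset_min = c(42, 64),
                       baseline_range = c(2, 8)) {
  stopifnot(is.data.frame(effects),
            all(c("n", "mult_lo", "mult_hi") %in% names(effects)))
  if (nrow(effects) == 0 || sum(effects$n) < 1) {
    stop("group must contain at least one neuron", call. = FALSE)
  }
  if (any(effects$mult_lo < 0) || any(effects$mult_hi < effects$mult_lo)) {
    stop("invalid multiplier range", call. = FALSE)
  }
  structure(
    list(label = label, effects = effects, onset_min = onset_min,
         baseline_range = baseline_range,
         n_neurons = sum(effects$n)),
    class = "group_spec"
  )
}

#' Built-in cohort presets
#'
#' Per-group presets mirroring the reported response structure of a
#' saline-control and three donepezil dose groups: neuron counts per
#' response class, percent-change ranges (as multiplier ranges) and onset
#' windows. The 5 mg/kg group's effect magnitudes were not reported; the
#' modest saline-scale ranges are used for it.
#'
#' @param name One of `"saline"`, `"don5"`, `"don10"`, `"don15"`.
#' @return A [group_spec()].
#' @export
cohort_preset <- function(name = c("saline", "don5", "don10", "don15")) {
  name <- match.arg(name)
  eff <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(n = m[, 1], mult_lo = m[, 2], mult_hi = m[, 3])
  }
  switch(name,
    # 15 units: 3 excited +25..70%, 2 inhibited -60..-70%, 10 null
    saline = group_spec("saline",
      eff(3, 1.25, 1.70,
          2, 0.30, 0.40,
          10, 1.00, 1.00),
      onset_min = c(47, 56)),
    # 16 units: 3 excited, 3 inhibited, 10 null (magnitudes unreported)
    don5 = group_spec("don5",
      eff(3, 1.25, 1.70,
          3, 0.30, 0.40,
          10, 1.00, 1.00),
      onset_min = c(47, 64)),
    # 14 units: 3 at +100..115%, 4 at +160..180%, 1 at +346%,
    # 1 inhibited at -80%, 5 null
    don10 = group_spec("don10",
      eff(3, 2.00, 2.15,
          4, 2.60, 2.80,
          1, 4.46, 4.46,
          1, 0.20, 0.20,
          5, 1.00, 1.00),
      onset_min = c(47, 56)),
    # 16 units: 4 at +120..190%, 3 at +240..270%, 3 at +310..420%,
    # 2 inhibited -55..-65%, 4 null
    don15 = group_spec("don15",
      eff(4, 2.20, 2.90,
          3, 3.40, 3.70,
          3, 4.10, 5.20,
          2, 0.35, 0.45,
          4, 1.00, 1.00),
      onset_min = c(42, 61))
  )
}

# Deterministic per-unit substream seed: a function of the global seed and
# the unit's index only, so any unit can be regenerated in isolation.
derive_seed <- function(seed, index) {
  as.integer(((as.double(seed) %% 1e7) * 7919 + index * 104729) %%
               2147483647)
}

#' Generate a simulated cohort
#'
#' One spike train per neuron across one or more groups, with per-neuron
#' ground truth retained. A single global seed fans out to per-neuron
#' substreams by unit index, so cohorts are reproducible unit by unit.
#'
#' @param group_specs A [group_spec()] or list of them (see
#'   [cohort_preset()]).
#' @param seed Integer global seed.
#' @param session_duration,injection_time Session structure in seconds.
#' @param refractory Dead time in seconds passed to the simulator.
#' @param ramp_duration Onset ramp in seconds (0 = step).
#' @return A list of [spike_train()]s; each carries `ground_truth` and a
#'   `group` field.
#' @export
generate_cohort <- function(group_specs, seed = 1L,
                            session_duration = 7200, injection_time = 900,
                            refractory = 0.002, ramp_duration = 0) {
  if (inherits(group_specs, "group_spec")) group_specs <- list(group_specs)
  if (!length(group_specs)) stop("empty cohort specification", call. = FALSE)
  trains <- list()
  unit_index <- 0L
  for (gs in group_specs) {
    stopifnot(inherits(gs, "group_spec"))
    class_of_unit <- rep(seq_len(nrow(gs$effects)), gs$effects$n)
    for (j in seq_along(class_of_unit)) {
      unit_index <- unit_index + 1L
      row <- gs$effects[class_of_unit[j], ]
      set.seed(derive_seed(seed, 2L * unit_index))
      baseline <- stats::runif(1, gs$baseline_range[1], gs$baseline_range[2])
      mult <- stats::runif(1, row$mult_lo, row$mult_hi)
      onset_s <- stats::runif(1, gs$onset_min[1], gs$onset_min[2]) * 60
      config <- simulation_config(
        baseline_rate = baseline, effect_multiplier = mult,
        onset_time = onset_s, ramp_duration = ramp_duration,
        refractory = refractory, injection_time = injection_time,
        session_duration = session_duration,
        seed = derive_seed(seed, 2L * unit_index + 1L))
      id <- sprintf("%s_%02d", gs$label, j)
      tr <- simulate_drug_response_train(config, unit_id = id)
      tr$group <- gs$label
      trains[[id]] <- tr
    }
  }
  trains
}

#' Ground-truth response label of a simulated train
#'
#' @param train A simulated [spike_train()] with `ground_truth`.
#' @return `"excitatory"`, `"inhibitory"` or `"unaffected"` according to
#'   the true effect multiplier.
#' @export
ground_truth_label <- function(train) {
  gt <- train$ground_truth
  if (is.null(gt)) stop("train has no ground truth", call. = FALSE)
  if (gt$effect_multiplier > 1) {
    "excitatory"
  } else if (gt$effect_multiplier < 1) {
    "inhibitory"
  } else {
    "unaffected"
  }
}
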