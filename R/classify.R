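#' Classifier configuration
#'
#' The response rule: a unit is called excitatory (inhibitory) when at
#' least `run_length` consecutive post-injection PSTH bins lie strictly
#' above (below) the baseline mean plus (minus) `k_sd` baseline SDs.
#' Defaults encode the 2-SD, 3-consecutive-bin criterion on 60-s bins.
#'
#' @param k_sd Baseline-SD multiplier for the response band (default 2).
#' @param run_length Required consecutive qualifying bins (default 3).
#' @param bin_width PSTH bin width in seconds (default 60); also sets the
#'   SD floor used for degenerate (zero-SD) baselines: the rate equivalent
#'   of one spike per bin, so a silent-then-active unit is classifiable.
#' @param percent_scope Bins averaged for the percent change:
#'   `"qualifying"` (bins in qualifying runs, the default) or
#'   `"post_onset"` (all bins from the first qualifying run onward).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(k_sd = 2, run_length = 3, bin_width = 60,
                              percent_scope = c("qualifying", "post_onset")) {
  if (k_sd <= 0) stop("k_sd must be > 0", call. = FALSE)
  if (run_length < 1) stop("run_length must be >= 1", call. = FALSE)
  structure(
    list(k_sd = k_sd, run_length = run_length, bin_width = bin_width,
         percent_scope = match.arg(percent_scope)),
    class = "classifier_config"
  )
}

#' Pyramidal-neuron inclusion criterion
#'
#' Hippocampal pyramidal neurons are identified by a spontaneous baseline
#' rate of eight spikes per second or less (inclusive).
#'
#' @param baseline_mean_rate Baseline mean rate in spikes/s (>= 0).
#' @param max_rate Inclusion cap in spikes/s (default 8).
#' @return Logical.
#' @export
is_pyramidal <- function(baseline_mean_rate, max_rate = 8) {
  if (any(!is.finite(baseline_mean_rate)) || any(baseline_mean_rate < 0)) {
    stop("baseline_mean_rate must be >= 0", call. = FALSE)
  }
  baseline_mean_rate <= max_rate
}

# Runs of length >= run_length in a logical vector; returns a list of
# (start, length) pairs in order.
qualifying_runs <- function(flag, run_length) {
  if (!length(flag)) return(list())
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= run_length
  mapply(function(s, l) list(start = s, length = l),
         starts[sel], r$lengths[sel], SIMPLIFY = FALSE)
}

#' Classify a unit's drug response from its PSTH
#'
#' Applies the baseline-referenced band rule to the post-injection bins:
#' `run_length` consecutive bins strictly above `mean + k_sd * sd` call an
#' excitatory response, strictly below `mean - k_sd * sd` an inhibitory
#' one; otherwise the unit is unaffected. When runs of both signs occur,
#' the earlier run decides the label and both are recorded. A zero-SD
#' baseline is floored at one spike per bin (`1/bin_width` spikes/s) and
#' flagged.
#'
#' @param psth A `binned_rate` from [make_psth()].
#' @param baseline A [baseline_statistics()] result.
#' @param injection_time Injection time in seconds (defaults to the
#'   PSTH's).
#' @param config A [classifier_config()].
#' @return An object of class `response_classification`: `label`
#'   (excitatory / inhibitory / unaffected), `onset_latency_min`,
#'   `percent_change`, `qualifying_bins` (PSTH bin indices of the
#'   label-defining runs), `runs_excitatory` / `runs_inhibitory`,
#'   `degenerate_baseline`, and threshold bookkeeping.
#' @export
classify_response <- function(psth, baseline,
                              injection_time = psth$injection_time,
                              config = classifier_config()) {
  stopifnot(inherits(psth, "binned_rate"), inherits(baseline, "baseline_stats"),
            inherits(config, "classifier_config"))
  if (is.null(injection_time)) stop("injection_time required", call. = FALSE)
  sd_used <- baseline$sd_rate
  degenerate <- sd_used == 0
  if (degenerate) sd_used <- 1 / psth$bin_width
  upper <- baseline$mean_rate + config$k_sd * sd_used
  lower <- baseline$mean_rate - config$k_sd * sd_used

  post <- psth$bin_starts >= injection_time - 1e-9
  post_idx <- which(post)
  rates <- psth$rates[post]
  runs_ex <- qualifying_runs(rates > upper, config$run_length)
  runs_in <- qualifying_runs(rates < lower, config$run_length)

  first_start <- function(runs) if (length(runs)) runs[[1]]$start else Inf
  label <- "unaffected"
  if (is.finite(first_start(runs_ex)) || is.finite(first_start(runs_in))) {
    label <- if (first_start(runs_ex) <= first_start(runs_in)) {
      "excitatory"
    } else {
      "inhibitory"
    }
  }
  winning <- switch(label, excitatory = runs_ex, inhibitory = runs_in,
                    unaffected = list())
  qbins <- integer(0)
  for (run in winning) {
    qbins <- c(qbins, post_idx[run$start + seq_len(run$length) - 1L])
  }
  out <- structure(
    list(label = label, qualifying_bins = qbins,
         runs_excitatory = runs_ex, runs_inhibitory = runs_in,
         degenerate_baseline = degenerate,
         upper_threshold = upper, lower_threshold = lower,
         injection_time = injection_time,
         bin_width = psth$bin_width,
         first_run_start_s = if (length(qbins)) {
           psth$bin_starts[qbins[1]]
         } else {
           NA_real_
         },
         onset_latency_min = NA_real_, percent_change = NA_real_,
         excluded = FALSE, exclusion_reason = NA_character_),
    class = "response_classification"
  )
  if (label != "unaffected") {
    out$onset_latency_min <- onset_latency(out, injection_time)
    if (baseline$mean_rate > 0) {
      out$percent_change <- percent_change(psth, baseline, out,
                                           scope = config$percent_scope)
    }
  }
  out
}

#' @export
print.response_classification <- function(x, ...) {
  if (x$label == "unaffected") {
    cat("<response_classification> unaffected\n")
  } else {
    cat(sprintf(
      "<response_classification> %s: onset %.1f min, %s%.0f%%%s\n",
      x$label, x$onset_latency_min,
      if (x$percent_change >= 0) "+" else "", x$percent_change,
      if (x$degenerate_baseline) " (degenerate baseline)" else ""))
  }
  invisible(x)
}

#' Onset latency of a classified response
#'
#' Time from the injection to the start of the first qualifying run, in
#' minutes.
#'
#' @param classification A [classify_response()] result with a non-null
#'   label.
#' @param injection_time Injection time in seconds.
#' @return Latency in minutes.
#' @export
onset_latency <- function(classification,
                          injection_time = classification$injection_time) {
  stopifnot(inherits(classification, "response_classification"))
  if (classification$label == "unaffected") {
    stop("onset latency undefined for an unaffected unit", call. = FALSE)
  }
  (classification$first_run_start_s - injection_time) / 60
}

#' Percent change of a classified response
#'
#' `100 * (mean qualifying-run rate - baseline mean) / baseline mean`;
#' negative for inhibition (a value of -80 is reported as an 80 percent
#' reduction). With `scope = "post_onset"` the mean is instead taken over
#' every post-injection bin from the first qualifying run onward.
#'
#' @param psth The `binned_rate` the unit was classified from.
#' @param baseline The unit's [baseline_statistics()].
#' @param classification The [classify_response()] result.
#' @param scope `"qualifying"` or `"post_onset"`.
#' @return Percent change relative to the baseline mean.
#' @export
percent_change <- function(psth, baseline, classification,
                           scope = c("qualifying", "post_onset")) {
  stopifnot(inherits(classification, "response_classification"))
  scope <- match.arg(scope)
  if (classification$label == "unaffected") {
    stop("percent change undefined for an unaffected unit", call. = FALSE)
  }
  if (baseline$mean_rate <= 0) {
    stop("percent change undefined for a zero baseline mean", call. = FALSE)
  }
  bins <- if (scope == "qualifying") {
    classification$qualifying_bins
  } else {
    seq(min(classification$qualifying_bins), length(psth$rates))
  }
  100 * (mean(psth$rates[bins]) - baseline$mean_rate) / baseline$mean_rate
}
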