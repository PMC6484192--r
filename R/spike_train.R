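#' Spike train container
#'
#' An ordered set of extracellular action-potential times for one unit over
#' one recording session. Times are in seconds from the start of the
#' recording; `injection_time` marks the drug (or vehicle) injection that
#' splits the session into a baseline and a post-injection window.
#'
#' @param times Numeric vector of event times in seconds. Sorted on input;
#'   must lie in `[0, duration)`.
#' @param duration Session length in seconds.
#' @param injection_time Injection time in seconds from recording start.
#' @param unit_id Character label for the unit.
#' @param ground_truth Optional [simulation_config()] retained when the
#'   train is synthetic, for recovery tests.
#'
#' @return An object of class `spike_train` with fields `times`,
#'   `duration`, `injection_time`, `unit_id` and (optionally)
#'   `ground_truth`.
#' @export
spike_train <- function(times, duration, injection_time = 900,
                        unit_id = "unit", ground_truth = NULL) {
  times <- as.numeric(times)
  if (length(times) && any(!is.finite(times))) {
    stop("spike times must be finite", call. = FALSE)
  }
  if (!is.finite(duration) || duration <= 0) {
    stop("duration must be a positive number", call. = FALSE)
  }
  if (!is.finite(injection_time) || injection_time < 0 ||
      injection_time > duration) {
    stop("injection_time must lie within [0, duration]", call. = FALSE)
  }
  if (length(times) && (min(times) < 0 || max(times) >= duration)) {
    stop("spike times must lie in [0, duration)", call. = FALSE)
  }
  if (is.unsorted(times, strictly = FALSE)) {
    warning("spike times were not sorted; sorting", call. = FALSE)
    times <- sort(times)
  }
  structure(
    list(times = times, duration = duration,
         injection_time = injection_time, unit_id = unit_id,
         ground_truth = ground_truth),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf(
    "<spike_train> %s: %d spikes over %.0f s (injection at %.0f s, mean rate %.3f Hz)\n",
    x$unit_id, length(x$times), x$duration, x$injection_time,
    length(x$times) / x$duration))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Mean firing rate over a time window
#'
#' @param train A [spike_train()].
#' @param t_start,t_end Window limits in seconds (half-open `[t_start,
#'   t_end)`).
#' @return Rate in spikes/s.
#' @export
mean_rate <- function(train, t_start = 0, t_end = train$duration) {
  stopifnot(inherits(train, "spike_train"))
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  n <- sum(train$times >= t_start & train$times < t_end)
  n / (t_end - t_start)
}
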