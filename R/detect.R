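#' Detection configuration
#'
#' Parameters of the threshold-and-window spike detector. The detector
#' thresholds a lightly smoothed copy of the trace at `threshold_k`
#' multiples of the smoothed noise SD, reports the raw-signal peak of each
#' excursion, and (optionally) retains only events whose peak height falls
#' in `height_window`. Units with mean-peak SNR at or below `min_snr` are
#' flagged for exclusion downstream.
#'
#' @param threshold_k Detection threshold in multiples of the (smoothed)
#'   noise SD. Default 4.
#' @param height_window Numeric `c(low, high)` spike-height acceptance
#'   window in signal units; default `c(0, Inf)` (no discrimination).
#' @param min_snr Minimum unit signal-to-noise ratio for inclusion
#'   (mean peak height over noise SD); the criterion is strict (`> min_snr`).
#' @param dead_time Detector dead time in seconds, measured from the
#'   trigger (excursion onset): retriggers within it extend the excursion
#'   rather than producing a new event. Default 1.5 ms, long enough to
#'   span a biphasic waveform's after-lobe while staying below a
#'   physiological refractory period.
#' @param smooth_width Boxcar pre-smoothing width in seconds; default
#'   0.25 ms, a quarter of the default waveform width. Set 0 to disable.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(threshold_k = 4, height_window = c(0, Inf),
                             min_snr = 2, dead_time = 0.0015,
                             smooth_width = 0.00025) {
  if (length(height_window) != 2 || height_window[1] >= height_window[2]) {
    stop("height_window must be c(low, high) with low < high", call. = FALSE)
  }
  if (min_snr <= 0) stop("min_snr must be > 0", call. = FALSE)
  if (threshold_k <= 0) stop("threshold_k must be > 0", call. = FALSE)
  structure(
    list(threshold_k = threshold_k, height_window = height_window,
         min_snr = min_snr, dead_time = dead_time,
         smooth_width = smooth_width),
    class = "detection_config"
  )
}

#' Robust noise SD of a voltage trace
#'
#' Median absolute deviation of the raw signal, scaled to the Gaussian SD.
#' Robust to the small fraction of samples occupied by spikes at
#' physiological firing rates.
#'
#' @param trace A [voltage_trace()].
#' @return Noise SD estimate in signal units.
#' @export
estimate_noise_sd <- function(trace) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (!length(trace$samples)) stop("empty trace", call. = FALSE)
  stats::mad(trace$samples, center = stats::median(trace$samples))
}

boxcar <- function(x, k) {
  if (k <= 1L) return(x)
  y <- stats::filter(x, rep(1 / k, k), sides = 2)
  y[is.na(y)] <- 0
  as.numeric(y)
}

#' Detect spikes by threshold crossing
#'
#' Finds excursions of the (smoothed) absolute signal above
#' `threshold_k` times the smoothed noise SD and reports one event per
#' excursion at the raw-signal peak. Retriggers within `dead_time` of an
#' excursion's onset extend that excursion rather than opening a new one.
#' Absolute-value thresholding handles negative-going extracellular
#' spikes with one code path.
#'
#' @param trace A [voltage_trace()].
#' @param config A [detection_config()].
#' @return A data.frame with columns `time` (s, peak sample) and
#'   `peak_height` (absolute raw peak, signal units), ordered by time.
#' @export
detect_spikes <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "voltage_trace"),
            inherits(config, "detection_config"))
  fs <- trace$sampling_rate
  k <- max(1L, round(config$smooth_width * fs))
  sm <- boxcar(trace$samples, k)
  noise_sm <- stats::mad(sm, center = stats::median(sm))
  thr <- config$threshold_k * noise_sm
  above <- abs(sm) > thr
  if (!any(above)) {
    return(data.frame(time = numeric(0), peak_height = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  # dead time runs from the trigger (excursion start), as in a hardware
  # discriminator: a retrigger within dead_time of the previous trigger —
  # e.g. a spike's after-lobe — extends that excursion instead of
  # producing a new event
  dead_n <- config$dead_time * fs
  merged_s <- starts[1]
  merged_e <- ends[1]
  if (length(starts) > 1) {
    for (j in 2:length(starts)) {
      last <- length(merged_s)
      if (starts[j] - merged_s[last] < dead_n) {
        merged_e[last] <- max(merged_e[last], ends[j])
      } else {
        merged_s <- c(merged_s, starts[j])
        merged_e <- c(merged_e, ends[j])
      }
    }
  }
  half <- k %/% 2 + 1L
  n <- length(trace$samples)
  times <- numeric(length(merged_s))
  peaks <- numeric(length(merged_s))
  for (j in seq_along(merged_s)) {
    lo <- max(1L, merged_s[j] - half)
    hi <- min(n, merged_e[j] + half)
    seg <- abs(trace$samples[lo:hi])
    i_pk <- lo + which.max(seg) - 1L
    times[j] <- (i_pk - 1L) / fs
    peaks[j] <- abs(trace$samples[i_pk])
  }
  data.frame(time = times, peak_height = peaks)
}

#' Spike-height window discrimination
#'
#' Retains the events whose peak height falls inside the window — the
#' software analogue of a hardware window discriminator assigning
#' threshold crossings to a unit by spike amplitude. A pure filter: output
#' times are a subset of input times, order preserved.
#'
#' @param events Event data.frame from [detect_spikes()].
#' @param height_window Numeric `c(low, high)`, inclusive bounds in signal
#'   units.
#' @param duration Session duration for the returned train (s).
#' @param injection_time Injection time for the returned train (s).
#' @param unit_id Unit label.
#' @return A [spike_train()] of the retained event times.
#' @export
discriminate_unit <- function(events, height_window, duration,
                              injection_time = 900, unit_id = "detected") {
  if (length(height_window) != 2 || height_window[1] >= height_window[2]) {
    stop("height_window must be c(low, high) with low < high", call. = FALSE)
  }
  keep <- events$peak_height >= height_window[1] &
    events$peak_height <= height_window[2]
  spike_train(events$time[keep], duration = duration,
              injection_time = injection_time, unit_id = unit_id)
}

#' Unit signal-to-noise ratio
#'
#' Mean spike peak height over the background noise SD. Units are retained
#' only when this exceeds `min_snr` (default criterion: SNR > 2); a unit
#' with no events has undefined SNR and is excluded.
#'
#' @param events Event data.frame from [detect_spikes()].
#' @param noise_sd Background noise SD (> 0).
#' @return SNR (dimensionless); `NA` if there are no events.
#' @export
unit_snr <- function(events, noise_sd) {
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    stop("noise_sd must be > 0", call. = FALSE)
  }
  if (!nrow(events)) return(NA_real_)
  mean(events$peak_height) / noise_sd
}

#' Score detected spikes against ground truth
#'
#' Greedy one-to-one matching of detected to true spike times within a
#' tolerance; reports recall and precision.
#'
#' @param true_times True spike times (s).
#' @param detected_times Detected spike times (s).
#' @param tol Matching tolerance in seconds (default 1 ms).
#' @return List with `recall`, `precision`, `n_matched`, `n_true`,
#'   `n_detected`.
#' @export
detection_performance <- function(true_times, detected_times, tol = 0.001) {
  n_true <- length(true_times)
  n_det <- length(detected_times)
  if (!n_true || !n_det) {
    return(list(recall = if (n_true) 0 else NA_real_,
                precision = if (n_det) 0 else NA_real_,
                n_matched = 0L, n_true = n_true, n_detected = n_det))
  }
  true_times <- sort(true_times)
  detected_times <- sort(detected_times)
  used <- rep(FALSE, n_true)
  matched <- 0L
  j <- 1L
  for (t in detected_times) {
    while (j <= n_true && (used[j] || true_times[j] < t - tol)) j <- j + 1L
    if (j <= n_true && abs(true_times[j] - t) <= tol) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(recall = matched / n_true, precision = matched / n_det,
       n_matched = matched, n_true = n_true, n_detected = n_det)
}
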