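#' Voltage trace container
#'
#' A uniformly sampled extracellular signal, used to exercise the spike
#' detection stage. Synthetic traces carry the true spike times for
#' recovery scoring.
#'
#' @param samples Numeric vector of signal values.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param noise_sd Noise standard deviation used at synthesis (if known).
#' @param true_spike_times True spike times in seconds (if synthetic).
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(samples, sampling_rate, noise_sd = NA_real_,
                          true_spike_times = NULL) {
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be > 0", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         noise_sd = noise_sd, true_spike_times = true_spike_times,
         duration = length(samples) / sampling_rate),
    class = "voltage_trace"
  )
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples at %.0f Hz (%.2f s)\n",
              length(x$samples), x$sampling_rate, x$duration))
  invisible(x)
}

# Biphasic extracellular spike template sampled at `fs`. Support runs from
# -width/2 to +width: a positive cosine main lobe of full width `width`
# peaking (exactly `peak_amplitude`) at offset 0, followed by a negative
# after-lobe of 0.35x amplitude peaking at +0.75*width.
spike_template <- function(peak_amplitude, width, fs) {
  k0 <- floor(width / 2 * fs)
  k1 <- floor(width * fs)
  tau <- (-k0:k1) / fs
  w <- numeric(length(tau))
  main <- tau <= width / 2
  w[main] <- peak_amplitude * cos(pi * tau[main] / width)
  after <- tau > width / 2
  w[after] <- -0.35 * peak_amplitude *
    sin(pi * (tau[after] - width / 2) / (width / 2))
  list(values = w, offsets = -k0:k1)
}

#' Synthesize an extracellular voltage trace from a spike train
#'
#' Adds a biphasic spike waveform at each spike time on top of white
#' Gaussian noise. The constructed signal-to-noise ratio is
#' `peak_amplitude / noise_sd`.
#'
#' @param train A [spike_train()].
#' @param peak_amplitude Waveform peak in signal units.
#' @param waveform_width Main-lobe width in seconds (default 1 ms).
#' @param noise_sd Gaussian noise SD in signal units.
#' @param sampling_rate Sampling rate in Hz; must resolve the waveform
#'   (`sampling_rate >= 10 / waveform_width`).
#' @param seed Integer seed for the noise.
#' @return A [voltage_trace()] with `true_spike_times = train$times`.
#' @export
synthesize_voltage <- function(train, peak_amplitude = 5,
                               waveform_width = 0.001, noise_sd = 1,
                               sampling_rate = 20000, seed = 1L) {
  stopifnot(inherits(train, "spike_train"))
  if (sampling_rate < 10 / waveform_width) {
    stop("waveform under-sampled: need sampling_rate >= 10 / waveform_width",
         call. = FALSE)
  }
  n <- round(train$duration * sampling_rate)
  set.seed(seed)
  x <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  tmpl <- spike_template(peak_amplitude, waveform_width, sampling_rate)
  for (t in train$times) {
    i0 <- round(t * sampling_rate) + 1L
    idx <- i0 + tmpl$offsets
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + tmpl$values[ok]
  }
  voltage_trace(x, sampling_rate, noise_sd = noise_sd,
                true_spike_times = train$times)
}
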