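#' Bin spike counts over a time range
#'
#' Counts spikes in half-open, fixed-width bins `[t, t + bin_width)`
#' starting at `t_start`. A trailing partial bin is dropped and recorded in
#' the `dropped_s` field, so the conservation invariant (total counts equal
#' spikes in the covered range) always holds on the covered range.
#'
#' @param train A [spike_train()].
#' @param bin_width Bin width in seconds (> 0).
#' @param t_start,t_end Range to bin (defaults: the full session).
#' @return An object of class `binned_rate` with fields `bin_width`,
#'   `t_start`, `counts`, `rates` (spikes/s), `bin_starts` and `dropped_s`
#'   (length of any dropped partial bin).
#' @export
bin_counts <- function(train, bin_width, t_start = 0,
                       t_end = train$duration) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("bin_width must be > 0", call. = FALSE)
  }
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  n_bins <- floor((t_end - t_start) / bin_width + 1e-9)
  if (n_bins < 1) stop("range shorter than one bin", call. = FALSE)
  dropped <- (t_end - t_start) - n_bins * bin_width
  idx <- floor((train$times - t_start) / bin_width)
  idx <- idx[idx >= 0 & idx < n_bins]
  counts <- tabulate(idx + 1L, nbins = n_bins)
  structure(
    list(bin_width = bin_width, t_start = t_start, counts = counts,
         rates = counts / bin_width,
         bin_starts = t_start + (seq_len(n_bins) - 1L) * bin_width,
         dropped_s = dropped),
    class = "binned_rate"
  )
}

#' @export
print.binned_rate <- function(x, ...) {
  cat(sprintf(
    "<binned_rate> %d bins of %.0f s from %.0f s (mean %.3f Hz)\n",
    length(x$counts), x$bin_width, x$t_start, mean(x$rates)))
  invisible(x)
}

#' Peri-stimulus time histogram of a session
#'
#' Bins the whole session into fixed-width bins (60 s by default), the
#' representation on which response classification operates. A 7200-s
#' session with injection at 900 s yields 120 bins: 15 baseline and 105
#' post-injection. The train's injection time is carried on the result.
#'
#' @param train A [spike_train()].
#' @param bin_width Bin width in seconds (default 60).
#' @return A `binned_rate` with an `injection_time` field.
#' @export
make_psth <- function(train, bin_width = 60) {
  stopifnot(inherits(train, "spike_train"))
  if (train$duration < bin_width) {
    stop("session shorter than one bin", call. = FALSE)
  }
  psth <- bin_counts(train, bin_width, 0, train$duration)
  psth$injection_time <- train$injection_time
  psth
}

#' Baseline firing statistics
#'
#' Mean and sample SD (denominator n - 1) of the pre-injection bin rates —
#' the reference quantities for response classification. Only bins that end
#' at or before the injection count as baseline.
#'
#' @param psth A `binned_rate` from [make_psth()].
#' @param injection_time Injection time in seconds (defaults to the PSTH's
#'   own, when present).
#' @return An object of class `baseline_stats` with `mean_rate`, `sd_rate`,
#'   `n_bins` and a `degenerate` flag (TRUE when `sd_rate` is 0).
#' @export
baseline_statistics <- function(psth, injection_time = psth$injection_time) {
  stopifnot(inherits(psth, "binned_rate"))
  if (is.null(injection_time)) stop("injection_time required", call. = FALSE)
  base <- psth$bin_starts + psth$bin_width <= injection_time + 1e-9
  n <- sum(base)
  if (n < 2) stop("need at least 2 complete baseline bins", call. = FALSE)
  r <- psth$rates[base]
  structure(
    list(mean_rate = mean(r), sd_rate = stats::sd(r), n_bins = n,
         degenerate = stats::sd(r) == 0),
    class = "baseline_stats"
  )
}
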