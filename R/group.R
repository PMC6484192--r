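#' Paired pre/post t test
#'
#' Two-tailed paired Student t test of per-neuron post-injection mean
#' rates against baseline mean rates: `t = mean(d) / (sd(d)/sqrt(n))` with
#' `d = post - baseline` and `n - 1` degrees of freedom.
#'
#' @param baseline_means Per-neuron baseline mean rates (spikes/s).
#' @param post_means Per-neuron post-injection mean rates, same order.
#' @return An object of class `ttest_result`: `t`, `df`, `p`, `n`,
#'   `mean_diff`, `sem_diff`.
#' @export
paired_t <- function(baseline_means, post_means) {
  if (length(baseline_means) != length(post_means)) {
    stop("baseline and post vectors must have equal length", call. = FALSE)
  }
  n <- length(baseline_means)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- post_means - baseline_means
  if (stats::sd(d) == 0) {
    stop("zero-variance differences: paired test degenerate", call. = FALSE)
  }
  tt <- stats::t.test(post_means, baseline_means, paired = TRUE)
  structure(
    list(t = unname(tt$statistic),
         df = as.integer(round(unname(tt$parameter))),
         p = tt$p.value, n = n, mean_diff = mean(d),
         sem_diff = stats::sd(d) / sqrt(n)),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf(
    "<ttest_result> t = %.3f, df = %d, p = %.4g (n = %d pairs, mean diff %.3f +/- %.3f Hz)\n",
    x$t, x$df, x$p, x$n, x$mean_diff, x$sem_diff))
  invisible(x)
}

unit_window_means <- function(train) {
  c(baseline = mean_rate(train, 0, train$injection_time),
    post = mean_rate(train, train$injection_time, train$duration))
}

#' Summarize a treatment group
#'
#' Response-class counts, the paired pre/post t test on per-neuron mean
#' rates, and a per-bin mean +/- SEM time course across the included
#' units. Units flagged excluded in their classification are omitted from
#' counts and the test but tallied.
#'
#' @param classifications List of [classify_response()] results, one per
#'   unit.
#' @param sessions List of matching [spike_train()]s, same order.
#' @param label Group label for the report.
#' @param bin_width Time-course bin width in seconds (default 60).
#' @return An object of class `group_result`: `label`, `n_neurons`,
#'   `counts` (excitatory / inhibitory / unaffected), `n_excluded`,
#'   `ttest` (or NULL when degenerate, with a `ttest_note`), and
#'   `timecourse` (data.frame: bin_start_s, mean_hz, sem_hz).
#' @export
summarize_group <- function(classifications, sessions, label = "group",
                            bin_width = 60) {
  if (length(classifications) != length(sessions) || !length(sessions)) {
    stop("classifications and sessions must be matched and nonempty",
         call. = FALSE)
  }
  excluded <- vapply(classifications, function(cl) isTRUE(cl$excluded),
                     logical(1))
  if (all(excluded)) stop("all units excluded", call. = FALSE)
  inc <- which(!excluded)
  labels <- vapply(classifications[inc], function(cl) cl$label, character(1))
  counts <- c(excitatory = sum(labels == "excitatory"),
              inhibitory = sum(labels == "inhibitory"),
              unaffected = sum(labels == "unaffected"))

  wm <- vapply(sessions[inc], unit_window_means, numeric(2))
  ttest <- NULL
  ttest_note <- NA_character_
  if (length(inc) >= 2 && stats::sd(wm["post", ] - wm["baseline", ]) > 0) {
    ttest <- paired_t(wm["baseline", ], wm["post", ])
  } else {
    ttest_note <- "degenerate or undersized group; no paired test"
  }

  rates <- vapply(sessions[inc],
                  function(tr) make_psth(tr, bin_width)$rates,
                  numeric(floor(sessions[[inc[1]]]$duration / bin_width)))
  rates <- matrix(rates, ncol = length(inc))
  n <- length(inc)
  timecourse <- data.frame(
    bin_start_s = (seq_len(nrow(rates)) - 1L) * bin_width,
    mean_hz = rowMeans(rates),
    sem_hz = apply(rates, 1, stats::sd) / sqrt(n))

  structure(
    list(label = label, n_neurons = length(sessions),
         n_included = length(inc), counts = counts,
         n_excluded = sum(excluded), ttest = ttest,
         ttest_note = ttest_note, timecourse = timecourse),
    class = "group_result"
  )
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf(
    "<group_result> %s: n = %d (%d excluded); excitatory %d, inhibitory %d, unaffected %d\n",
    x$label, x$n_neurons, x$n_excluded,
    x$counts[["excitatory"]], x$counts[["inhibitory"]],
    x$counts[["unaffected"]]))
  if (!is.null(x$ttest)) print(x$ttest)
  invisible(x)
}

#' Per-unit baseline/post scatter table
#'
#' One row per included unit with its baseline and post-injection mean
#' rates and its response label — the table behind baseline-versus-post
#' scatterplots.
#'
#' @param sessions List of [spike_train()]s.
#' @param classifications Matching list of [classify_response()] results.
#' @return A data.frame with columns `unit_id`, `baseline_hz`, `post_hz`,
#'   `label`.
#' @export
response_scatter <- function(sessions, classifications) {
  if (length(sessions) != length(classifications)) {
    stop("sessions and classifications must be matched", call. = FALSE)
  }
  rows <- lapply(seq_along(sessions), function(i) {
    cl <- classifications[[i]]
    if (isTRUE(cl$excluded)) return(NULL)
    wm <- unit_window_means(sessions[[i]])
    data.frame(unit_id = sessions[[i]]$unit_id,
               baseline_hz = wm[["baseline"]], post_hz = wm[["post"]],
               label = cl$label)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(unit_id = character(0), baseline_hz = numeric(0),
                      post_hz = numeric(0), label = character(0)))
  }
  do.call(rbind, rows)
}
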