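#' Read spike times from a plain-text timestamp file
#'
#' One event time in seconds per line; blank lines and `#` comments are
#' ignored. Out-of-order input is sorted with a warning; non-numeric lines
#' raise a parse error naming the line.
#'
#' @param path File path.
#' @param duration Session duration in seconds (default 7200).
#' @param injection_time Injection time in seconds (default 900).
#' @param unit_id Unit label (defaults to the file name).
#' @return A [spike_train()].
#' @export
read_spike_times <- function(path, duration = 7200, injection_time = 900,
                             unit_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(body)))
  vals <- suppressWarnings(as.numeric(trimws(body[keep])))
  if (anyNA(vals)) {
    bad <- keep[which(is.na(vals))[1]]
    stop(sprintf("non-numeric value at %s line %d", path, bad),
         call. = FALSE)
  }
  if (length(vals) && any(vals < 0)) {
    stop("negative spike time in ", path, call. = FALSE)
  }
  if (is.null(unit_id)) unit_id <- tools::file_path_sans_ext(basename(path))
  if (!length(vals)) warning("empty spike file: ", path, call. = FALSE)
  spike_train(vals, duration = duration, injection_time = injection_time,
              unit_id = unit_id)
}

#' Write spike times to a plain-text timestamp file
#'
#' Seconds, one per line, 17 significant digits so a write/read round trip
#' reproduces the timestamps exactly.
#'
#' @param train A [spike_train()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_times <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  header <- sprintf(
    "# unit_id: %s\n# duration_s: %.17g\n# injection_time_s: %.17g",
    train$unit_id, train$duration, train$injection_time)
  writeLines(c(header, sprintf("%.17g", train$times)), path)
  invisible(path)
}

#' Write / read a voltage trace as CSV
#'
#' Two columns (`time_s`, `value`) with a header; the sampling rate is
#' recovered from the time column on read.
#'
#' @param trace A [voltage_trace()].
#' @param path File path.
#' @return `path` invisibly (write); a [voltage_trace()] (read).
#' @export
write_voltage_csv <- function(trace, path) {
  stopifnot(inherits(trace, "voltage_trace"))
  t <- (seq_along(trace$samples) - 1) / trace$sampling_rate
  utils::write.csv(data.frame(time_s = t, value = trace$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_voltage_csv
#' @export
read_voltage_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  if (nrow(d) < 2) stop("voltage CSV needs at least 2 samples", call. = FALSE)
  fs <- 1 / stats::median(diff(d$time_s))
  voltage_trace(d$value, sampling_rate = fs)
}

#' Pipeline configuration
#'
#' Declarative settings for the end-to-end analysis, defaulting to the
#' study design: a 7200-s session, injection at 900 s (15-min baseline,
#' 105-min post window), 60-s PSTH bins over 1000-ms acquisition bins, a
#' 2-SD / 3-consecutive-bin response rule, the pyramidal inclusion cap of
#' 8 spikes/s, and an SNR > 2 unit-isolation criterion.
#'
#' @param session_duration,injection_time Session structure in seconds.
#' @param psth_bin_width PSTH bin width in seconds.
#' @param acquisition_bin_width Acquisition bin width in seconds.
#' @param k_sd,run_length Classifier band width and run requirement.
#' @param pyramidal_max_rate Baseline-rate inclusion cap (spikes/s).
#' @param min_snr Unit SNR inclusion threshold (strict `>`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(session_duration = 7200, injection_time = 900,
                            psth_bin_width = 60, acquisition_bin_width = 1,
                            k_sd = 2, run_length = 3,
                            pyramidal_max_rate = 8, min_snr = 2) {
  stopifnot(session_duration > 0, injection_time > 0,
            injection_time < session_duration, psth_bin_width > 0)
  structure(
    list(session_duration = session_duration,
         injection_time = injection_time,
         psth_bin_width = psth_bin_width,
         acquisition_bin_width = acquisition_bin_width,
         classifier = classifier_config(k_sd = k_sd,
                                        run_length = run_length,
                                        bin_width = psth_bin_width),
         pyramidal_max_rate = pyramidal_max_rate,
         min_snr = min_snr),
    class = "pipeline_config"
  )
}

#' Classify one unit end to end
#'
#' PSTH construction, baseline statistics, the pyramidal inclusion filter
#' and response classification for a single session. Non-pyramidal units
#' (baseline mean above the cap) and units failing a supplied SNR are
#' classified but flagged excluded.
#'
#' @param train A [spike_train()].
#' @param config A [pipeline_config()].
#' @param snr Optional unit SNR from the detection stage; `NA` (no events)
#'   excludes the unit.
#' @return A [classify_response()] result with exclusion flags set.
#' @export
classify_unit <- function(train, config = pipeline_config(), snr = NULL) {
  psth <- make_psth(train, config$psth_bin_width)
  baseline <- baseline_statistics(psth, train$injection_time)
  cl <- classify_response(psth, baseline, train$injection_time,
                          config$classifier)
  if (!is_pyramidal(baseline$mean_rate, config$pyramidal_max_rate)) {
    cl$excluded <- TRUE
    cl$exclusion_reason <- "non_pyramidal"
  } else if (!is.null(snr) && (is.na(snr) || snr <= config$min_snr)) {
    cl$excluded <- TRUE
    cl$exclusion_reason <- "low_snr"
  }
  cl
}

#' Run the full analysis over a session manifest
#'
#' Reads every session listed in the manifest (or accepts in-memory
#' trains), classifies each unit, and produces per-group summaries.
#' Deterministic given inputs; reports are written under `out_dir` when
#' given (per-unit TSV + JSON, per-group JSON, time-course and scatter
#' TSV).
#'
#' @param manifest A data.frame with columns `unit_id`, `group`,
#'   `spike_file` and optionally `injection_time` (s), `duration` (s),
#'   `dose`; or a named list of [spike_train()]s with `group` fields.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List with `units` (per-unit classification table), `groups`
#'   (list of [summarize_group()] results) and `scatter`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.data.frame(manifest)) {
    needed <- c("unit_id", "group", "spike_file")
    if (!all(needed %in% names(manifest))) {
      stop("manifest needs columns: ", paste(needed, collapse = ", "),
           call. = FALSE)
    }
    missing <- manifest$spike_file[!file.exists(manifest$spike_file)]
    if (length(missing)) {
      stop("missing spike file(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    trains <- lapply(seq_len(nrow(manifest)), function(i) {
      inj <- if ("injection_time" %in% names(manifest)) {
        manifest$injection_time[i]
      } else {
        config$injection_time
      }
      dur <- if ("duration" %in% names(manifest)) {
        manifest$duration[i]
      } else {
        config$session_duration
      }
      tr <- read_spike_times(manifest$spike_file[i], duration = dur,
                             injection_time = inj,
                             unit_id = manifest$unit_id[i])
      tr$group <- manifest$group[i]
      tr
    })
  } else {
    trains <- manifest
    if (!length(trains)) stop("empty manifest", call. = FALSE)
  }

  classifications <- lapply(trains, classify_unit, config = config)
  units <- do.call(rbind, lapply(seq_along(trains), function(i) {
    cl <- classifications[[i]]
    data.frame(
      unit_id = trains[[i]]$unit_id,
      group = if (is.null(trains[[i]]$group)) "all" else trains[[i]]$group,
      label = cl$label,
      onset_min = cl$onset_latency_min,
      percent_change = cl$percent_change,
      degenerate_baseline = cl$degenerate_baseline,
      excluded = cl$excluded,
      reason = cl$exclusion_reason)
  }))

  groups <- lapply(split(seq_along(trains), units$group), function(idx) {
    summarize_group(classifications[idx], trains[idx],
                    label = units$group[idx[1]],
                    bin_width = config$psth_bin_width)
  })
  scatter <- response_scatter(trains, classifications)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(units, file.path(out_dir, "classifications.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(units, file.path(out_dir, "classifications.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    grp_json <- lapply(groups, function(g) {
      list(label = g$label, n_neurons = g$n_neurons,
           n_included = g$n_included, n_excluded = g$n_excluded,
           counts = as.list(g$counts),
           ttest = if (is.null(g$ttest)) NULL else unclass(g$ttest))
    })
    jsonlite::write_json(grp_json, file.path(out_dir, "group_stats.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    for (g in groups) {
      utils::write.table(
        g$timecourse,
        file.path(out_dir, sprintf("timecourse_%s.tsv", g$label)),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    utils::write.table(scatter, file.path(out_dir, "scatter.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(units = units, groups = groups, scatter = scatter)
}

#' Export a binned series as TSV
#'
#' @param binned A `binned_rate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binned_tsv <- function(binned, path) {
  stopifnot(inherits(binned, "binned_rate"))
  utils::write.table(
    data.frame(bin_start_s = binned$bin_starts, count = binned$counts,
               rate_hz = binned$rates),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
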