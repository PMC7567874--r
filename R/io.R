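# Recording container, serialization, and the standard preprocessing chain:
# line-noise removal, channel exclusion, common-average reference, epoching.

#' Construct a multichannel recording
#'
#' The package's core container: a channels x samples matrix with its sample
#' rate, channel identifiers, electrode table, and event table.
#'
#' @param data numeric matrix, channels x samples.
#' @param sample_rate_hz sampling rate (Hz).
#' @param channel_ids character vector, one id per row of `data`.
#' @param electrode_table data.frame with at least an `id` column matching
#'   `channel_ids`.
#' @param events data.frame with columns `onset_s`, `duration_s`, `type`,
#'   `trial_id` (may have zero rows).
#' @return An object of class `recording`.
#' @export
recording <- function(data, sample_rate_hz, channel_ids = NULL,
                      electrode_table = NULL, events = NULL) {
  data <- as.matrix(data)
  if (anyNA(data) || any(!is.finite(data)))
    stop("recording data must be finite with no NA")
  assert_scalar_pos(sample_rate_hz, "sample_rate_hz")
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%03d", seq_len(nrow(data)))
  if (length(channel_ids) != nrow(data))
    stop("channel_ids must match the number of data rows")
  if (anyDuplicated(channel_ids)) stop("channel ids must be unique")
  if (!is.null(electrode_table) && !all(channel_ids %in% electrode_table$id))
    stop("channel_ids must all appear in the electrode table")
  if (is.null(events))
    events <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                         type = character(0), trial_id = integer(0))
  req <- c("onset_s", "duration_s", "type", "trial_id")
  if (!all(req %in% names(events)))
    stop("events must have columns onset_s, duration_s, type, trial_id")
  structure(list(data = data, sample_rate_hz = sample_rate_hz,
                 channel_ids = channel_ids, electrode_table = electrode_table,
                 events = events),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$sample_rate_hz,
              ncol(x$data) / x$sample_rate_hz, nrow(x$events)))
  invisible(x)
}

#' Write / read a recording container
#'
#' Recordings round-trip losslessly through the package's serialized
#' container. `read_recording` validates the container and raises a
#' `ecogpred_format_error` when required fields are absent or inconsistent.
#'
#' @param rec a [recording()].
#' @param path file path (conventionally `.rds`).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  obj <- unclass(rec)
  obj$container <- "ecogpred_recording_v1"
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$container, "ecogpred_recording_v1"))
    stop_format("not an ecogpred recording container")
  for (field in c("data", "sample_rate_hz", "channel_ids", "events"))
    if (is.null(obj[[field]]))
      stop_format(sprintf("recording container missing field `%s`", field))
  if (nrow(obj$events) &&
      max(obj$events$onset_s) > ncol(obj$data) / obj$sample_rate_hz)
    stop_format("event onsets exceed recording duration: sample-rate mismatch?")
  recording(obj$data, obj$sample_rate_hz, obj$channel_ids,
            obj$electrode_table, obj$events)
}

#' Remove line noise with zero-phase Butterworth bandstop filters
#'
#' Applies a forward-backward (zero-phase) second-order Butterworth bandstop
#' at the line frequency and its harmonics (60, 120, 180 Hz by default).
#'
#' @param rec a [recording()].
#' @param base_hz line frequency.
#' @param n_harmonics total number of notches (fundamental plus
#'   `n_harmonics - 1` harmonics).
#' @param half_width_hz half-width of each stop band (Hz).
#' @return The filtered [recording()].
#' @export
notch_line_noise <- function(rec, base_hz = 60, n_harmonics = 3,
                             half_width_hz = 2) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sample_rate_hz
  if (base_hz * n_harmonics >= fs / 2)
    stop("requested notch harmonics exceed the Nyquist frequency")
  for (h in seq_len(n_harmonics)) {
    f0 <- base_hz * h
    bf <- signal::butter(2, c(f0 - half_width_hz, f0 + half_width_hz) / (fs / 2),
                         type = "stop")
    for (i in seq_len(nrow(rec$data)))
      rec$data[i, ] <- signal::filtfilt(bf, rec$data[i, ])
  }
  rec
}

#' Exclude channels contaminated by line noise or saturation
#'
#' A channel is excluded when its 60 Hz power exceeds the local spectral
#' baseline (median power over 50-70 Hz, excluding 58-62 Hz) by more than
#' `line_noise_db`, or when it saturates: samples pinned exactly at the
#' channel's extreme value for more than `saturation_frac` of the recording.
#'
#' @param rec a [recording()].
#' @param line_noise_db exclusion threshold (dB above local baseline).
#' @param base_hz line frequency (Hz).
#' @param saturation_frac rail-fraction threshold for the saturation rule.
#' @return A list with the cleaned `recording` and a `report` data.frame
#'   (channel, line_noise_db, saturation_frac, excluded, reason).
#' @export
exclude_channels <- function(rec, line_noise_db = 10, base_hz = 60,
                             saturation_frac = 0.001) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sample_rate_hz
  n <- ncol(rec$data)
  f <- seq(0, fs, length.out = n + 1L)[1:n]
  in_band <- f >= base_hz - 10 & f <= base_hz + 10
  at_line <- f >= base_hz - 1 & f <= base_hz + 1
  local_bg <- in_band & !(f >= base_hz - 2 & f <= base_hz + 2)
  rep_rows <- lapply(seq_len(nrow(rec$data)), function(i) {
    x <- rec$data[i, ]
    p <- Mod(stats::fft(x))^2
    db <- 10 * log10(mean(p[at_line]) / stats::median(p[local_bg]))
    sat <- (sum(x == max(x)) + sum(x == min(x))) / n
    data.frame(channel = rec$channel_ids[i], line_noise_db = db,
               saturation_frac = sat,
               excluded = db > line_noise_db || sat > saturation_frac,
               reason = if (db > line_noise_db) "line_noise"
                        else if (sat > saturation_frac) "saturation" else "",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  keep <- !report$excluded
  if (!any(keep)) stop("all channels excluded: no usable data remain")
  out <- rec
  out$data <- rec$data[keep, , drop = FALSE]
  out$channel_ids <- rec$channel_ids[keep]
  if (!is.null(out$electrode_table))
    out$electrode_table <- out$electrode_table[
      out$electrode_table$id %in% out$channel_ids, , drop = FALSE]
  list(recording = out, report = report)
}

#' Re-reference to the common average
#'
#' Subtracts the mean across channels at every sample, so the per-sample
#' channel mean of the output is identically zero.
#'
#' @param rec a [recording()] with at least two channels.
#' @return The re-referenced [recording()].
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$data) < 2)
    stop("common average reference requires at least two channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Epoch a recording around events
#'
#' Slices one trial per event of the requested type, aligned to event onset.
#' Trials whose window falls outside the recording are dropped with a
#' warning; the number dropped is recorded in the result.
#'
#' @param rec a [recording()].
#' @param event_type which event type to align to.
#' @param window_s length-2 window around each event (s); samples are taken
#'   from the half-open interval `[start, end)`.
#' @param baseline_window_s baseline window relative to the event (s);
#'   default -300 to -50 ms.
#' @return An object of class `epoch_set`: list with `data` (electrodes x
#'   trials x time), `time`, `sample_rate_hz`, `baseline_window_s`,
#'   `alignment`, `electrode_table`, `channel_ids`, `n_dropped`.
#' @export
epoch_recording <- function(rec, event_type = "stimulus_onset",
                            window_s = c(-0.5, 4),
                            baseline_window_s = c(-0.3, -0.05)) {
  stopifnot(inherits(rec, "recording"), length(window_s) == 2,
            window_s[1] < window_s[2])
  if (baseline_window_s[1] < window_s[1] || baseline_window_s[2] > window_s[2])
    stop("baseline window must lie within the epoch window")
  fs <- rec$sample_rate_hz
  ev <- rec$events[rec$events$type == event_type, , drop = FALSE]
  if (!nrow(ev)) stop(sprintf("no events of type `%s`", event_type))
  n_time <- round((window_s[2] - window_s[1]) * fs)
  onset_samp <- round(ev$onset_s * fs)
  start <- onset_samp + round(window_s[1] * fs) + 1L
  ok <- start >= 1L & (start + n_time - 1L) <= ncol(rec$data)
  if (any(!ok))
    warning(sprintf("%d trial(s) dropped: epoch window outside recording", sum(!ok)))
  start <- start[ok]
  n_el <- nrow(rec$data)
  arr <- array(NA_real_, dim = c(n_el, length(start), n_time))
  for (j in seq_along(start))
    arr[, j, ] <- rec$data[, start[j]:(start[j] + n_time - 1L), drop = FALSE]
  structure(list(data = arr,
                 time = window_s[1] + (seq_len(n_time) - 1L) / fs,
                 sample_rate_hz = fs, baseline_window_s = baseline_window_s,
                 alignment = event_type, electrode_table = rec$electrode_table,
                 channel_ids = rec$channel_ids, n_dropped = sum(!ok),
                 trial_ids = ev$trial_id[ok]),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d electrodes x %d trials x %d samples @ %g Hz, aligned to %s\n",
              d[1], d[2], d[3], x$sample_rate_hz, x$alignment))
  invisible(x)
}

#' Filter behavioral trials by correctness and response latency
#'
#' Drops trials answered incorrectly or with a response latency above the
#' cutoff (2 s by default).
#'
#' @param trials data.frame with logical `correct` and numeric `rt_s`.
#' @param max_rt_s latency cutoff (s).
#' @return The filtered data.frame.
#' @export
filter_behavior_trials <- function(trials, max_rt_s = 2) {
  stopifnot(all(c("correct", "rt_s") %in% names(trials)))
  trials[trials$correct & trials$rt_s <= max_rt_s, , drop = FALSE]
}
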