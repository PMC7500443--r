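#' Trial epochs container
#'
#' @param data trials x channels x samples array (uV).
#' @param window_name window label (`"pre"`, `"post"`, `"post_bin1"`, ...).
#' @param window_def two-element ms offset pair defining the window relative
#'   to stimulation onset (pre) or offset (post windows).
#' @param srate sampling rate (Hz).
#' @param channels channel labels.
#' @return object of class `trial_epochs`.
#' @export
trial_epochs <- function(data, window_name, window_def, srate, channels) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(channels))
  structure(list(data = data, window_name = window_name,
                 window_def = window_def, srate = srate, channels = channels),
            class = "trial_epochs")
}

#' @export
print.trial_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_epochs> '%s' [%g, %g] ms: %d trials x %d channels x %d samples\n",
              x$window_name, x$window_def[1], x$window_def[2], d[1], d[2], d[3]))
  invisible(x)
}

## extract one window per trial; start/end are ms offsets relative to the
## anchor sample column ("onset" or "offset", 0-based half-open interval)
extract_window <- function(recording, events, start_ms, end_ms,
                           anchor = c("onset", "offset"), name = "win") {
  anchor <- match.arg(anchor)
  sr <- recording$srate
  ref <- if (anchor == "onset") events$stim_onset else events$stim_offset
  a <- ref + round(start_ms / 1000 * sr)       # 0-based start (inclusive)
  b <- ref + round(end_ms / 1000 * sr)         # 0-based end (exclusive)
  n <- ncol(recording$data)
  bad <- which(a < 0 | b > n)
  if (length(bad)) {
    stop(sprintf("window '%s' out of recording bounds for trial %d",
                 name, events$trial_id[bad[1]]))
  }
  len <- b[1] - a[1]
  out <- array(0, c(nrow(events), nrow(recording$data), len))
  for (i in seq_len(nrow(events))) {
    out[i, , ] <- recording$data[, (a[i] + 1):b[i]]
  }
  trial_epochs(out, name, c(start_ms, end_ms), sr, recording$layout$label)
}

#' Extract the 500 ms pre- and post-stimulation analysis windows
#'
#' Pre window: -600..-100 ms relative to stimulation onset. Post window:
#' +100..+600 ms relative to stimulation offset. The 100 ms trims guard
#' against filter edge effects and residual stimulation artifacts; no sample
#' from the stimulation interval itself is included.
#'
#' @param recording an [eeg_recording()].
#' @param events matching `event_table`.
#' @return list with `pre` and `post` [trial_epochs()].
#' @export
epoch_windows <- function(recording, events) {
  list(pre = extract_window(recording, events, -600, -100, "onset", "pre"),
       post = extract_window(recording, events, 100, 600, "offset", "post"))
}

#' Extract the full 1-s pre- and post-stimulation intervals
#'
#' The offline pipeline band-pass filters these full intervals first and only
#' then trims to the 500 ms analysis windows, so that filter edge effects
#' fall into the trimmed 100 ms margins.
#'
#' @inheritParams epoch_windows
#' @param pre_dur,post_dur interval durations (s).
#' @return list with `pre` and `post` [trial_epochs()].
#' @export
epoch_intervals <- function(recording, events, pre_dur = 1, post_dur = 1) {
  list(pre = extract_window(recording, events, -pre_dur * 1000, 0,
                            "onset", "pre_interval"),
       post = extract_window(recording, events, 0, post_dur * 1000,
                             "offset", "post_interval"))
}

#' Zero-phase 5-40 Hz band-pass filter for epochs
#'
#' Forward-backward 4th-order Butterworth (passband 5-40 Hz), applied along
#' the time axis of every trial and channel.
#'
#' @param epochs a [trial_epochs()].
#' @param band passband in Hz.
#' @param order prototype filter order.
#' @return filtered `trial_epochs` of identical shape.
#' @export
bandpass_5_40 <- function(epochs, band = c(5, 40), order = 4) {
  stopifnot(inherits(epochs, "trial_epochs"))
  if (epochs$srate <= 2 * band[2]) stop("sampling rate too low for the passband")
  filt <- butter_bandpass(order, band[1], band[2], epochs$srate)
  d <- dim(epochs$data)
  ## time along rows, one column per trial x channel; equal-length epochs are
  ## filtered through the cached linear filtfilt operator (single BLAS call)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  out <- filtfilt_operator(filt, d[3]) %*% flat
  epochs$data <- aperm(array(out, c(d[3], d[1], d[2])), c(2, 3, 1))
  epochs
}

## trim a 1-s interval epoch set to a 500-ms analysis window
trim_interval <- function(epochs, start_ms, end_ms, name) {
  sr <- epochs$srate
  rel <- round((c(start_ms, end_ms) - epochs$window_def[1]) / 1000 * sr)
  epochs$data <- epochs$data[, , (rel[1] + 1):rel[2], drop = FALSE]
  epochs$window_name <- name
  epochs$window_def <- c(start_ms, end_ms)
  epochs
}

#' Extract the overlapping post-stimulation time bins
#'
#' Four 500-ms post-stimulation windows starting +100, +200, +300 and
#' +400 ms after stimulation offset (bin 1 equals the standard post window),
#' plus the fixed -600..-100 ms pre window.
#'
#' @inheritParams epoch_windows
#' @return named list: `pre`, `post_bin1` .. `post_bin4` ([trial_epochs()]).
#' @export
timebin_windows <- function(recording, events) {
  out <- list(pre = extract_window(recording, events, -600, -100, "onset", "pre"))
  for (k in 1:4) {
    out[[paste0("post_bin", k)]] <-
      extract_window(recording, events, 100 * k, 100 * k + 500, "offset",
                     paste0("post_bin", k))
  }
  out
}
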