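#' Continuous multichannel EEG recording
#'
#' Lightweight container for a continuous recording: a channels x samples
#' matrix in microvolts plus sampling-rate and montage metadata.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param montage Montage data.frame as returned by [montage_1020()]; its
#'   `label` order must match the rows of `data`.
#' @param reference Reference label, e.g. `"average"` or an electrode name.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, sampling_rate, montage,
                          reference = "average") {
  stopifnot(is.matrix(data), nrow(data) == nrow(montage))
  if (!all(is.finite(data))) stop("raw_recording: data must be finite")
  rownames(data) <- montage$label
  structure(list(data = data, sampling_rate = sampling_rate,
                 channels = montage$label, montage = montage,
                 reference = reference),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s), ref=%s\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate, x$reference))
  invisible(x)
}

#' Event list: time-stamped trial markers
#'
#' One row per marker. `event` is `"dec"` (decision) or `"fb"` (feedback);
#' `value` is the decision side (`left`/`right`) or the feedback valence
#' (`gain`/`loss`); `block_E` is the block's reward parameter.
#'
#' @param sample Integer sample indices (1-based), strictly increasing
#'   within each marker stream.
#' @param event Character, `"dec"` or `"fb"`.
#' @param value Character marker value.
#' @param trial Integer trial number.
#' @param block_E Numeric reward parameter of the block.
#' @return A data.frame of class `event_list`.
#' @export
event_list <- function(sample, event, value, trial, block_E) {
  df <- data.frame(sample = as.integer(sample), event = event, value = value,
                   trial = as.integer(trial), block_E = block_E,
                   stringsAsFactors = FALSE)
  df <- df[order(df$sample), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_list", "data.frame")
  df
}

#' Epoched EEG data
#'
#' Trials x channels x time array time-locked to an event, carrying
#' per-trial condition labels and rejection flags.
#'
#' @param data Numeric array trials x channels x time, microvolts.
#' @param times Time axis in ms relative to the event; must include 0 and be
#'   uniformly spaced.
#' @param sampling_rate Hz.
#' @param montage Montage data.frame.
#' @param labels Character condition label per trial.
#' @param lock Event the epochs are locked to (`"decision"` or `"feedback"`).
#' @param rejected Logical flag per trial.
#' @param reason Character rejection reason per trial (`NA` if kept).
#' @return An object of class `epochs`.
#' @export
epochs <- function(data, times, sampling_rate, montage, labels, lock,
                   rejected = rep(FALSE, dim(data)[1]),
                   reason = rep(NA_character_, dim(data)[1])) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times),
            dim(data)[1] == length(labels), dim(data)[2] == nrow(montage))
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(abs(dt - 1000 / sampling_rate) > 1e-6) || any(dt <= 0))
      stop("epochs: time axis must increase uniformly at 1000/sampling_rate ms")
  }
  if (!any(abs(times) < 1e-9)) stop("epochs: time axis must include t=0")
  structure(list(data = data, times = times, sampling_rate = sampling_rate,
                 channels = montage$label, montage = montage,
                 labels = labels, lock = lock,
                 rejected = rejected, reason = reason),
            class = "epochs")
}

#' Number of kept (non-rejected) trials
#' @param x An `epochs` object.
#' @return Integer count.
#' @export
n_kept <- function(x) sum(!x$rejected)

#' @export
print.epochs <- function(x, ...) {
  cat(sprintf("<epochs> %d trials (%d kept) x %d channels x %d samples, lock=%s, t=[%g, %g] ms\n",
              dim(x$data)[1], n_kept(x), dim(x$data)[2], dim(x$data)[3],
              x$lock, min(x$times), max(x$times)))
  invisible(x)
}

#' Condition-average (evoked) waveform
#'
#' @param data Channels x time matrix in microvolts.
#' @param times Time axis in ms.
#' @param sampling_rate Hz.
#' @param montage Montage data.frame.
#' @param condition Condition label.
#' @param n Number of trials averaged.
#' @return An object of class `evoked`.
#' @export
evoked <- function(data, times, sampling_rate, montage, condition, n) {
  stopifnot(is.matrix(data), ncol(data) == length(times),
            nrow(data) == nrow(montage), n >= 1)
  rownames(data) <- montage$label
  structure(list(data = data, times = times, sampling_rate = sampling_rate,
                 channels = montage$label, montage = montage,
                 condition = condition, n = n),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> '%s' (n=%d): %d channels x %d samples, t=[%g, %g] ms\n",
              x$condition, x$n, nrow(x$data), ncol(x$data),
              min(x$times), max(x$times)))
  invisible(x)
}

# Channel trace helper: one channel's waveform from evoked/raw
channel_trace <- function(x, channel) {
  i <- match(channel, x$channels)
  if (is.na(i)) stop(sprintf("channel '%s' not present", channel))
  x$data[i, ]
}

# Half-open (start, end] selection on a time axis in ms
window_index <- function(times, window, closed_start = FALSE) {
  eps <- 1e-9
  lo <- if (closed_start) times >= window[1] - eps else times > window[1] + eps
  which(lo & times <= window[2] + eps)
}
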