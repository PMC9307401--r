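#' Constant-method baseline correction
#'
#' For every trial and channel, the mean over the baseline window is
#' subtracted from the whole epoch, so the waveform's baseline coincides
#' with the zero line. The window is half-open `(start, end]` on the epoch
#' time axis.
#'
#' @param x An [epochs] object.
#' @param baseline_window `c(start, end)` in ms; must overlap the time axis.
#' @return Baseline-corrected [epochs].
#' @export
baseline_correct <- function(x, baseline_window) {
  stopifnot(inherits(x, "epochs"))
  idx <- window_index(x$times, baseline_window)
  if (length(idx) == 0)
    stop("baseline_correct: baseline window contains no samples")
  bl <- apply(x$data[, , idx, drop = FALSE], c(1, 2), mean)
  x$data <- x$data - array(rep(bl, dim(x$data)[3]), dim = dim(x$data))
  x
}

#' Detect blink intervals on the EOG channel
#'
#' Returns the maximal intervals where the absolute EOG amplitude exceeds
#' the threshold; intervals separated by less than `merge_gap_ms` are
#' merged (a biphasic blink briefly re-crosses the threshold).
#'
#' @param raw A [raw_recording].
#' @param veog_channel EOG channel name (default `"VEOG"`).
#' @param threshold Microvolts (default 100, the blink criterion).
#' @param merge_gap_ms Merge intervals whose gap is below this (default 100).
#' @return data.frame with `start` and `end` in seconds (empty if none).
#' @export
detect_blinks <- function(raw, veog_channel = "VEOG", threshold = 100,
                          merge_gap_ms = 100) {
  stopifnot(inherits(raw, "raw_recording"))
  v <- channel_trace(raw, veog_channel)
  over <- abs(v) > threshold
  if (!any(over))
    return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by short sub-threshold gaps
  gap <- merge_gap_ms / 1000 * raw$sampling_rate
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] - merged[nrow(merged), 2] < gap)
      merged[nrow(merged), 2] <- iv[i, 2]
    else
      merged <- rbind(merged, iv[i, ])
  }
  data.frame(start = (merged[, 1] - 1) / raw$sampling_rate,
             end = (merged[, 2] - 1) / raw$sampling_rate)
}

# Fixed-point symmetric ICA (tanh contrast) on whitened data.
# Returns unmixing applied to centered data: S = W %*% Xc.
fast_ica <- function(X, tol = 1e-4, max_iter = 100) {
  n <- nrow(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- Xc %*% t(Xc) / ncol(Xc)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < max(e$values) * 1e-10)
    stop("fast_ica: rank-deficient data, decomposition unstable")
  K <- diag(1 / sqrt(e$values)) %*% t(e$vectors)  # whitening
  Z <- K %*% Xc
  W <- matrix(stats::rnorm(n * n), n, n)
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gp <- rowMeans(1 - G^2)
    W1 <- sym_orth(G %*% t(Z) / ncol(Z) - diag(gp) %*% W)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  unmix <- W %*% K
  list(S = unmix %*% Xc, unmixing = unmix,
       mixing = e$vectors %*% diag(sqrt(e$values)) %*% t(W), mean = mu)
}

#' Remove ocular components by EOG correlation
#'
#' The EEG channels are decomposed into statistically independent
#' components (whitening followed by a fixed-point symmetric ICA with tanh
#' contrast); every component whose absolute Pearson correlation with the
#' EOG trace exceeds `corr_threshold` is zeroed and the recording is
#' reconstructed from the remainder. The EOG channel itself is left
#' untouched so later stages can still inspect it.
#'
#' @param raw A [raw_recording].
#' @param veog_channel EOG channel name.
#' @param corr_threshold Absolute correlation above which a component is
#'   classed as ocular (default 0.7).
#' @param ica_seed Seed for the ICA random initialization.
#' @return list with `raw` (cleaned recording) and `removed` (component
#'   count zeroed).
#' @export
remove_ocular <- function(raw, veog_channel = "VEOG", corr_threshold = 0.7,
                          ica_seed = 1L) {
  stopifnot(inherits(raw, "raw_recording"))
  v <- channel_trace(raw, veog_channel)
  eeg_idx <- which(!raw$montage$eog)
  if (length(eeg_idx) < 2)
    stop("remove_ocular: need at least 2 EEG channels")
  X <- raw$data[eeg_idx, , drop = FALSE]
  dec <- with_local_seed(ica_seed, fast_ica(X))
  if (stats::sd(v) == 0) {
    rho <- rep(0, nrow(dec$S))
  } else {
    rho <- abs(apply(dec$S, 1, function(s) stats::cor(s, v)))
  }
  bad <- which(rho > corr_threshold)
  S <- dec$S
  S[bad, ] <- 0
  Xc <- dec$mixing %*% S + dec$mean
  out <- raw
  out$data[eeg_idx, ] <- Xc
  list(raw = out, removed = length(bad))
}

#' Extract event-locked epochs from a continuous recording
#'
#' One epoch per marker of the requested lock; the sample at t = 0 is the
#' marker sample, and the epoch covers `window` (both endpoints included,
#' so (-500, 0] ms at 500 Hz yields 251 samples). Decision-locked epochs
#' are labeled by decision side, feedback-locked epochs by outcome valence.
#' Events too close to the recording edge are kept in the tensor but
#' flagged rejected with reason `"edge"`.
#'
#' @param raw A [raw_recording].
#' @param events An [event_list].
#' @param lock `"decision"` or `"feedback"`.
#' @param window `c(start, end)` in ms, covering 0.
#' @return An [epochs] object.
#' @export
extract_epochs <- function(raw, events, lock = c("decision", "feedback"),
                           window = if (match.arg(lock) == "decision")
                             c(-500, 0) else c(-100, 500)) {
  lock <- match.arg(lock)
  stopifnot(inherits(raw, "raw_recording"))
  if (!(window[1] <= 0 && window[2] >= 0))
    stop("extract_epochs: window must cover t = 0")
  fs <- raw$sampling_rate
  ev <- events[events$event == if (lock == "decision") "dec" else "fb", ,
               drop = FALSE]
  k0 <- ceiling(window[1] / 1000 * fs - 1e-9)
  k1 <- floor(window[2] / 1000 * fs + 1e-9)
  rel <- k0:k1
  times <- rel * 1000 / fs
  n_samp <- ncol(raw$data)
  n_ev <- nrow(ev)
  data <- array(0, dim = c(n_ev, nrow(raw$data), length(rel)))
  rejected <- rep(FALSE, n_ev)
  reason <- rep(NA_character_, n_ev)
  for (i in seq_len(n_ev)) {
    j <- ev$sample[i] + rel
    if (j[1] < 1 || j[length(j)] > n_samp) {
      rejected[i] <- TRUE
      reason[i] <- "edge"
    } else {
      data[i, , ] <- raw$data[, j]
    }
  }
  epochs(data, times, fs, raw$montage, labels = ev$value, lock = lock,
         rejected = rejected, reason = reason)
}

#' Reject epochs exceeding an amplitude threshold
#'
#' Trials with any EEG-channel sample whose absolute amplitude exceeds the
#' threshold inside the scan window are flagged rejected (reason
#' `"amplitude"`); already-rejected trials and the EOG channel are ignored.
#'
#' @param x An [epochs] object.
#' @param amplitude_threshold Microvolts (default 100).
#' @param scan_window `c(start, end)` ms, half-open `(start, end]`
#'   (default (-200, 500), clipped to the epoch's time axis).
#' @return [epochs] with updated rejection flags.
#' @export
reject_epochs <- function(x, amplitude_threshold = 100,
                          scan_window = c(-200, 500)) {
  stopifnot(inherits(x, "epochs"))
  idx <- window_index(x$times, scan_window)
  if (length(idx) == 0)
    stop("reject_epochs: scan window does not intersect the epoch time axis")
  ch <- which(!x$montage$eog)
  for (i in seq_len(dim(x$data)[1])) {
    if (x$rejected[i]) next
    if (max(abs(x$data[i, ch, idx])) > amplitude_threshold) {
      x$rejected[i] <- TRUE
      x$reason[i] <- "amplitude"
    }
  }
  x
}

#' Average kept epochs of one condition
#'
#' The condition-average waveform: the pointwise arithmetic mean over the
#' kept (non-rejected) trials carrying the requested label,
#' `xbar_i = (1/n) * sum_j x_ij`.
#'
#' @param x An [epochs] object.
#' @param condition Label to average (e.g. `"left"`, `"gain"`).
#' @return An [evoked] waveform with the trial count `n` recorded.
#' @export
average_epochs <- function(x, condition) {
  stopifnot(inherits(x, "epochs"))
  sel <- which(x$labels == condition & !x$rejected)
  if (length(sel) == 0)
    stop(sprintf("average_epochs: no kept trials for condition '%s'", condition))
  avg <- apply(x$data[sel, , , drop = FALSE], c(2, 3), mean)
  evoked(avg, x$times, x$sampling_rate, x$montage, condition, length(sel))
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase, so
#' latency statistics are unbiased); DC gain 1, attenuation at twice the
#' cutoff at least 24 dB.
#'
#' @param x An [evoked], [raw_recording], or numeric vector/matrix (rows =
#'   channels; a plain vector/matrix needs `sampling_rate`).
#' @param cutoff Cutoff frequency in Hz (default 30).
#' @param sampling_rate Required when `x` is not a package container.
#' @return Same type as `x`, filtered.
#' @export
lowpass_filter <- function(x, cutoff = 30, sampling_rate = NULL) {
  if (inherits(x, "evoked") || inherits(x, "raw_recording")) {
    x$data <- lowpass_filter(x$data, cutoff, x$sampling_rate)
    return(x)
  }
  if (is.null(sampling_rate))
    stop("lowpass_filter: sampling_rate required for plain numeric input")
  if (cutoff >= sampling_rate / 2)
    stop("lowpass_filter: cutoff must be below the Nyquist frequency")
  bf <- signal::butter(4, cutoff / (sampling_rate / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients that a
  # plain forward-backward pass leaves on short epochs (the epoch endpoint
  # t = 0 is exactly where the pre-decision statistics are read)
  filt1 <- function(v) {
    n <- length(v)
    p <- min(n - 1, ceiling(6 * sampling_rate / cutoff))
    pre <- 2 * v[1] - v[seq(p + 1, 2)]
    post <- 2 * v[n] - v[seq(n - 1, n - p)]
    y <- as.numeric(signal::filtfilt(bf, c(pre, v, post)))
    y[(p + 1):(p + n)]
  }
  if (is.matrix(x)) t(apply(x, 1, filt1)) else filt1(x)
}

#' Common average reference
#'
#' At every time point the mean over the EEG channels (EOG excluded) is
#' subtracted from every EEG channel, so the EEG channel-mean of the output
#' is zero at each sample. Idempotent.
#'
#' @param x An [evoked] or [raw_recording].
#' @return Same type, re-referenced; `reference` set to `"average"` for
#'   recordings.
#' @export
average_reference <- function(x) {
  stopifnot(inherits(x, "evoked") || inherits(x, "raw_recording"))
  eeg <- which(!x$montage$eog)
  if (length(eeg) < 2)
    stop("average_reference: need at least 2 EEG channels")
  mu <- colMeans(x$data[eeg, , drop = FALSE])
  x$data[eeg, ] <- sweep(x$data[eeg, , drop = FALSE], 2, mu)
  if (inherits(x, "raw_recording")) x$reference <- "average"
  x
}
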