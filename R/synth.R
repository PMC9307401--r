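#' Reward parameter of a gambling block
#'
#' The reward parameter E is the value printed in the left square divided by
#' the value printed in the right square. It indexes the risk level of a
#' block: larger E means a larger bet on the left option.
#'
#' @param left_value Stake of the left square (currency units).
#' @param right_value Stake of the right square (currency units, default 5).
#' @return E, dimensionless.
#' @examples
#' reward_parameter(25, 5)  # 5
#' reward_parameter(50, 5)  # 10
#' @export
reward_parameter <- function(left_value, right_value = 5) {
  if (!is.numeric(right_value) || right_value <= 0)
    stop("reward_parameter: right_value must be > 0")
  left_value / right_value
}

#' Number of trials in a timed session
#'
#' A session of `session_minutes` minutes at `trial_duration` seconds per
#' choice yields `floor(60 * minutes / duration)` trials (300 for the
#' default 15-minute, 3-second design).
#'
#' @param session_minutes Session length, minutes.
#' @param trial_duration Seconds per choice.
#' @return Integer trial count.
#' @export
n_trials_for <- function(session_minutes = 15, trial_duration = 3) {
  as.integer(floor(session_minutes * 60 / trial_duration))
}

#' Configuration of one gambling-task recording session
#'
#' @param left_value Stake of the left square; the block's reward parameter
#'   is `left_value / right_value`.
#' @param right_value Stake of the right square (default 5).
#' @param n_trials Trials per session (default `n_trials_for()` = 300).
#' @param trial_duration Seconds per trial (default 3).
#' @param decision_time Seconds from trial onset to the choice (default 1);
#'   the feedback colour change follows the choice by exactly 1 s.
#' @param sampling_rate Hz (default 500).
#' @param montage Electrode layout (default 63-channel 10-10 + VEOG,
#'   i.e. a 64-channel cap); must contain `"Fz"` and one EOG channel.
#' @param seed Integer RNG seed; mandatory for reproducibility.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(left_value, right_value = 5,
                              n_trials = n_trials_for(),
                              trial_duration = 3, decision_time = 1,
                              sampling_rate = 500,
                              montage = montage_1020(63), seed = 1L) {
  if (n_trials <= 0) stop("experiment_config: n_trials must be > 0")
  if (sampling_rate <= 60)  # must exceed twice the 30 Hz analysis cutoff
    stop("experiment_config: sampling_rate must exceed twice the filter cutoff")
  if (!"Fz" %in% montage$label)
    stop("experiment_config: montage must contain Fz")
  if (!any(montage$eog))
    stop("experiment_config: montage must contain an EOG channel")
  structure(list(left_value = left_value, right_value = right_value,
                 E = reward_parameter(left_value, right_value),
                 n_trials = as.integer(n_trials),
                 trial_duration = trial_duration,
                 decision_time = decision_time,
                 sampling_rate = sampling_rate, montage = montage,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Effect sizes and nuisance parameters of a simulated session
#'
#' Ground-truth parameters injected by [generate_session()]. Amplitudes are
#' expressed at Fz under the common average reference (all template scalp
#' maps have zero spatial mean over the EEG channels and unit Fz weight).
#'
#' @param divergence_onset ms before the decision at which the left-choice
#'   frontal negativity begins (a linear ramp reaching
#'   `divergence_amplitude` at the decision).
#' @param divergence_amplitude Ramp amplitude at the decision, microvolts at
#'   Fz (negative: left choices more negative).
#' @param mfn_latency ms after feedback at which the feedback component
#'   peaks (default 232).
#' @param loss_amplitude,gain_amplitude Peak amplitude of the feedback
#'   component at Fz, microvolts, for loss and gain trials.
#' @param mfn_width Gaussian SD of the feedback component, ms.
#' @param noise_rms RMS of the 1/f background noise, microvolts per channel.
#' @param blink_rate Blinks per minute on the VEOG channel.
#' @param bad_block_intervals Optional list of `c(start, end)` second pairs
#'   to contaminate with high-amplitude noise.
#' @return An object of class `session_effects`.
#' @export
session_effects <- function(divergence_onset = 107,
                            divergence_amplitude = -6,
                            mfn_latency = 232,
                            loss_amplitude = -0.34, gain_amplitude = 0.37,
                            mfn_width = 50, noise_rms = 5,
                            blink_rate = 6, bad_block_intervals = list()) {
  if (divergence_onset <= 0) stop("session_effects: divergence_onset must be > 0")
  if (mfn_width <= 0) stop("session_effects: mfn_width must be > 0")
  if (noise_rms < 0 || blink_rate < 0)
    stop("session_effects: noise_rms and blink_rate must be >= 0")
  structure(as.list(environment()), class = "session_effects")
}

# Zero-mean scalp map with unit Fz weight. Reference-free surface
# potentials have zero spatial mean, so templates built this way pass
# unchanged through common-average referencing; normalizing at Fz makes the
# configured amplitudes read directly off the Fz trace.
scalp_map <- function(montage, focus, sigma = 0.35, ref_channel = "Fz") {
  d2 <- (montage$x - focus[1])^2 + (montage$y - focus[2])^2
  w <- exp(-d2 / (2 * sigma^2))
  w[montage$eog] <- 0
  eeg <- !montage$eog
  w[eeg] <- w[eeg] - mean(w[eeg])
  wf <- w[montage$label == ref_channel]
  if (abs(wf) < 0.05)
    stop("scalp_map: reference channel weight too small to normalize")
  w / wf
}

# 1/f ("pink") gaussian noise via spectral shaping: flat below f_lo,
# amplitude ~ f^(-1/2) above, standardized to the requested RMS. The lower
# band edge emulates the acquisition amplifier's high-pass: without it,
# sub-0.1 Hz drift carries most of the variance and swamps every
# correlation computed on the continuous recording.
pink_noise <- function(n, sampling_rate, rms, f_lo = 0.5) {
  if (rms == 0) return(numeric(n))
  white <- stats::rnorm(n)
  f <- seq(0, sampling_rate / 2, length.out = floor(n / 2) + 1)
  hp <- (f / f_lo) / sqrt(1 + (f / f_lo)^2)  # 1st-order high-pass at f_lo
  shape <- hp / sqrt(pmax(f, f_lo))
  spec <- stats::fft(white)
  full <- c(shape, rev(shape[2:(n - length(shape) + 1)]))
  x <- Re(stats::fft(spec * full, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# Biphasic blink transient: 100 ms main lobe, 50 ms opposite rebound.
blink_shape <- function(sampling_rate) {
  t <- seq(0, 0.15, by = 1 / sampling_rate)
  s <- ifelse(t <= 0.1, sin(pi * t / 0.1), -0.3 * sin(pi * (t - 0.1) / 0.05))
  s
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate one gambling-task EEG session with known ground truth
#'
#' Generates a continuous multichannel recording containing, per trial, a
#' decision marker and a feedback marker 1 s later. Left-choice trials carry
#' a frontal negative ramp that starts `divergence_onset` ms before the
#' decision; every feedback event evokes a Gaussian-windowed component
#' peaking `mfn_latency` ms later whose Fz amplitude depends on the gain or
#' loss outcome. 1/f background noise and super-threshold blink transients
#' (VEOG, propagated to frontal channels with distance-decaying weights)
#' are added on top. The injected parameters are returned as ground truth
#' for parameter-recovery testing.
#'
#' @param config An [experiment_config()].
#' @param effects A [session_effects()] (per-block defaults are sensible for
#'   the E = 5 block).
#' @return A list with elements `raw` ([raw_recording]), `events`
#'   ([event_list]) and `truth` (ground-truth list, including blink times).
#' @examples
#' cfg <- experiment_config(25, n_trials = 10, montage = montage_1020(19),
#'                          seed = 7)
#' s <- generate_session(cfg, session_effects(noise_rms = 1, blink_rate = 0))
#' s$raw
#' @export
generate_session <- function(config, effects = session_effects()) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(effects, "session_effects"))
  fs <- config$sampling_rate
  trial_ms <- config$trial_duration * 1000
  if (effects$divergence_onset >= trial_ms)
    stop("generate_session: divergence_onset must be shorter than the trial")
  if (effects$divergence_onset >= config$decision_time * 1000)
    stop("generate_session: divergence ramp must fit before the decision")
  m <- config$montage
  n_ch <- nrow(m)
  n_samp <- round(config$n_trials * config$trial_duration * fs)

  with_local_seed(config$seed, {
    sides <- ifelse(stats::runif(config$n_trials) < 0.5, "left", "right")
    outcomes <- ifelse(stats::runif(config$n_trials) < 0.5, "gain", "loss")

    dec_samp <- round((seq_len(config$n_trials) - 1) * config$trial_duration * fs +
                        config$decision_time * fs) + 1L
    fb_samp <- dec_samp + as.integer(fs)  # exactly 1 s after the choice

    X <- matrix(0, n_ch, n_samp)

    # pre-decision divergence: left-choice-only linear ramp at frontal sites
    w_div <- scalp_map(m, focus = c(0, 0.55), sigma = 0.40)
    onset_samp <- round(effects$divergence_onset / 1000 * fs)
    ramp <- seq_len(onset_samp) / onset_samp  # reaches 1 at the decision
    release <- rev(seq_len(round(0.3 * fs))) / round(0.3 * fs)  # 300 ms decay
    for (k in which(sides == "left")) {
      i0 <- dec_samp[k] - onset_samp
      X[, i0:(dec_samp[k] - 1)] <- X[, i0:(dec_samp[k] - 1)] +
        outer(w_div * effects$divergence_amplitude, ramp)
      j <- dec_samp[k]:min(dec_samp[k] + length(release) - 1, n_samp)
      X[, j] <- X[, j] + outer(w_div * effects$divergence_amplitude,
                               release[seq_along(j)])
    }

    # post-feedback component: Gaussian bump, valence-dependent amplitude
    # and topography (gain anterior-focused, loss posterior-focused)
    w_gain <- scalp_map(m, focus = c(0, 0.45), sigma = 0.40)
    w_loss <- scalp_map(m, focus = c(0, -0.55), sigma = 0.45)
    half <- round(4 * effects$mfn_width / 1000 * fs)
    rel <- (-half):half
    bump <- exp(-(rel / fs * 1000 - 0)^2 / (2 * effects$mfn_width^2))
    for (k in seq_len(config$n_trials)) {
      c0 <- fb_samp[k] + round(effects$mfn_latency / 1000 * fs)
      j <- (c0 - half):(c0 + half)
      ok <- j >= 1 & j <= n_samp
      amp <- if (outcomes[k] == "gain") effects$gain_amplitude else effects$loss_amplitude
      wmap <- if (outcomes[k] == "gain") w_gain else w_loss
      X[, j[ok]] <- X[, j[ok]] + outer(wmap * amp, bump[ok])
    }

    # 1/f background noise, independent per channel
    if (effects$noise_rms > 0)
      for (i in seq_len(n_ch))
        X[i, ] <- X[i, ] + pink_noise(n_samp, fs, effects$noise_rms)

    # blinks: VEOG transients > 100 uV, propagated to frontal EEG sites
    blink_times <- numeric(0)
    if (effects$blink_rate > 0) {
      n_blink <- stats::rpois(1, effects$blink_rate * n_samp / fs / 60)
      blink_times <- sort(stats::runif(n_blink, 0.2, n_samp / fs - 0.4))
      shape <- blink_shape(fs)
      # propagation profile: ~45% of VEOG at the frontal pole, ~15-20% at
      # Fz, a few percent posteriorly (typical blink artifact topography)
      d_fp <- sqrt((m$x - 0)^2 + (m$y - 0.9)^2)
      w_bl <- 0.5 * exp(-d_fp / 0.45)
      w_bl[m$eog] <- 1
      for (tb in blink_times) {
        amp <- stats::runif(1, 150, 400)
        j <- round(tb * fs) + seq_along(shape)
        X[, j] <- X[, j] + outer(w_bl * amp, shape)
      }
    }

    # bad blocks: broadband high-amplitude contamination
    for (iv in effects$bad_block_intervals) {
      j <- max(1, round(iv[1] * fs)):min(n_samp, round(iv[2] * fs))
      X[, j] <- X[, j] + matrix(stats::rnorm(n_ch * length(j), 0, 150),
                                n_ch, length(j))
    }

    events <- event_list(
      sample = c(dec_samp, fb_samp),
      event = rep(c("dec", "fb"), each = config$n_trials),
      value = c(sides, outcomes),
      trial = rep(seq_len(config$n_trials), 2),
      block_E = config$E)

    truth <- list(divergence_onset = effects$divergence_onset,
                  divergence_amplitude = effects$divergence_amplitude,
                  mfn_latency = effects$mfn_latency,
                  loss_amplitude = effects$loss_amplitude,
                  gain_amplitude = effects$gain_amplitude,
                  delta = abs(effects$gain_amplitude - effects$loss_amplitude),
                  blink_times = blink_times,
                  bad_block_intervals = effects$bad_block_intervals,
                  seed = config$seed)

    list(raw = raw_recording(X, fs, m), events = events, truth = truth)
  })
}

#' Simulate a cohort of subjects with between-subject variability
#'
#' Each subject's divergence onset, component amplitudes and feedback-peak
#' latency are drawn from normal perturbations around the cohort effects;
#' the per-subject draw is recorded in that subject's ground truth.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config An [experiment_config()]; subject k uses seed
#'   `config$seed + k`.
#' @param effects Cohort-level [session_effects()].
#' @param onset_sd Between-subject SD of the divergence onset, ms.
#' @param amplitude_sd Between-subject SD of the loss/gain amplitudes, uV.
#' @param latency_sd Between-subject SD of the feedback-peak latency, ms.
#' @return A list of `generate_session()` results, one per subject.
#' @export
generate_cohort <- function(n_subjects, config, effects = session_effects(),
                            onset_sd = 9, amplitude_sd = 0.1,
                            latency_sd = 5) {
  if (n_subjects < 1) stop("generate_cohort: n_subjects must be >= 1")
  if (onset_sd < 0 || amplitude_sd < 0 || latency_sd < 0)
    stop("generate_cohort: negative between-subject sd")
  lapply(seq_len(n_subjects), function(k) {
    seed_k <- config$seed + k
    eff_k <- with_local_seed(seed_k * 2L + 1L, {
      e <- effects
      e$divergence_onset <- max(1, effects$divergence_onset +
                                  stats::rnorm(1, 0, onset_sd))
      e$mfn_latency <- effects$mfn_latency + stats::rnorm(1, 0, latency_sd)
      shift <- stats::rnorm(2, 0, amplitude_sd)
      e$loss_amplitude <- effects$loss_amplitude + shift[1]
      e$gain_amplitude <- effects$gain_amplitude + shift[2]
      e
    })
    cfg_k <- config
    cfg_k$seed <- as.integer(seed_k)
    generate_session(cfg_k, eff_k)
  })
}
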