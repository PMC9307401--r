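# Small in-code fixtures shared across test files.

tiny_config <- function(n_trials = 12, seed = 1L, channels = 19,
                        sampling_rate = 500) {
  experiment_config(25, n_trials = n_trials, sampling_rate = sampling_rate,
                    montage = montage_1020(channels), seed = seed)
}

quiet_effects <- function(...) {
  session_effects(noise_rms = 0, blink_rate = 0, ...)
}

# evoked with a given Fz trace (zeros on all other channels)
fz_evoked <- function(fz, times, condition = "x", sampling_rate = 500,
                      montage = montage_1020(19)) {
  data <- matrix(0, nrow(montage), length(times))
  data[montage$label == "Fz", ] <- fz
  evoked(data, times, sampling_rate, montage, condition, 1L)
}

# independent oracle for the PT: exhaustive scan over the sample grid for
# every intersection (coincidence within tol, or an interpolated adjacent
# sign change), keeping the latest one; mirrors the statistic's definition
# but via brute-force enumeration
pt_oracle <- function(d, t_ax, tol = 1e-9) {
  s <- sign(d)
  s[abs(d) < tol] <- 0
  if (all(s == 0)) return(list(error = "no separation"))
  cand <- t_ax[s == 0]
  for (k in seq_len(length(d) - 1)) {
    if (s[k] != 0 && s[k + 1] != 0 && s[k] != s[k + 1]) {
      cand <- c(cand,
                t_ax[k] + (t_ax[k + 1] - t_ax[k]) * d[k] / (d[k] - d[k + 1]))
    }
  }
  if (length(cand) == 0)
    return(list(pt = max(t_ax) - min(t_ax), persistence_ok = FALSE))
  t_star <- max(cand)
  tail_s <- s[t_ax > t_star + 1e-9]
  tail_s <- tail_s[tail_s != 0]
  list(pt = -t_star,
       persistence_ok = length(unique(tail_s)) == 1 && s[length(s)] != 0)
}

# random smooth waveform pair on a grid ending at 0 (for PT property tests)
random_wave_pair <- function(n_samples, sampling_rate = 500) {
  t_ax <- seq(-(n_samples - 1), 0) * 1000 / sampling_rate
  smooth <- function() {
    x <- cumsum(stats::rnorm(n_samples))
    stats::filter(c(x[1], x, x[n_samples])[seq_len(n_samples + 2)],
                  rep(1 / 3, 3), sides = 2)[2:(n_samples + 1)]
  }
  list(a = as.numeric(smooth()), b = as.numeric(smooth()), times = t_ax)
}
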