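make_epochs <- function(data, sampling_rate = 500, montage = montage_1020(19),
                        labels = NULL, lock = "decision",
                        t0_index = dim(data)[3]) {
  times <- (seq_len(dim(data)[3]) - t0_index) * 1000 / sampling_rate
  if (is.null(labels)) labels <- rep("left", dim(data)[1])
  epochs(data, times, sampling_rate, montage, labels, lock)
}

test_that("constant-method baseline correction zeroes the baseline mean", {
  m <- montage_1020(19)
  # constant epochs become all-zero
  d <- array(7, dim = c(3, nrow(m), 251))
  ep <- baseline_correct(make_epochs(d), c(-500, -400))
  expect_equal(max(abs(ep$data)), 0)

  # linear-ramp epoch: output equals explicit mean subtraction (oracle)
  d2 <- array(0, dim = c(1, nrow(m), 251))
  ramp <- seq(-500, 0, by = 2)
  d2[1, , ] <- matrix(ramp, nrow(m), 251, byrow = TRUE)
  ep2 <- baseline_correct(make_epochs(d2), c(-460, -440))
  win <- ramp[ramp > -460 & ramp <= -440]
  expect_equal(ep2$data[1, 1, ], ramp - mean(win), tolerance = 1e-12)

  # idempotence on already-corrected data
  ep3 <- baseline_correct(ep2, c(-460, -440))
  expect_equal(ep3$data, ep2$data, tolerance = 1e-12)

  expect_error(baseline_correct(make_epochs(d), c(10, 20)), "window")
})

test_that("blink detection finds and merges threshold excursions", {
  m <- montage_1020(19)
  fs <- 500
  X <- matrix(0, nrow(m), 10 * fs)
  raw <- raw_recording(X, fs, m)
  expect_equal(nrow(detect_blinks(raw)), 0)

  # 200 uV transient at t = 5 s (oracle: direct threshold scan)
  X2 <- X
  X2[m$label == "VEOG", 5 * fs + 1:25] <- 200
  b <- detect_blinks(raw_recording(X2, fs, m))
  expect_equal(nrow(b), 1)
  expect_true(b$start[1] <= 5 && b$end[1] >= 5)

  # two transients 50 ms apart merge into one interval
  X3 <- X
  v <- which(m$label == "VEOG")
  X3[v, 1000 + 1:10] <- 150
  X3[v, 1035 + 1:10] <- -150  # 50 ms gap from end of first
  b3 <- detect_blinks(raw_recording(X3, fs, m))
  expect_equal(nrow(b3), 1)

  # but a 200 ms gap stays two intervals
  X4 <- X
  X4[v, 1000 + 1:10] <- 150
  X4[v, 1110 + 1:10] <- 150
  expect_equal(nrow(detect_blinks(raw_recording(X4, fs, m))), 2)

  expect_error(detect_blinks(raw, veog_channel = "nope"), "not present")
})

test_that("ocular ICA removes blink components and spares clean data", {
  cfg <- tiny_config(n_trials = 40, seed = 5)

  # blink-free: nothing removed, reconstruction is the identity
  s0 <- generate_session(cfg, session_effects(noise_rms = 3, blink_rate = 0))
  oc0 <- remove_ocular(s0$raw)
  expect_identical(oc0$removed, 0L)
  expect_lt(max(abs(oc0$raw$data - s0$raw$data)), 1)

  # blink-bearing: at least one component goes, and the EOG correlation of
  # the frontal EEG strictly drops (oracle: correlation before vs after)
  s <- generate_session(cfg, session_effects(noise_rms = 3, blink_rate = 15))
  v <- s$raw$data["VEOG", ]
  pre <- abs(cor(s$raw$data["Fz", ], v))
  oc <- remove_ocular(s$raw)
  post <- abs(cor(oc$raw$data["Fz", ], v))
  expect_gte(oc$removed, 1)
  expect_lt(post, pre)

  # a vacuous threshold removes nothing and round-trips the data
  oc1 <- remove_ocular(s$raw, corr_threshold = 1.0)
  expect_identical(oc1$removed, 0L)
  expect_lt(max(abs(oc1$raw$data - s$raw$data)), 1e-6)
})

test_that("epoch extraction is sample-exact and labels by lock", {
  cfg <- tiny_config(n_trials = 6, seed = 6)
  s <- generate_session(cfg, session_effects(noise_rms = 2, blink_rate = 0))

  ep <- extract_epochs(s$raw, s$events, "decision", c(-500, 0))
  expect_equal(dim(ep$data)[3], 251)  # (-500, 0] at 500 Hz incl. t = 0
  expect_setequal(unique(ep$labels), intersect(c("left", "right"), ep$labels))

  # the sample at t = 0 is the marker sample
  dec <- s$events$sample[s$events$event == "dec"]
  k0 <- which(abs(ep$times) < 1e-9)
  for (i in seq_along(dec))
    expect_equal(ep$data[i, , k0], unname(s$raw$data[, dec[i]]))

  fb <- extract_epochs(s$raw, s$events, "feedback", c(-100, 500))
  expect_setequal(unique(fb$labels), intersect(c("gain", "loss"), fb$labels))

  # zero events
  e0 <- s$events[0, ]
  class(e0) <- class(s$events)
  ep0 <- extract_epochs(s$raw, e0, "decision", c(-500, 0))
  expect_equal(dim(ep0$data)[1], 0)

  # event too close to the recording edge is flagged, not dropped
  ev_edge <- event_list(sample = c(10L, 3000L), event = c("dec", "dec"),
                        value = c("left", "left"), trial = 1:2, block_E = 5)
  ep_e <- extract_epochs(s$raw, ev_edge, "decision", c(-500, 0))
  expect_true(ep_e$rejected[1])
  expect_equal(ep_e$reason[1], "edge")
  expect_false(ep_e$rejected[2])
})

test_that("amplitude rejection flags exactly the over-threshold trials", {
  m <- montage_1020(19)
  d <- array(0, dim = c(4, nrow(m), 351))
  # trial 2: 101 uV at t = +100 ms inside the scan window -> rejected
  # trial 3: 101 uV at t = -300 ms outside (-200, 500) -> kept
  # trial 4: 101 uV on VEOG only -> kept (EOG excluded)
  times <- seq(-200, 500, by = 2)
  ep <- epochs(d, times, 500, m, labels = rep("gain", 4), lock = "feedback")
  ep$data[2, 3, which(abs(times - 100) < 1e-9)] <- 101
  ep2 <- ep
  ep2$times <- seq(-400, 300, by = 2)
  ep2$data[3, 3, which(abs(ep2$times + 300) < 1e-9)] <- 101
  ep2$data[4, which(m$label == "VEOG"), 200] <- 150

  r <- reject_epochs(ep, 100, c(-200, 500))
  expect_identical(which(r$rejected), 2L)
  expect_equal(r$reason[2], "amplitude")
  expect_equal(n_kept(r), 3)

  r2 <- reject_epochs(ep2, 100, c(-200, 500))
  expect_false(r2$rejected[3])
  expect_false(r2$rejected[4])

  # rejection count is monotone non-increasing in the threshold
  set.seed(9)
  dn <- array(rnorm(20 * nrow(m) * 351, sd = 60), c(20, nrow(m), 351))
  epn <- epochs(dn, times, 500, m, labels = rep("x", 20), lock = "feedback")
  counts <- vapply(c(50, 100, 150, 200), function(th)
    sum(reject_epochs(epn, th)$rejected), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("epoch averaging equals the naive two-loop mean and skips rejects", {
  m <- montage_1020(19)
  # constants 1, 2, 3 -> 2 (hand mean)
  d <- array(0, c(3, nrow(m), 11))
  for (i in 1:3) d[i, , ] <- i
  ep <- make_epochs(d, labels = rep("left", 3))
  expect_equal(max(abs(average_epochs(ep, "left")$data - 2)), 0)

  # Eq-style oracle: naive double loop within 1e-9
  set.seed(10)
  d2 <- array(rnorm(5 * nrow(m) * 11), c(5, nrow(m), 11))
  ep2 <- make_epochs(d2, labels = c("a", "a", "b", "a", "b"))
  avg <- average_epochs(ep2, "a")
  naive <- matrix(0, nrow(m), 11)
  for (tr in c(1, 2, 4)) for (k in 1:11) naive[, k] <- naive[, k] + d2[tr, , k]
  naive <- naive / 3
  expect_lt(max(abs(avg$data - naive)), 1e-9)
  expect_equal(avg$n, 3L)

  # flagged trials do not influence the mean
  ep3 <- ep2
  ep3$rejected[4] <- TRUE
  avg3 <- average_epochs(ep3, "a")
  expect_equal(avg3$n, 2L)
  expect_lt(max(abs(avg3$data - (d2[1, , ] + d2[2, , ]) / 2)), 1e-9)

  expect_error(average_epochs(ep2, "zzz"), "zzz")
})

test_that("zero-phase low-pass keeps the passband and kills the stopband", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)

  # DC gain 1
  expect_lt(max(abs(lowpass_filter(rep(2, length(t)), 30, fs) - 2)), 1e-6)

  amp_ratio <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- lowpass_filter(x, 30, fs)
    mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
    max(abs(y[mid])) / max(abs(x[mid]))
  }
  expect_gt(amp_ratio(5), 0.95)                    # 5 Hz within 5%
  expect_lt(20 * log10(amp_ratio(60)), -24)        # >= 24 dB down at 60 Hz

  expect_error(lowpass_filter(t, 300, fs), "Nyquist")
})

test_that("common average reference zero-sums EEG channels and is idempotent", {
  cfg <- tiny_config(n_trials = 4, seed = 7)
  s <- generate_session(cfg, session_effects(noise_rms = 3, blink_rate = 5))
  ref <- average_reference(s$raw)
  eeg <- which(!ref$montage$eog)
  expect_lt(max(abs(colSums(ref$data[eeg, ]))), 1e-9)
  # EOG untouched
  expect_equal(ref$data["VEOG", ], s$raw$data["VEOG", ])
  # idempotence
  ref2 <- average_reference(ref)
  expect_lt(max(abs(ref2$data - ref$data)), 1e-9)

  # identical channels cancel entirely
  m <- montage_1020(19)
  X <- matrix(rep(rnorm(100), each = nrow(m)), nrow(m), 100)
  r <- average_reference(raw_recording(X, 500, m))
  expect_lt(max(abs(r$data[!m$eog, ])), 1e-12)
})

test_that("full chain on noiseless data returns the templates at Fz", {
  cfg <- tiny_config(n_trials = 40, seed = 8)
  eff <- quiet_effects(divergence_onset = 120, divergence_amplitude = -6,
                       loss_amplitude = -0.5, gain_amplitude = 0.5)
  s <- generate_session(cfg, eff)
  res <- preprocess_session(s, preprocess_params(ocular = FALSE))
  # divergence amplitude at the decision within filter ripple
  fzl <- res$decision$left$data["Fz", ]
  expect_equal(unname(fzl[length(fzl)]), -6, tolerance = 0.02 * 6)
  # feedback amplitudes at 232 ms within ripple
  k <- which(abs(res$feedback$gain$times - 232) < 1e-6)
  expect_equal(unname(res$feedback$gain$data["Fz", k]), 0.5, tolerance = 0.01)
  expect_equal(unname(res$feedback$loss$data["Fz", k]), -0.5, tolerance = 0.01)
})
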