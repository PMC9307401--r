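test_that("reward parameter is the stake ratio", {
  expect_equal(reward_parameter(25, 5), 5)
  expect_equal(reward_parameter(35, 5), 7)
  expect_equal(reward_parameter(50, 5), 10)
  expect_equal(reward_parameter(5, 5), 1)
  expect_error(reward_parameter(25, 0), "right_value")
  expect_error(reward_parameter(25, -2), "right_value")
})

test_that("delta amplitude is |gain - loss|, symmetric, shift-invariant", {
  expect_equal(delta_amplitude(-0.34, 0.37), 0.71)
  expect_equal(delta_amplitude(0.52, 2.04), 1.52)
  expect_equal(delta_amplitude(0.32, 2.15), 1.83)
  expect_equal(delta_amplitude(1.4, 1.4), 0)
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(1); b <- rnorm(1); c <- rnorm(1)
    expect_equal(delta_amplitude(a, b), delta_amplitude(b, a))
    expect_equal(delta_amplitude(a + c, b + c), delta_amplitude(a, b))
  }
})

test_that("PT finds the last intersection before the decision", {
  times <- seq(-500, 0, by = 2)

  # flat vs ramp starting at -120 ms: the curves part at -120
  ramp <- ifelse(times > -120, (times + 120) / 120, 0)
  a <- fz_evoked(rep(0, length(times)), times)
  b <- fz_evoked(ramp, times, "y")
  r <- compute_pt(a, b)
  expect_equal(r$pt, 120)
  expect_equal(r$crossing_time, -120)
  expect_true(r$persistence_ok)

  # identical waveforms: no separation to measure
  expect_error(compute_pt(a, a), "not separated")

  # two crossings at -300 and -150, then single-signed through 0
  # (d has simple roots exactly there and stays negative afterwards)
  q <- (times + 300) * (times + 150) * 1e-4
  b2 <- fz_evoked(q, times, "y")   # d = a - b2 = -q
  r2 <- compute_pt(a, b2)
  expect_equal(r2$pt, 150, tolerance = 1e-6)
  expect_true(r2$persistence_ok)

  # single-signed over the whole window: separated throughout
  b3 <- fz_evoked(rep(-1, length(times)), times, "y")
  r3 <- compute_pt(a, b3)
  expect_equal(r3$pt, 500)
  expect_false(r3$persistence_ok)

  # crossing interpolation lands between samples
  d4 <- times + 101  # zero at -101, between the -102 and -100 samples
  r4 <- compute_pt(fz_evoked(d4, times), fz_evoked(rep(0, length(times)),
                                                   times, "y"))
  expect_equal(r4$crossing_time, -101, tolerance = 1e-9)

  expect_error(compute_pt(a, b, window = c(-500, -100)), "end at the decision")
})

test_that("PT matches the exhaustive-scan oracle on random waveforms", {
  set.seed(123)
  n_cases <- 300
  agree <- 0
  for (i in seq_len(n_cases)) {
    w <- random_wave_pair(sample(50:1000, 1))
    a <- fz_evoked(w$a, w$times)
    b <- fz_evoked(w$b, w$times, "y")
    d <- w$a - w$b
    oracle <- pt_oracle(d, w$times)
    if (!is.null(oracle$error)) {
      expect_error(compute_pt(a, b, window = c(min(w$times), 0)))
      agree <- agree + 1
      next
    }
    got <- compute_pt(a, b, window = c(min(w$times), 0))
    if (isTRUE(all.equal(got$pt, oracle$pt)) &&
        got$persistence_ok == oracle$persistence_ok) agree <- agree + 1
  }
  expect_identical(agree, n_cases)
})

test_that("feedback-peak latency is the windowed argmax with early ties", {
  times <- seq(-100, 500, by = 2)
  g <- exp(-(times - 232)^2 / (2 * 50^2))
  loss <- fz_evoked(-g, times, "loss")
  gain <- fz_evoked(rep(0, length(times)), times, "gain")
  expect_equal(as.numeric(mfn_latency(loss, gain)), 232)

  # flat difference: earliest sample of the window (tie rule)
  flat <- fz_evoked(rep(1, length(times)), times, "loss")
  lat <- mfn_latency(flat, fz_evoked(rep(0, length(times)), times, "gain"))
  expect_equal(as.numeric(lat), 150)
  expect_true(attr(lat, "at_boundary"))

  # peak outside the window: boundary sample, flagged
  g2 <- exp(-(times - 100)^2 / (2 * 30^2))
  lat2 <- mfn_latency(fz_evoked(g2, times, "loss"), gain)
  expect_equal(as.numeric(lat2), 150)
  expect_true(attr(lat2, "at_boundary"))

  expect_error(mfn_latency(loss, gain, window = c(600, 700)), "empty")
})

test_that("max separation time and fractional-area latency behave", {
  times <- seq(-500, 0, by = 2)
  d <- exp(-(times + 50)^2 / (2 * 20^2))
  a <- fz_evoked(d, times)
  z <- fz_evoked(rep(0, length(times)), times, "y")
  expect_equal(max_separation_time(a, z), 50)

  mono <- fz_evoked((times + 500) / 500, times)
  expect_equal(max_separation_time(mono, z), 0)

  flat <- fz_evoked(rep(1, length(times)), times)
  expect_equal(max_separation_time(flat, z), 500)  # earliest sample tie rule

  tf <- seq(-100, 500, by = 2)
  bump <- exp(-(tf - 232)^2 / (2 * 50^2))
  expect_equal(fractional_area_latency(fz_evoked(bump, tf, "loss"),
                                       fz_evoked(rep(0, length(tf)), tf, "gain")),
               232, tolerance = 2)
})

test_that("matched-filter onset fit recovers ramp onsets", {
  times <- seq(-500, 0, by = 2)
  z <- fz_evoked(rep(0, length(times)), times, "y")
  for (onset in c(80, 106, 178, 300)) {  # on the 2 ms sample grid
    ramp <- ifelse(times > -onset, -(times + onset) / onset, 0)
    a <- fz_evoked(3 * ramp, times)
    expect_equal(fit_divergence_onset(a, z), onset)
  }
  # off-grid onset resolves to the nearest grid step
  ramp <- ifelse(times > -107, -(times + 107) / 107, 0)
  expect_lte(abs(fit_divergence_onset(fz_evoked(3 * ramp, times), z) - 107), 2)
  # moderate noise: recovery within a few samples
  set.seed(5)
  noisy <- fz_evoked(3 * ifelse(times > -150, -(times + 150) / 150, 0) +
                       rnorm(length(times), sd = 0.3), times)
  expect_lt(abs(fit_divergence_onset(noisy, z) - 150), 20)
})

test_that("scalp maps interpolate sensibly and are linear", {
  m <- montage_1020(19)
  times <- c(-2, 0, 2)
  mk <- function(vals) evoked(matrix(vals, nrow(m), 3), times, 500, m, "x", 1)

  tm <- topomap(mk(3), 0)
  expect_true(all(abs(tm$grid - 3) < 1e-9, na.rm = TRUE))
  # masked outside the head circle
  expect_true(is.na(tm$grid[1, 1]))

  # single hot channel: grid maximum at that channel's position
  v <- rep(0, nrow(m)); v[m$label == "C3"] <- 5
  e <- mk(0); e$data[, ] <- v
  tm2 <- topomap(e, 0)
  peak <- which(tm2$grid == max(tm2$grid, na.rm = TRUE), arr.ind = TRUE)[1, ]
  pos <- c(tm2$gx[peak[1]], tm2$gy[peak[2]])
  c3 <- unlist(m[m$label == "C3", c("x", "y")])
  expect_lt(sqrt(sum((pos - c3)^2)), 0.06)

  # linearity: map(a - b) == map(a) - map(b)
  set.seed(6)
  ea <- mk(0); ea$data[, ] <- rnorm(nrow(m))
  eb <- mk(0); eb$data[, ] <- rnorm(nrow(m))
  ed <- mk(0); ed$data <- ea$data - eb$data
  expect_equal(topomap(ed, 0)$grid,
               topomap(ea, 0)$grid - topomap(eb, 0)$grid, tolerance = 1e-9)

  expect_error(topomap(ea, 1), "time axis")
})

test_that("group statistics: summaries and permutation inference", {
  gs <- group_stats(list(a = c(1, 2, 3), b = c(1, 2, 3)), n_perm = 500)
  expect_equal(gs$summary$mean, c(2, 2))
  expect_equal(gs$summary$sd, c(1, 1))
  expect_gte(gs$pairwise$p[1], 0.9)  # identical groups: p near 1

  # complete separation at n = 10 per group: p at the permutation floor
  set.seed(7)
  x <- rnorm(10); y <- rnorm(10) + 10 * sd(x)
  t2 <- perm_test_unpaired(x, y, n_perm = 10000, seed = 2)
  expect_lte(t2$p, 0.001)

  tp <- perm_test_paired(1:10 + 100, 1:10, n_perm = 2000, seed = 3)
  expect_lte(tp$p, 0.01)
  tp0 <- perm_test_paired(1:10, 1:10, n_perm = 2000, seed = 3)
  expect_gte(tp0$p, 0.9)

  expect_error(group_stats(list(a = 1, b = c(1, 2))), "at least 2")
})
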