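#' Difference waveform of two evoked responses
#' @param a,b [evoked] objects on identical time axes and montages.
#' @return An [evoked] holding `a - b` (n = smaller trial count).
#' @export
difference_wave <- function(a, b) {
  stopifnot(inherits(a, "evoked"), inherits(b, "evoked"),
            isTRUE(all.equal(a$times, b$times)),
            identical(a$channels, b$channels))
  evoked(a$data - b$data, a$times, a$sampling_rate, a$montage,
         sprintf("%s - %s", a$condition, b$condition), min(a$n, b$n))
}

#' Prestimulus time (PT): last pre-decision intersection of two waveforms
#'
#' The PT is the time before the decision at which the two condition-average
#' waveforms last intersect and stay separated through t = 0. Concretely,
#' with d(t) = a(t) - b(t) at the chosen channel, the crossing time t* is
#' the latest t < 0 at which the curves intersect -- d changes sign between
#' consecutive samples (position refined by linear interpolation) or
#' coincides with zero within `tol` -- such that the sign of d is constant
#' on (t*, 0]; PT = -t*.
#'
#' If d never changes sign inside the search window but is single-signed
#' throughout, the waveforms are separated for the whole window: PT is the
#' window length and `persistence_ok` is `FALSE` (the true intersection
#' lies before the window). If d is zero everywhere within tolerance the
#' waveforms are not separated and an error is raised.
#'
#' @param a,b [evoked] waveforms on identical time axes.
#' @param channel Channel to compare (default `"Fz"`).
#' @param window Search window in ms, ending at 0 (default (-500, 0)).
#' @param tol Separation tolerance in microvolts: |d| below this counts as
#'   "not separated" (default 1e-9).
#' @return A list of class `pt_result`: `pt` (ms, >= 0), `crossing_time`
#'   (ms, < 0), `channel`, `persistence_ok`.
#' @export
compute_pt <- function(a, b, channel = "Fz", window = c(-500, 0),
                       tol = 1e-9) {
  stopifnot(inherits(a, "evoked"), inherits(b, "evoked"),
            isTRUE(all.equal(a$times, b$times)))
  if (abs(window[2]) > 1e-9)
    stop("compute_pt: search window must end at the decision (t = 0)")
  idx <- which(a$times >= window[1] - 1e-9 & a$times <= 1e-9)
  if (length(idx) < 2)
    stop("compute_pt: search window not on the time axis")
  t_ax <- a$times[idx]
  d <- channel_trace(a, channel)[idx] - channel_trace(b, channel)[idx]
  if (max(abs(d)) < tol)
    stop("compute_pt: waveforms are not separated (no intersection to find)")
  s <- sign(d)
  s[abs(d) < tol] <- 0
  # intersection candidates: samples where the curves coincide (|d| < tol)
  # and interpolated zero-crossings between successive nonzero samples of
  # opposite sign (zero-runs between them are already candidates)
  cand <- t_ax[s == 0]
  for (k in seq_len(length(d) - 1)) {
    if (s[k] != 0 && s[k + 1] != 0 && s[k] != s[k + 1]) {
      cand <- c(cand, t_ax[k] + (t_ax[k + 1] - t_ax[k]) *
                  d[k] / (d[k] - d[k + 1]))
    }
  }
  if (length(cand) == 0) {
    # single-signed throughout: separated over the whole window; the true
    # intersection lies before it
    return(structure(list(pt = window[2] - window[1],
                          crossing_time = window[1], channel = channel,
                          persistence_ok = FALSE),
                     class = "pt_result"))
  }
  t_star <- max(cand)
  # persistence: a single nonzero sign from the intersection through t = 0
  after_signs <- s[t_ax > t_star + 1e-9]
  tail_signs <- unique(after_signs[after_signs != 0])
  persistence_ok <- length(tail_signs) == 1 && s[length(s)] != 0
  structure(list(pt = -t_star, crossing_time = t_star, channel = channel,
                 persistence_ok = persistence_ok),
            class = "pt_result")
}

#' @export
print.pt_result <- function(x, ...) {
  cat(sprintf("PT = %.1f ms before the decision (channel %s, crossing at %.1f ms%s)\n",
              x$pt, x$channel, x$crossing_time,
              if (x$persistence_ok) "" else "; separation not persistent"))
  invisible(x)
}

#' Latency of the feedback-locked loss/gain divergence (MFN peak)
#'
#' The latency at which |loss(t) - gain(t)| is maximal inside the search
#' window, at sample resolution; ties resolve to the earliest sample. If
#' the maximum sits on a window boundary the returned value carries
#' attribute `at_boundary = TRUE` (the true peak may lie outside).
#'
#' @param evoked_loss,evoked_gain [evoked] waveforms.
#' @param channel Channel (default `"Fz"`).
#' @param window Search window in ms (default (150, 350), bracketing the
#'   medial-frontal negativity).
#' @return Latency in ms (numeric scalar with attribute `at_boundary`).
#' @export
mfn_latency <- function(evoked_loss, evoked_gain, channel = "Fz",
                        window = c(150, 350)) {
  stopifnot(inherits(evoked_loss, "evoked"), inherits(evoked_gain, "evoked"))
  t_ax <- evoked_loss$times
  idx <- which(t_ax >= window[1] - 1e-9 & t_ax <= window[2] + 1e-9)
  if (length(idx) == 0)
    stop("mfn_latency: empty search window")
  d <- abs(channel_trace(evoked_loss, channel)[idx] -
             channel_trace(evoked_gain, channel)[idx])
  k <- which.max(d)  # which.max takes the first (earliest) maximum
  lat <- t_ax[idx[k]]
  attr(lat, "at_boundary") <- k == 1L || k == length(idx)
  lat
}

#' Loss/gain delta amplitude
#'
#' The absolute difference between the gain and loss evoked amplitudes at
#' the feedback-component latency. Symmetric in its arguments and invariant
#' under a common shift.
#'
#' @param loss_amp,gain_amp Amplitudes in microvolts.
#' @return Delta in microvolts (>= 0).
#' @examples
#' delta_amplitude(-0.34, 0.37)  # 0.71
#' @export
delta_amplitude <- function(loss_amp, gain_amp) abs(gain_amp - loss_amp)

#' Mean amplitude around a latency
#'
#' Standard ERP mean-amplitude measure: the average of a channel's waveform
#' over `latency +/- halfwidth` ms (more noise-robust than a single-sample
#' peak reading).
#'
#' @param x An [evoked].
#' @param channel Channel name.
#' @param latency Center of the measurement window, ms.
#' @param halfwidth Half-width of the window, ms (default 20; 0 reads the
#'   single nearest sample).
#' @return Mean amplitude in microvolts.
#' @export
amplitude_at <- function(x, channel, latency, halfwidth = 20) {
  stopifnot(inherits(x, "evoked"))
  tr <- channel_trace(x, channel)
  idx <- which(x$times >= latency - halfwidth - 1e-9 &
                 x$times <= latency + halfwidth + 1e-9)
  if (length(idx) == 0)
    stop("amplitude_at: window off the time axis")
  mean(tr[idx])
}

#' Fractional-area latency of the loss/gain divergence
#'
#' The time at which the cumulative area under |loss(t) - gain(t)| inside
#' the window reaches `frac` of its total. Markedly more noise-robust than
#' peak picking for latency estimation because the noise integrates out.
#'
#' @inheritParams mfn_latency
#' @param frac Area fraction (default 0.5, the half-area latency).
#' @return Latency in ms.
#' @export
fractional_area_latency <- function(evoked_loss, evoked_gain, channel = "Fz",
                                    window = c(150, 350), frac = 0.5) {
  stopifnot(inherits(evoked_loss, "evoked"), inherits(evoked_gain, "evoked"))
  t_ax <- evoked_loss$times
  idx <- which(t_ax >= window[1] - 1e-9 & t_ax <= window[2] + 1e-9)
  if (length(idx) == 0) stop("fractional_area_latency: empty search window")
  d <- abs(channel_trace(evoked_loss, channel)[idx] -
             channel_trace(evoked_gain, channel)[idx])
  a <- cumsum(d)
  t_ax[idx[which.min(abs(a - frac * a[length(a)]))]]
}

#' Fit the pre-decision divergence onset by matched filtering
#'
#' Models the condition difference as a linear ramp that starts at the
#' divergence onset and grows until the decision (t = 0), and estimates the
#' onset as the ramp duration maximizing the normalized inner product
#' between the observed difference and the ramp template. Because the fit
#' integrates over the whole ramp, it remains stable at single-subject
#' signal-to-noise ratios where the literal last zero-crossing of a noisy
#' difference waveform wanders by tens of milliseconds.
#'
#' @param a,b [evoked] waveforms (e.g. left- and right-choice averages).
#' @param channel Channel to fit (default `"Fz"`).
#' @param window Search window ending at 0, ms.
#' @param polarity Sign of the divergence (`-1` for a negative-going
#'   left-choice ramp); default the sign of the mean difference over the
#'   last 50 ms before the decision.
#' @param min_onset Smallest onset considered, ms (default 20).
#' @return Onset in ms before the decision.
#' @export
fit_divergence_onset <- function(a, b, channel = "Fz", window = c(-500, 0),
                                 polarity = NULL, min_onset = 20) {
  stopifnot(inherits(a, "evoked"), inherits(b, "evoked"),
            isTRUE(all.equal(a$times, b$times)))
  t_ax <- a$times
  idx <- which(t_ax >= window[1] - 1e-9 & t_ax <= 1e-9)
  tt <- t_ax[idx]
  d <- channel_trace(a, channel)[idx] - channel_trace(b, channel)[idx]
  if (is.null(polarity))
    polarity <- sign(mean(d[tt >= -50]))
  if (polarity == 0) stop("fit_divergence_onset: zero difference near t = 0")
  step <- 1000 / a$sampling_rate
  onsets <- seq(min_onset, -window[1], by = step)
  score <- vapply(onsets, function(o) {
    templ <- ifelse(tt > -o, (tt + o) / o, 0)
    polarity * sum(d * templ) / sqrt(sum(templ^2))
  }, 0)
  onsets[which.max(score)]
}

#' Time of maximal pre-decision separation
#'
#' The time before the decision at which |a(t) - b(t)| is largest inside
#' the window (the rationale for mapping the scalp shortly before the
#' choice). Ties resolve to the earliest sample.
#'
#' @inheritParams compute_pt
#' @return ms before the decision (>= 0).
#' @export
max_separation_time <- function(a, b, channel = "Fz", window = c(-500, 0)) {
  stopifnot(inherits(a, "evoked"), inherits(b, "evoked"))
  t_ax <- a$times
  idx <- which(t_ax >= window[1] - 1e-9 & t_ax <= window[2] + 1e-9)
  if (length(idx) == 0) stop("max_separation_time: empty window")
  d <- abs(channel_trace(a, channel)[idx] - channel_trace(b, channel)[idx])
  -t_ax[idx[which.max(d)]]
}

#' Scalp topographic map at one latency
#'
#' Reads every channel's value at the given latency and interpolates onto a
#' square raster over the unit head circle with inverse-distance weighting
#' (power 2); raster points outside the convex hull of the electrodes take
#' the nearest electrode's value, and points outside the head circle are
#' masked `NA`. EOG channels are excluded.
#'
#' @param x An [evoked] (or difference) waveform.
#' @param latency Latency in ms; must lie on the time axis.
#' @param grid_n Raster resolution per side (default 67).
#' @return A list of class `topomap`: `latency`, `values` (named
#'   per-channel vector), `grid` (grid_n x grid_n matrix), `gx`, `gy`.
#' @export
topomap <- function(x, latency, grid_n = 67) {
  stopifnot(inherits(x, "evoked"))
  k <- which(abs(x$times - latency) < 1e-6)
  if (length(k) != 1)
    stop("topomap: latency does not lie on the waveform's time axis")
  eeg <- which(!x$montage$eog)
  px <- x$montage$x[eeg]; py <- x$montage$y[eeg]
  v <- x$data[eeg, k]
  names(v) <- x$montage$label[eeg]
  gx <- seq(-1, 1, length.out = grid_n)
  gy <- seq(-1, 1, length.out = grid_n)
  pts <- expand.grid(x = gx, y = gy)
  inside <- pts$x^2 + pts$y^2 <= 1
  hull <- grDevices::chull(px, py)
  in_hull <- rep(FALSE, nrow(pts))
  in_hull[inside] <- mgcv::in.out(cbind(px, py)[c(hull, hull[1]), ],
                                  as.matrix(pts[inside, ]))
  z <- rep(NA_real_, nrow(pts))
  for (i in which(inside)) {
    d2 <- (px - pts$x[i])^2 + (py - pts$y[i])^2
    if (any(d2 < 1e-12)) {
      z[i] <- v[which.min(d2)]
    } else if (in_hull[i]) {
      w <- 1 / d2
      z[i] <- sum(w * v) / sum(w)
    } else {
      z[i] <- v[which.min(d2)]
    }
  }
  structure(list(latency = latency, values = v,
                 grid = matrix(z, grid_n, grid_n), gx = gx, gy = gy),
            class = "topomap")
}

#' Plot a scalp map
#' @param x A [topomap].
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.topomap <- function(x, ...) {
  graphics::image(x$gx, x$gy, x$grid, asp = 1, xlab = "", ylab = "",
                  main = sprintf("%g ms", x$latency),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(cos(th), sin(th))
  invisible(x)
}

#' Two-sample permutation test on the difference of means
#'
#' @param x,y Numeric vectors (independent groups).
#' @param n_perm Number of random label shuffles (default 10000).
#' @param seed RNG seed (fixed for reproducibility).
#' @return list with `statistic` (mean(x) - mean(y)) and two-sided `p`.
#' @export
perm_test_unpaired <- function(x, y, n_perm = 10000, seed = 1L) {
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  nx <- length(x)
  with_local_seed(seed, {
    null <- replicate(n_perm, {
      i <- sample.int(length(pool), nx)
      mean(pool[i]) - mean(pool[-i])
    })
    list(statistic = obs,
         p = (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_perm + 1))
  })
}

#' Paired sign-flip permutation test
#'
#' @param x,y Numeric vectors of equal length (paired observations).
#' @inheritParams perm_test_unpaired
#' @return list with `statistic` (mean(x - y)) and two-sided `p`.
#' @export
perm_test_paired <- function(x, y, n_perm = 10000, seed = 1L) {
  d <- x - y
  obs <- mean(d)
  with_local_seed(seed, {
    null <- replicate(n_perm, mean(d * sample(c(-1, 1), length(d),
                                              replace = TRUE)))
    list(statistic = obs,
         p = (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_perm + 1))
  })
}

#' Group-level summary and between-group permutation inference
#'
#' Mean and SD per group plus a two-sided permutation test (random label
#' shuffles of the pooled values) for every pair of groups.
#'
#' @param values_by_group Named list of numeric vectors, one per group
#'   (>= 2 subjects each).
#' @inheritParams perm_test_unpaired
#' @return list with `summary` (group, n, mean, sd) and `pairwise`
#'   (group1, group2, diff, p) data.frames.
#' @export
group_stats <- function(values_by_group, n_perm = 10000, seed = 1L) {
  if (any(lengths(values_by_group) < 2))
    stop("group_stats: every group needs at least 2 subjects")
  gn <- names(values_by_group)
  if (is.null(gn)) gn <- as.character(seq_along(values_by_group))
  summary <- data.frame(group = gn,
                        n = lengths(values_by_group),
                        mean = vapply(values_by_group, mean, 0),
                        sd = vapply(values_by_group, stats::sd, 0),
                        row.names = NULL)
  pairs <- utils::combn(seq_along(values_by_group), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tst <- perm_test_unpaired(values_by_group[[i1]], values_by_group[[i2]],
                              n_perm, seed + j)
    data.frame(group1 = gn[i1], group2 = gn[i2],
               diff = tst$statistic, p = tst$p)
  }))
  list(summary = summary, pairwise = pairwise)
}
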