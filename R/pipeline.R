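#' Preprocessing parameters
#'
#' Bundles the preprocessing chain's tunables: epoch windows, baseline
#' windows (half-open, ms), the artifact-scan window and threshold, the
#' low-pass cutoff, and whether to run the independent-component ocular
#' removal stage.
#'
#' @param ocular Run correlation-gated ICA ocular removal on the continuous
#'   recording before epoching.
#' @param corr_threshold Absolute EOG correlation above which a component
#'   is removed.
#' @param amplitude_threshold Epoch-rejection threshold, microvolts.
#' @param scan_window Artifact-scan window, ms.
#' @param window_decision,window_feedback Epoch windows, ms.
#' @param baseline_decision,baseline_feedback Baseline windows, ms.
#' @param cutoff Low-pass cutoff, Hz.
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(ocular = TRUE, corr_threshold = 0.7,
                              amplitude_threshold = 100,
                              scan_window = c(-200, 500),
                              window_decision = c(-500, 0),
                              window_feedback = c(-100, 500),
                              baseline_decision = c(-500, -400),
                              baseline_feedback = c(-100, 0),
                              cutoff = 30) {
  structure(as.list(environment()), class = "preprocess_params")
}

#' Run the preprocessing chain on one session
#'
#' Applies, in order: ocular-component removal on the continuous recording
#' (optional), decision- and feedback-locked epoching, constant-method
#' baseline correction, amplitude-threshold rejection, per-condition
#' averaging, zero-phase low-pass filtering of the averages, and common
#' average referencing.
#'
#' @param session list with `raw` and `events` (as returned by
#'   [generate_session()] or [read_edf()]).
#' @param params A [preprocess_params()].
#' @return list with `decision` (evoked `left`, `right`), `feedback`
#'   (evoked `gain`, `loss`), per-lock kept/total counts, and
#'   `removed_components`.
#' @export
preprocess_session <- function(session, params = preprocess_params()) {
  raw <- session$raw
  removed <- 0L
  if (isTRUE(params$ocular)) {
    oc <- remove_ocular(raw, corr_threshold = params$corr_threshold)
    raw <- oc$raw
    removed <- oc$removed
  }
  finish <- function(ep, conditions) {
    out <- lapply(conditions, function(cond) {
      average_reference(lowpass_filter(average_epochs(ep, cond),
                                       params$cutoff))
    })
    names(out) <- conditions
    out$n_total <- dim(ep$data)[1]
    out$n_kept <- n_kept(ep)
    out
  }
  dec <- reject_epochs(
    baseline_correct(
      extract_epochs(raw, session$events, "decision", params$window_decision),
      params$baseline_decision),
    params$amplitude_threshold, params$scan_window)
  fb <- reject_epochs(
    baseline_correct(
      extract_epochs(raw, session$events, "feedback", params$window_feedback),
      params$baseline_feedback),
    params$amplitude_threshold, params$scan_window)
  list(decision = finish(dec, c("left", "right")),
       feedback = finish(fb, c("loss", "gain")),
       removed_components = removed)
}

#' Equal-weight grand average of evoked waveforms
#' @param evoked_list list of [evoked] objects on identical axes.
#' @return An [evoked]; `n` is the number of waveforms averaged.
#' @export
grand_average <- function(evoked_list) {
  stopifnot(length(evoked_list) >= 1)
  acc <- Reduce(`+`, lapply(evoked_list, function(e) e$data))
  e1 <- evoked_list[[1]]
  evoked(acc / length(evoked_list), e1$times, e1$sampling_rate, e1$montage,
         e1$condition, length(evoked_list))
}

#' Analysis parameters
#'
#' @param channel Analysis channel (default `"Fz"`, indexing the medial
#'   frontal cortex).
#' @param pt_window Pre-decision search window for the PT, ms.
#' @param mfn_window Post-feedback search window for the loss/gain peak, ms.
#' @param amp_halfwidth Half-width of the mean-amplitude window, ms.
#' @param n_permutations Permutations for group tests.
#' @param pt_mode How per-subject PT values are obtained: `"matched"`
#'   (default) fits each subject's divergence onset by ramp matched
#'   filtering ([fit_divergence_onset()]; stable at single-subject SNR);
#'   `"independent"` runs [compute_pt()] on each subject's own averages
#'   (the literal last-crossing, noisy for single subjects); `"grand"`
#'   reports the grand-average last-crossing PT alone.
#' @param latency_method How the feedback-component measurement latency is
#'   estimated from a grand-average difference: `"fractional_area"`
#'   (default, half-area latency; noise-robust) or `"peak"`
#'   ([mfn_latency()] argmax).
#' @param amp_method How per-subject feedback amplitudes are measured:
#'   `"regression"` (default) projects each subject's waveform onto the
#'   grand-average component shape (centered least squares;
#'   peak-microvolt scale, no window-attenuation bias), or `"mean"`, the
#'   classic mean amplitude over `latency +/- amp_halfwidth`, which has
#'   marginally lower variance but systematically under-reads a peaked
#'   component by the window's attenuation factor.
#' @return list of class `analysis_params`.
#' @export
analysis_params <- function(channel = "Fz", pt_window = c(-500, 0),
                            mfn_window = c(150, 350), amp_halfwidth = 20,
                            n_permutations = 10000,
                            pt_mode = c("matched", "independent", "grand"),
                            latency_method = c("fractional_area", "peak"),
                            amp_method = c("regression", "mean")) {
  pt_mode <- match.arg(pt_mode)
  latency_method <- match.arg(latency_method)
  amp_method <- match.arg(amp_method)
  structure(as.list(environment()), class = "analysis_params")
}

# Component shape template from a grand-average loss/gain difference,
# normalized to +1 at its (signed) extremum so regression coefficients
# read as peak amplitudes in microvolts at the analysis channel. The
# extremum value comes from a local quadratic apex fit rather than the raw
# sample maximum: the max of a noisy curve is upward-biased by selection,
# which would deflate every regression coefficient by the same factor.
feedback_template <- function(g_loss, g_gain, channel, window) {
  t_ax <- g_loss$times
  idx <- which(t_ax >= window[1] - 1e-9 & t_ax <= window[2] + 1e-9)
  d <- channel_trace(g_loss, channel)[idx] - channel_trace(g_gain, channel)[idx]
  k <- which.max(abs(d))
  i <- max(1, k - 10):min(length(d), k + 10)
  apex <- d[k]
  if (length(i) >= 7) {
    co <- unname(stats::coef(stats::lm(d[i] ~ I(i) + I(i^2))))
    cand <- co[1] - co[2]^2 / (4 * co[3])
    if (is.finite(cand) && sign(cand) == sign(d[k]) &&
        abs(cand) > 0.5 * abs(d[k]) && abs(cand) < 2 * abs(d[k]))
      apex <- cand
  }
  list(idx = idx, shape = d / apex)
}

# Template-regression amplitude: least-squares projection onto the
# component shape (baseline offsets removed by centering both).
amp_regression <- function(evk, channel, templ) {
  x <- channel_trace(evk, channel)[templ$idx]
  s <- templ$shape - mean(templ$shape)
  sum((x - mean(x)) * s) / sum(s^2)
}

feedback_latency <- function(g_loss, g_gain, analysis) {
  if (analysis$latency_method == "fractional_area")
    fractional_area_latency(g_loss, g_gain, analysis$channel,
                            analysis$mfn_window)
  else
    as.numeric(mfn_latency(g_loss, g_gain, analysis$channel,
                           analysis$mfn_window))
}

#' Analyze one block (cohort of preprocessed subjects)
#'
#' PT: the grand-average last-crossing PT ([compute_pt()]) is always
#' reported; per-subject PT values come, in the default `"matched"` mode,
#' from each subject's ramp matched-filter onset fit
#' ([fit_divergence_onset()]; single-subject averages are too noisy for a
#' stable last-crossing of their own, see the methods vignette), or from
#' the subject's own last-crossing in `"independent"` mode.
#'
#' Feedback: the loss/gain peak latency is taken from the grand-average
#' difference (or from `measure_latency`, typically a collapsed localizer
#' pooled over blocks); per-subject loss and gain mean amplitudes are read
#' around that latency, the group delta is the absolute difference of the
#' loss and gain group means, and loss vs gain is tested with a paired
#' sign-flip permutation test.
#'
#' @param subjects list of [preprocess_session()] results.
#' @param analysis An [analysis_params()].
#' @param seed Seed for the permutation test.
#' @param measure_latency Latency (ms) at which amplitudes are measured
#'   (and reported); default the block's own grand-average latency via
#'   `latency_method`.
#' @param template Component shape template for regression amplitudes
#'   (typically pooled over blocks); default the block's own.
#' @return list with `pt` (per-subject ms), `pt_mean`, `pt_sd`, `pt_grand`,
#'   `mfn_latency_ms` (block peak), `measure_latency_ms`, `loss`, `gain`
#'   (per-subject amplitudes), group means/SDs, `delta`, `p_loss_vs_gain`,
#'   and the grand-average waveforms.
#' @export
analyze_block <- function(subjects, analysis = analysis_params(), seed = 1L,
                          measure_latency = NULL, template = NULL) {
  ch <- analysis$channel
  g_left <- grand_average(lapply(subjects, function(s) s$decision$left))
  g_right <- grand_average(lapply(subjects, function(s) s$decision$right))
  pt_grand <- compute_pt(g_left, g_right, ch, analysis$pt_window)$pt
  if (analysis$pt_mode == "independent") {
    pt <- vapply(subjects, function(s) {
      compute_pt(s$decision$left, s$decision$right, ch, analysis$pt_window)$pt
    }, 0)
  } else if (analysis$pt_mode == "grand") {
    pt <- pt_grand
  } else {
    pol <- sign(mean((channel_trace(g_left, ch) -
                        channel_trace(g_right, ch))[g_left$times >= -50]))
    pt <- vapply(subjects, function(s) {
      fit_divergence_onset(s$decision$left, s$decision$right, ch,
                           analysis$pt_window, polarity = pol)
    }, 0)
  }
  g_loss <- grand_average(lapply(subjects, function(s) s$feedback$loss))
  g_gain <- grand_average(lapply(subjects, function(s) s$feedback$gain))
  lat <- mfn_latency(g_loss, g_gain, ch, analysis$mfn_window)
  meas <- measure_latency %||% feedback_latency(g_loss, g_gain, analysis)
  if (analysis$amp_method == "regression") {
    templ <- template %||% feedback_template(g_loss, g_gain, ch,
                                             analysis$mfn_window)
    loss <- vapply(subjects, function(s)
      amp_regression(s$feedback$loss, ch, templ), 0)
    gain <- vapply(subjects, function(s)
      amp_regression(s$feedback$gain, ch, templ), 0)
  } else {
    loss <- vapply(subjects, function(s)
      amplitude_at(s$feedback$loss, ch, meas, analysis$amp_halfwidth), 0)
    gain <- vapply(subjects, function(s)
      amplitude_at(s$feedback$gain, ch, meas, analysis$amp_halfwidth), 0)
  }
  p_lg <- if (length(subjects) >= 2)
    perm_test_paired(loss, gain, analysis$n_permutations, seed)$p else NA_real_
  list(pt = pt, pt_mean = mean(pt), pt_sd = stats::sd(pt),
       pt_grand = pt_grand,
       mfn_latency_ms = as.numeric(lat), measure_latency_ms = meas,
       latency_at_boundary = isTRUE(attr(lat, "at_boundary")),
       loss = loss, gain = gain,
       loss_mean = mean(loss), loss_sd = stats::sd(loss),
       gain_mean = mean(gain), gain_sd = stats::sd(gain),
       delta = delta_amplitude(mean(loss), mean(gain)),
       p_loss_vs_gain = p_lg,
       grand_loss = g_loss, grand_gain = g_gain,
       grand_left = grand_average(lapply(subjects, function(s) s$decision$left)),
       grand_right = grand_average(lapply(subjects, function(s) s$decision$right)))
}

#' Run configuration for a full simulated study
#'
#' One entry per block (experiment); each block's reward parameter E is the
#' left stake over the right stake. The defaults mirror the three-block
#' design (X = 25, 35, 50 against 5; onsets growing and feedback effects
#' strengthening with E).
#'
#' @param blocks list of per-block lists with fields `left_value`,
#'   `right_value`, `divergence_onset`, `divergence_amplitude`,
#'   `loss_amplitude`, `gain_amplitude`.
#' @param n_subjects Cohort size per block.
#' @param n_trials Trials per session.
#' @param sampling_rate Hz.
#' @param montage_channels 19 or 63 EEG channels.
#' @param noise_rms Background 1/f RMS, microvolts.
#' @param blink_rate Blinks per minute.
#' @param mfn_latency_ms Configured feedback-peak latency, ms.
#' @param onset_sd,amplitude_sd,latency_sd Between-subject SDs.
#' @param preprocess A [preprocess_params()].
#' @param analysis An [analysis_params()].
#' @param seed Integer master seed (mandatory).
#' @return list of class `run_config`.
#' @export
run_config <- function(blocks = default_blocks(), n_subjects = 36,
                       n_trials = n_trials_for(), sampling_rate = 500,
                       montage_channels = 63, noise_rms = 5, blink_rate = 6,
                       mfn_latency_ms = 232,
                       onset_sd = 9, amplitude_sd = 0.1, latency_sd = 5,
                       preprocess = preprocess_params(),
                       analysis = analysis_params(), seed) {
  if (missing(seed)) stop("run_config: a seed is mandatory")
  if (length(blocks) == 0) stop("run_config: at least one block is required")
  for (b in blocks) {
    need <- c("left_value", "right_value", "divergence_onset",
              "divergence_amplitude", "loss_amplitude", "gain_amplitude")
    if (!all(need %in% names(b)))
      stop("run_config: each block needs fields ",
           paste(need, collapse = ", "))
  }
  structure(list(blocks = blocks, n_subjects = n_subjects,
                 n_trials = n_trials, sampling_rate = sampling_rate,
                 montage_channels = montage_channels, noise_rms = noise_rms,
                 blink_rate = blink_rate, mfn_latency_ms = mfn_latency_ms,
                 onset_sd = onset_sd, amplitude_sd = amplitude_sd,
                 latency_sd = latency_sd, preprocess = preprocess,
                 analysis = analysis, seed = as.integer(seed)),
            class = "run_config")
}

#' Default three-block design
#'
#' The three gambling blocks: stakes 25/35/50 against 5 (E = 5, 7, 10),
#' pre-decision divergence onsets 107/144/178 ms with amplitude deepening
#' with E, and feedback amplitudes (loss, gain) of (-0.34, +0.37),
#' (+0.52, +2.04), (+0.32, +2.15) microvolts at Fz.
#'
#' @return list of block definitions for [run_config()].
#' @export
default_blocks <- function() {
  list(
    list(left_value = 25, right_value = 5, divergence_onset = 107,
         divergence_amplitude = -6, loss_amplitude = -0.34,
         gain_amplitude = 0.37),
    list(left_value = 35, right_value = 5, divergence_onset = 144,
         divergence_amplitude = -9, loss_amplitude = 0.52,
         gain_amplitude = 2.04),
    list(left_value = 50, right_value = 5, divergence_onset = 178,
         divergence_amplitude = -12, loss_amplitude = 0.32,
         gain_amplitude = 2.15))
}

#' Read / write a run configuration as JSON
#' @param path JSON path.
#' @return [read_run_config()] returns a `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  pp <- do.call(preprocess_params, j$preprocess %||% list())
  ap <- do.call(analysis_params, j$analysis %||% list())
  j$preprocess <- NULL; j$analysis <- NULL
  do.call(run_config, c(j, list(preprocess = pp, analysis = ap)))
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_run_config(config, f)
  unname(tools::md5sum(f))
}

#' Simulate, preprocess and analyze a full study
#'
#' Generates one cohort per block (subject k of block b uses seed
#' `seed + 10000*b + k`), runs the preprocessing chain per subject, the
#' block-level PT and feedback analyses, and between-block permutation
#' tests on PT and on the per-subject gain-loss differences. Deterministic
#' given the configuration (the report embeds the config hash and seed).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory; if non-`NULL`, writes `report.json`,
#'   CSV tables (`pt_table.csv`, `mfn_table.csv`, `rejection.csv`) and PNG
#'   scalp maps.
#' @return The report list, invisibly with attribute `paths` when written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  blocks <- lapply(seq_along(config$blocks), function(b) {
    blk <- config$blocks[[b]]
    cfg <- experiment_config(
      blk$left_value, blk$right_value, n_trials = config$n_trials,
      sampling_rate = config$sampling_rate,
      montage = montage_1020(config$montage_channels),
      seed = config$seed + 10000L * b)
    eff <- session_effects(
      divergence_onset = blk$divergence_onset,
      divergence_amplitude = blk$divergence_amplitude,
      mfn_latency = config$mfn_latency_ms,
      loss_amplitude = blk$loss_amplitude,
      gain_amplitude = blk$gain_amplitude,
      noise_rms = config$noise_rms, blink_rate = config$blink_rate)
    sessions <- generate_cohort(config$n_subjects, cfg, eff,
                                config$onset_sd, config$amplitude_sd,
                                config$latency_sd)
    subjects <- lapply(sessions, preprocess_session, params = config$preprocess)
    list(E = cfg$E, truths = lapply(sessions, `[[`, "truth"),
         subjects = subjects)
  })

  # collapsed localizer: the feedback-component measurement latency comes
  # from the loss/gain difference pooled over every subject of every block
  all_subjects <- unlist(lapply(blocks, `[[`, "subjects"), recursive = FALSE)
  pooled_loss <- grand_average(lapply(all_subjects, function(s) s$feedback$loss))
  pooled_gain <- grand_average(lapply(all_subjects, function(s) s$feedback$gain))
  pooled_lat <- feedback_latency(pooled_loss, pooled_gain, config$analysis)
  pooled_templ <- feedback_template(pooled_loss, pooled_gain,
                                    config$analysis$channel,
                                    config$analysis$mfn_window)

  for (b in seq_along(blocks)) {
    blocks[[b]]$analysis <- analyze_block(blocks[[b]]$subjects,
                                          config$analysis,
                                          seed = config$seed + b,
                                          measure_latency = as.numeric(pooled_lat),
                                          template = pooled_templ)
  }

  Es <- vapply(blocks, `[[`, 0, "E")
  pt_by_block <- lapply(blocks, function(b) b$analysis$pt)
  names(pt_by_block) <- sprintf("E=%g", Es)
  dsig_by_block <- lapply(blocks, function(b) b$analysis$gain - b$analysis$loss)
  names(dsig_by_block) <- names(pt_by_block)
  np <- config$analysis$n_permutations
  pt_stats <- group_stats(pt_by_block, np, seed = config$seed + 101L)
  delta_stats <- group_stats(dsig_by_block, np, seed = config$seed + 202L)

  pt_table <- data.frame(
    E = Es,
    n = vapply(blocks, function(b) length(b$analysis$pt), 0L),
    pt_mean_ms = round(vapply(blocks, function(b) b$analysis$pt_mean, 0)),
    pt_sd_ms = round(vapply(blocks, function(b) b$analysis$pt_sd, 0), 1))
  mfn_table <- data.frame(
    E = Es,
    loss_uV = vapply(blocks, function(b) b$analysis$loss_mean, 0),
    loss_sd = vapply(blocks, function(b) b$analysis$loss_sd, 0),
    gain_uV = vapply(blocks, function(b) b$analysis$gain_mean, 0),
    gain_sd = vapply(blocks, function(b) b$analysis$gain_sd, 0),
    latency_ms = vapply(blocks, function(b) b$analysis$mfn_latency_ms, 0),
    measure_latency_ms = vapply(blocks, function(b) b$analysis$measure_latency_ms, 0),
    delta_uV = vapply(blocks, function(b) b$analysis$delta, 0),
    p_loss_vs_gain = vapply(blocks, function(b) b$analysis$p_loss_vs_gain, 0))
  rejection <- do.call(rbind, lapply(seq_along(blocks), function(b) {
    s <- blocks[[b]]$subjects
    data.frame(E = Es[b], subject = seq_along(s),
               dec_kept = vapply(s, function(x) x$decision$n_kept, 0),
               dec_total = vapply(s, function(x) x$decision$n_total, 0),
               fb_kept = vapply(s, function(x) x$feedback$n_kept, 0),
               fb_total = vapply(s, function(x) x$feedback$n_total, 0),
               ica_removed = vapply(s, function(x) x$removed_components, 0L))
  }))

  report <- list(
    provenance = list(
      package = "prestim",
      version = as.character(utils::packageVersion("prestim")),
      config_hash = config_hash(config),
      seed = config$seed,
      stage_order = c("ocular_removal", "epoching", "baseline_correction",
                      "amplitude_rejection", "averaging", "lowpass_filter",
                      "average_reference")),
    pooled_mfn_latency_ms = as.numeric(pooled_lat),
    pt_table = pt_table,
    pt_grand_ms = vapply(blocks, function(b) b$analysis$pt_grand, 0),
    pt_per_subject = pt_by_block,
    pt_pairwise = pt_stats$pairwise,
    mfn_table = mfn_table,
    delta_pairwise = delta_stats$pairwise,
    rejection = rejection)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      report = file.path(out_dir, "report.json"),
      pt = file.path(out_dir, "pt_table.csv"),
      mfn = file.path(out_dir, "mfn_table.csv"),
      rejection = file.path(out_dir, "rejection.csv"))
    jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    utils::write.csv(pt_table, paths["pt"], row.names = FALSE)
    utils::write.csv(mfn_table, paths["mfn"], row.names = FALSE)
    utils::write.csv(rejection, paths["rejection"], row.names = FALSE)
    for (b in seq_along(blocks)) {
      a <- blocks[[b]]$analysis
      diff_dec <- difference_wave(a$grand_left, a$grand_right)
      t50 <- diff_dec$times[which.min(abs(diff_dec$times + 50))]
      tm <- a$grand_loss$times[which.min(abs(a$grand_loss$times -
                                               a$mfn_latency_ms))]
      png_path <- file.path(out_dir, sprintf("topomap_E%g.png", Es[b]))
      grDevices::png(png_path, width = 900, height = 320)
      op <- graphics::par(mfrow = c(1, 3))
      plot(topomap(diff_dec, t50))
      plot(topomap(a$grand_loss, tm))
      plot(topomap(a$grand_gain, tm))
      graphics::par(op)
      grDevices::dev.off()
      paths[sprintf("topomap_E%g", Es[b])] <- png_path
    }
    attr(report, "paths") <- paths
  }
  invisible(report)
}
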