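# Small builders used across test files. All fixtures are generated in code.

# epoch_set from a trials x time matrix (single channel) or 3d array
toy_epochs <- function(x, rate_hz = 512, window_ms = c(-200, 1200),
                       condition = "Probe", channels = NULL) {
  time_ms <- epoch_time_axis(rate_hz, window_ms)
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), 1, ncol(x)))
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(x)[2]))
  stopifnot(dim(x)[3] == length(time_ms))
  epoch_set(x, time_ms, rate_hz, condition, channels)
}

# constant-valued epochs
const_epochs <- function(n_trials, value, n_time = 716, rate_hz = 512,
                         condition = "Probe") {
  toy_epochs(matrix(value, n_trials, n_time), rate_hz = rate_hz,
             window_ms = c(-200, 1200 + (n_time - 716) * 1000 / rate_hz),
             condition = condition)
}

# zero-effect, zero-noise parameter set (every sample deterministically 0);
# explicit arguments override the silent defaults
silent_params <- function(...) {
  args <- list(probe_burst_amp_uv = 0, probe_p600_amp_uv = 0,
               irrelevant_neg_amp_uv = 0, target_p3_amp_uv = 0,
               ssvep_amp_uv = 0, drift_slope_uv_per_s = 0,
               noise_psd = list(one_over_f_exponent = 1, pink_sd_uv = 0,
                                white_sd_uv = 0, alpha_amp_uv = 0),
               blink_rate_per_trial = 0)
  args[names(list(...))] <- list(...)
  do.call(sim_params, args)
}

# parameters with condition differences removed but noise kept: the null
# cohort of the calibration checks
null_effect_params <- function(...) {
  sim_params(probe_burst_amp_uv = 0, probe_p600_amp_uv = 0,
             irrelevant_neg_amp_uv = 0, ...)
}

# brute-force window scan oracle: naive loop over every start sample,
# earliest tie wins; independent of the cumsum path in the package
oracle_scan <- function(x, t_ms, rate_hz, polarity, bounds_ms, width_ms) {
  w <- round(width_ms * rate_hz / 1000)
  best <- NULL
  best_val <- if (polarity == "maximal") -Inf else Inf
  for (s in seq_len(length(x) - w + 1)) {
    if (t_ms[s] < bounds_ms[1] - 1e-6) next
    if (t_ms[s] > bounds_ms[2] - width_ms + 1e-6) next
    v <- mean(x[s:(s + w - 1)])
    better <- if (polarity == "maximal") v > best_val else v < best_val
    if (better) { best <- s; best_val <- v }
  }
  list(start = best, value = best_val)
}

# oracle for the time-frequency frame scan (maximal only)
oracle_frame_scan <- function(course, t_f, width_ms, bounds_ms) {
  step <- t_f[2] - t_f[1]
  wf <- max(1, round(width_ms / step))
  best <- NULL; best_val <- -Inf
  for (s in seq_len(length(course) - wf + 1)) {
    if (t_f[s] < bounds_ms[1] - 1e-6) next
    if (t_f[s] > bounds_ms[2] - width_ms + 1e-6) next
    v <- mean(course[s:(s + wf - 1)])
    if (v > best_val) { best <- s; best_val <- v }
  }
  best
}

# minimal hand-built tf_decomposition for unit tests of the map operations
toy_decomp <- function(coef, freqs, times_ms, baseline_ms = c(-100, 0)) {
  structure(list(coef = coef, freqs = freqs, times_ms = times_ms,
                 n_freq = length(freqs), n_time = length(times_ms),
                 rate_hz = 512, baseline_ms = baseline_ms, channel = "Pz",
                 condition = "Probe",
                 params = list(win_ms = 512, step_ms = 12, taper = "hann",
                               n_trials = nrow(coef))),
            class = "tf_decomposition")
}

toy_map <- function(values, freqs, times_ms, kind = "ERSP_dB") {
  structure(list(values = values, freqs = freqs, times_ms = times_ms,
                 kind = kind, condition = "Probe", channel = "Pz"),
            class = "tf_map")
}
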