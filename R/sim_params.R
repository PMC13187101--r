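#' Generative parameters for the synthetic RSVP-EEG cohort
#'
#' Bundles every parameter of the synthetic cohort: the deterministic
#' condition templates (Probe theta-band burst plus late positivity,
#' Irrelevant negative deflection, Target P3b), trial-level variability
#' (latency jitter, amplitude scaling), background noise (1/f, white, alpha),
#' steady-state visual evoked potential (SSVEP) at the RSVP presentation
#' rate, linear drift, blink artifacts, between-participant spread, and the
#' behavioral response model. Defaults reproduce the paradigm's standard
#' conditions: 14 participants, 75 trials per condition at 512 Hz over a
#' -200..1200 ms epoch, a 3.5 Hz Hann-windowed burst confined to
#' 280--620 ms, an Irrelevant negativity peaking at 300 ms, a Target P3b
#' peaking near +8.5 uV around 550 ms, and an SSVEP at 1000/133 Hz (one
#' stream item every 133 ms).
#'
#' @param n_participants number of participants in the cohort.
#' @param trials_per_condition trials per condition before artifact
#'   injection (>= 2).
#' @param rate_hz sampling rate, samples/s.
#' @param epoch_ms epoch start/end in ms relative to critical-stimulus onset
#'   (start < 0 < end).
#' @param channels montage labels; EEG channels first, then the two bipolar
#'   EOG channels.
#' @param channel_gain named EEG gain vector placing the effects
#'   parietally (largest at Pz).
#' @param probe_burst_freq_hz burst frequency in Hz (midpoint of the
#'   observed 3--4 Hz band).
#' @param probe_burst_window_ms burst support in ms, inside the epoch.
#' @param probe_burst_amp_uv burst peak amplitude at Pz, uV.
#' @param probe_p600_amp_uv,probe_p600_center_ms,probe_p600_sd_ms Gaussian
#'   late-positivity amplitude (uV), center and width (ms) for the Probe.
#' @param irrelevant_neg_amp_uv,irrelevant_neg_center_ms,irrelevant_neg_sd_ms
#'   magnitude (uV, applied negatively), center and width (ms) of the
#'   Irrelevant deflection.
#' @param target_p3_amp_uv,target_p3_center_ms,target_p3_sd_ms Target P3b
#'   Gaussian amplitude (uV), center and width (ms).
#' @param latency_jitter_sd_ms SD of the per-trial latency shift, ms (drives
#'   inter-trial coherence).
#' @param amp_var_cv coefficient of variation of the per-trial amplitude
#'   scale.
#' @param noise_psd list with `one_over_f_exponent` (spectral slope chi of
#'   the 1/f^chi component), `pink_sd_uv` (its SD), `white_sd_uv`, and
#'   `alpha_amp_uv` (10 Hz alpha amplitude, random phase per trial).
#' @param ssvep_freq_hz,ssvep_amp_uv stimulus-locked SSVEP frequency and
#'   amplitude.
#' @param drift_slope_uv_per_s slope of the linear drift added to every
#'   trial.
#' @param blink_rate_per_trial probability that [inject_blinks()] puts a
#'   blink in a trial, in \[0, 1\].
#' @param blink_amp_uv range (uV) of blink peak amplitude on VEOG; must
#'   exceed the 100 uV rejection threshold to be detectable.
#' @param between_subject_sd fractional SD of the per-participant amplitude
#'   factor.
#' @param behavior list of behavioral-generator knobs: per-participant hit
#'   and false-alarm rate mean/SD, and per-item-class means/SDs of the 1--5
#'   seen and prior-familiarity ratings (classes `probe_present`,
#'   `probe_absent`, `irrelevant_present`, `irrelevant_absent`). These are
#'   calibration knobs with defaults near the paradigm's typical group
#'   means, not ground truth.
#' @param seed master integer seed; all randomness derives from it via
#'   [derive_seed()].
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_participants = 14,
                       trials_per_condition = 75,
                       rate_hz = 512,
                       epoch_ms = c(-200, 1200),
                       channels = c("Pz", "Cz", "Fz", "VEOG", "HEOG"),
                       channel_gain = c(Pz = 1, Cz = 0.8, Fz = 0.7),
                       probe_burst_freq_hz = 3.5,
                       probe_burst_window_ms = c(280, 620),
                       probe_burst_amp_uv = 4.5,
                       probe_p600_amp_uv = 2.4,
                       probe_p600_center_ms = 500,
                       probe_p600_sd_ms = 80,
                       irrelevant_neg_amp_uv = 1.5,
                       irrelevant_neg_center_ms = 300,
                       irrelevant_neg_sd_ms = 60,
                       target_p3_amp_uv = 8.5,
                       target_p3_center_ms = 550,
                       target_p3_sd_ms = 100,
                       latency_jitter_sd_ms = 40,
                       amp_var_cv = 0.3,
                       noise_psd = list(one_over_f_exponent = 1,
                                        pink_sd_uv = 5,
                                        white_sd_uv = 3,
                                        alpha_amp_uv = 1.5),
                       ssvep_freq_hz = 1000 / 133,
                       ssvep_amp_uv = 1,
                       drift_slope_uv_per_s = 1,
                       blink_rate_per_trial = 0.1,
                       blink_amp_uv = c(130, 250),
                       between_subject_sd = 0.35,
                       behavior = list(
                         hit_rate_mean = 0.726, hit_rate_sd = 0.24,
                         fa_rate_mean = 0.033, fa_rate_sd = 0.027,
                         seen_mean = c(probe_present = 2.4,
                                       probe_absent = 1.1,
                                       irrelevant_present = 1.2,
                                       irrelevant_absent = 1.1),
                         seen_sd = 1.25,
                         prior_mean = c(probe_present = 4.8,
                                        probe_absent = 4.2,
                                        irrelevant_present = 1.0,
                                        irrelevant_absent = 1.0),
                         prior_sd = 0.6),
                       seed = 1L) {
  p <- structure(as.list(environment()), class = "sim_params")
  validate_sim_params(p)
}

#' Validate simulation parameters
#'
#' Checks the structural invariants of a [sim_params()] object and fails
#' with an error naming the offending field.
#'
#' @param p a `sim_params` object.
#' @return `p`, invisibly validated (returned for chaining).
#' @export
validate_sim_params <- function(p) {
  fail <- function(field, why)
    stop(sprintf("invalid sim_params: `%s` %s", field, why), call. = FALSE)
  if (!is.numeric(p$n_participants) || p$n_participants < 1)
    fail("n_participants", "must be >= 1")
  if (!is.numeric(p$trials_per_condition) || p$trials_per_condition < 2)
    fail("trials_per_condition", "must be >= 2")
  if (!is.numeric(p$rate_hz) || p$rate_hz <= 0)
    fail("rate_hz", "must be positive")
  if (length(p$epoch_ms) != 2 || !(p$epoch_ms[1] < 0 && 0 < p$epoch_ms[2]))
    fail("epoch_ms", "must satisfy start < 0 < end")
  amp_fields <- c("probe_burst_amp_uv", "probe_p600_amp_uv",
                  "irrelevant_neg_amp_uv", "target_p3_amp_uv",
                  "ssvep_amp_uv")
  for (f in amp_fields)
    if (!is.finite(p[[f]])) fail(f, "must be finite")
  if (p$probe_burst_window_ms[1] < p$epoch_ms[1] ||
      p$probe_burst_window_ms[2] > p$epoch_ms[2] ||
      p$probe_burst_window_ms[1] >= p$probe_burst_window_ms[2])
    fail("probe_burst_window_ms", "must be an interval inside the epoch")
  if (!is.finite(p$latency_jitter_sd_ms) || p$latency_jitter_sd_ms < 0)
    fail("latency_jitter_sd_ms", "must be >= 0")
  if (p$amp_var_cv < 0) fail("amp_var_cv", "must be >= 0")
  if (p$blink_rate_per_trial < 0 || p$blink_rate_per_trial > 1)
    fail("blink_rate_per_trial", "must be in [0, 1]")
  if (p$between_subject_sd < 0) fail("between_subject_sd", "must be >= 0")
  needed <- c("one_over_f_exponent", "pink_sd_uv", "white_sd_uv",
              "alpha_amp_uv")
  if (!all(needed %in% names(p$noise_psd)))
    fail("noise_psd", paste("must contain", paste(needed, collapse = ", ")))
  eog <- c("VEOG", "HEOG")
  if (!all(eog %in% p$channels))
    fail("channels", "must include VEOG and HEOG")
  eeg <- setdiff(p$channels, eog)
  if (!all(eeg %in% names(p$channel_gain)))
    fail("channel_gain", "must name every EEG channel")
  invisible(p)
}

#' EEG (non-EOG) channels of a parameter set
#' @param p a `sim_params` object.
#' @return character vector of EEG channel labels.
#' @keywords internal
eeg_channels <- function(p) setdiff(p$channels, c("VEOG", "HEOG"))

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_params> %d participants x %d trials/condition @ %g Hz, ",
    "epoch %g..%g ms\n"),
    x$n_participants, x$trials_per_condition, x$rate_hz,
    x$epoch_ms[1], x$epoch_ms[2]))
  cat(sprintf("  probe: %.3g Hz burst (%g..%g ms, %.3g uV) + P600f %.3g uV @ %g ms\n",
              x$probe_burst_freq_hz, x$probe_burst_window_ms[1],
              x$probe_burst_window_ms[2], x$probe_burst_amp_uv,
              x$probe_p600_amp_uv, x$probe_p600_center_ms))
  cat(sprintf("  irrelevant: -%.3g uV @ %g ms; target: %.3g uV @ %g ms\n",
              x$irrelevant_neg_amp_uv, x$irrelevant_neg_center_ms,
              x$target_p3_amp_uv, x$target_p3_center_ms))
  cat(sprintf("  jitter %g ms, amp CV %g, between-subject SD %g, seed %d\n",
              x$latency_jitter_sd_ms, x$amp_var_cv, x$between_subject_sd,
              x$seed))
  invisible(x)
}
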