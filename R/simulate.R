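#' Deterministic condition template at the reference (Pz) channel
#'
#' Probe: Hann-windowed sinusoidal burst confined to the burst window plus a
#' Gaussian late positivity. Irrelevant: negative Gaussian deflection.
#' Target: positive Gaussian (P3b). All in microvolts at unit per-trial and
#' per-participant scale.
#'
#' @param p a [sim_params()] object.
#' @param condition `"probe"`, `"irrelevant"` or `"target"`.
#' @param time_ms epoch time axis in ms.
#' @return numeric vector, one value per sample.
#' @export
condition_template <- function(p, condition, time_ms) {
  gauss <- function(amp, center, sd) amp * exp(-(time_ms - center)^2 / (2 * sd^2))
  switch(condition,
    probe = {
      w0 <- p$probe_burst_window_ms[1]
      w1 <- p$probe_burst_window_ms[2]
      u <- (time_ms - w0) / (w1 - w0)
      taper <- ifelse(u >= 0 & u <= 1, 0.5 - 0.5 * cos(2 * pi * u), 0)
      burst <- p$probe_burst_amp_uv * taper *
        sin(2 * pi * p$probe_burst_freq_hz * (time_ms - w0) / 1000)
      burst + gauss(p$probe_p600_amp_uv, p$probe_p600_center_ms,
                    p$probe_p600_sd_ms)
    },
    irrelevant = -gauss(p$irrelevant_neg_amp_uv, p$irrelevant_neg_center_ms,
                        p$irrelevant_neg_sd_ms),
    target = gauss(p$target_p3_amp_uv, p$target_p3_center_ms,
                   p$target_p3_sd_ms),
    stop("unknown condition: ", condition, call. = FALSE))
}

#' 1/f^chi background noise via spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain by
#' `f^(-exponent/2)` (DC removed) and rescaled to the requested SD.
#'
#' @param n number of samples.
#' @param rate_hz sampling rate.
#' @param exponent spectral slope chi.
#' @param sd_uv target standard deviation in uV; 0 returns silence.
#' @return numeric vector of length `n`.
#' @keywords internal
colored_noise <- function(n, rate_hz, exponent, sd_uv) {
  if (sd_uv <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  k <- 0:(n - 1)
  fr <- pmin(k, n - k) * rate_hz / n
  a <- ifelse(fr > 0, fr^(-exponent / 2), 0)
  y <- Re(stats::fft(stats::fft(x) * a, inverse = TRUE)) / n
  y <- y - mean(y)
  y * (sd_uv / stats::sd(y))
}

#' Shift a signal by an integer number of samples (zero padded)
#' @param x numeric vector.
#' @param k shift in samples (positive = later).
#' @return shifted vector of the same length.
#' @keywords internal
shift_signal <- function(x, k) {
  n <- length(x)
  k <- max(min(k, n), -n)
  y <- numeric(n)
  if (k >= 0) y[seq_len(n - k) + k] <- x[seq_len(n - k)]
  else y[seq_len(n + k)] <- x[seq_len(n + k) - k]
  y
}

#' Simulate one participant's epoched EEG and behavior
#'
#' Each condition's trials are the condition template with a per-trial
#' latency shift `N(0, latency_jitter_sd_ms)` (rounded to samples) and
#' amplitude scale `N(1, amp_var_cv)` (truncated at 0), scaled by a
#' per-participant amplitude factor `N(1, between_subject_sd)` and by the
#' channel gain vector, plus 1/f + white + alpha background noise, a
#' stimulus-locked SSVEP, and a linear drift. EOG channels carry white noise
#' only (blinks are added separately by [inject_blinks()]). Output is a pure
#' function of `(params$seed, participant_index)`.
#'
#' @param params a [sim_params()] object.
#' @param participant_index participant number, 1-based, `<= n_participants`.
#' @return a `participant_data` object: `epoch_set`s `probe`, `irrelevant`,
#'   `target` (EEG channels), `eog` (per-condition trials x 2 x time
#'   arrays), `behavior` (see [simulate_behavior()]), the participant index
#'   and amplitude factor.
#' @export
simulate_participant <- function(params, participant_index) {
  validate_sim_params(params)
  if (participant_index < 1 || participant_index > params$n_participants)
    stop("invalid sim_params: `participant_index` must be in 1..n_participants",
         call. = FALSE)
  p <- params
  time_ms <- epoch_time_axis(p$rate_hz, p$epoch_ms)
  n_t <- length(time_ms)
  n_tr <- p$trials_per_condition
  eeg <- eeg_channels(p)
  gain <- p$channel_gain[eeg]

  g <- with_seed(derive_seed(p$seed, participant_index, salt = 0),
                 max(0.1, stats::rnorm(1, 1, p$between_subject_sd)))
  drift <- p$drift_slope_uv_per_s * time_ms / 1000
  ssvep <- p$ssvep_amp_uv * sin(2 * pi * p$ssvep_freq_hz * time_ms / 1000)

  conditions <- c(probe = "Probe", irrelevant = "Irrelevant",
                  target = "Target")
  sets <- list()
  eog <- list()
  for (ci in seq_along(conditions)) {
    cond <- names(conditions)[ci]
    sets_eog <- with_seed(derive_seed(p$seed, participant_index, salt = ci), {
      template <- condition_template(p, cond, time_ms)
      # scale standard-normal draws so the RNG stream is identical across
      # parameter settings (rnorm with sd = 0 would consume no draws)
      shifts <- round(stats::rnorm(n_tr) * p$latency_jitter_sd_ms *
                        p$rate_hz / 1000)
      scales <- pmax(0, 1 + stats::rnorm(n_tr) * p$amp_var_cv)
      a <- array(0, dim = c(n_tr, length(eeg), n_t),
                 dimnames = list(NULL, eeg, NULL))
      e <- array(0, dim = c(n_tr, 2, n_t),
                 dimnames = list(NULL, c("VEOG", "HEOG"), NULL))
      for (tr in seq_len(n_tr)) {
        sig <- shift_signal(template, shifts[tr]) * scales[tr] * g
        for (ch in seq_along(eeg)) {
          noise <- colored_noise(n_t, p$rate_hz,
                                 p$noise_psd$one_over_f_exponent,
                                 p$noise_psd$pink_sd_uv) +
            (if (p$noise_psd$white_sd_uv > 0)
               stats::rnorm(n_t, 0, p$noise_psd$white_sd_uv) else 0)
          alpha <- if (p$noise_psd$alpha_amp_uv > 0)
            p$noise_psd$alpha_amp_uv *
              sin(2 * pi * 10 * time_ms / 1000 + stats::runif(1, 0, 2 * pi))
          else 0
          a[tr, ch, ] <- gain[ch] * (sig + ssvep) + noise + alpha + drift
        }
        for (ch in 1:2)
          e[tr, ch, ] <- if (p$noise_psd$white_sd_uv > 0)
            stats::rnorm(n_t, 0, 3.3 * p$noise_psd$white_sd_uv) else 0
      }
      list(a = a, e = e)
    })
    sets[[cond]] <- epoch_set(sets_eog$a, time_ms, p$rate_hz,
                              conditions[[ci]], eeg)
    eog[[cond]] <- sets_eog$e
  }

  behavior <- with_seed(derive_seed(p$seed, participant_index, salt = 8),
                        simulate_behavior(p))
  structure(
    list(probe = sets$probe, irrelevant = sets$irrelevant,
         target = sets$target, eog = eog, behavior = behavior,
         participant = participant_index, amp_factor = g),
    class = "participant_data")
}

#' @export
print.participant_data <- function(x, ...) {
  cat(sprintf(
    "<participant_data> participant %d (amplitude factor %.2f)\n",
    x$participant, x$amp_factor))
  for (cond in c("probe", "irrelevant", "target"))
    cat(sprintf("  %s: %d trials\n", cond, n_trials(x[[cond]])))
  invisible(x)
}

#' Simulate the behavioral record of one participant
#'
#' Target yes/no responses for 3 x `trials_per_condition` streams (one third
#' of which contain the Target), from a per-participant hit and false-alarm
#' rate drawn around the configured group means; and the end-of-experiment
#' recognition test of 12 items (3 per class), each with a 1--5 "how often
#' seen" rating and a 1--5 prior-familiarity rating, drawn from discretised
#' Gaussians around the configured class means. Called under the
#' participant's derived seed by [simulate_participant()].
#'
#' @param p a [sim_params()] object.
#' @return list with `trials` (data.frame: trial, target_present,
#'   response_yes), `ratings` (data.frame: item, class, seen_rating,
#'   prior_rating), `hit_rate`, `fa_rate`.
#' @export
simulate_behavior <- function(p) {
  b <- p$behavior
  n_streams <- 3 * p$trials_per_condition
  n_target <- p$trials_per_condition
  present <- sample(rep(c(TRUE, FALSE), c(n_target, n_streams - n_target)))
  hit_rate <- min(0.99, max(0.02, stats::rnorm(1, b$hit_rate_mean,
                                               b$hit_rate_sd)))
  fa_rate <- min(0.5, max(0.001, stats::rnorm(1, b$fa_rate_mean,
                                              b$fa_rate_sd)))
  response <- ifelse(present, stats::runif(n_streams) < hit_rate,
                     stats::runif(n_streams) < fa_rate)
  classes <- c("probe_present", "probe_absent", "irrelevant_present",
               "irrelevant_absent")
  cls <- rep(classes, each = 3)
  clamp_rating <- function(x) pmin(5, pmax(1, round(x)))
  seen <- clamp_rating(stats::rnorm(12, b$seen_mean[cls], b$seen_sd))
  prior <- clamp_rating(stats::rnorm(12, b$prior_mean[cls], b$prior_sd))
  list(trials = data.frame(trial = seq_len(n_streams),
                           target_present = present,
                           response_yes = response),
       ratings = data.frame(item = 1:12, class = cls,
                            seen_rating = seen, prior_rating = prior),
       hit_rate = hit_rate, fa_rate = fa_rate)
}

#' Simulate a cohort of participants
#'
#' Participants are mutually independent given the master seed (each has its
#' own derived stream) and the output is bit-for-bit reproducible for a
#' fixed seed.
#'
#' @param params a [sim_params()] object.
#' @return list of `participant_data`, length `n_participants`.
#' @export
simulate_cohort <- function(params) {
  validate_sim_params(params)
  lapply(seq_len(params$n_participants),
         function(i) simulate_participant(params, i))
}

#' Inject blink artifacts into a participant's trials
#'
#' Selected trials (probability `blink_rate_per_trial` each) receive a
#' Gaussian-shaped VEOG transient whose peak exceeds the 100 uV rejection
#' threshold, with a scaled frontal projection onto the EEG channels
#' (Fz 12%, Cz 5%, Pz 2% of the blink). The flagged trial indices are
#' returned in `$blink_trials` so the round trip through
#' [reject_artifacts()] can be checked.
#'
#' @param data a `participant_data` object.
#' @param params the [sim_params()] used to generate it.
#' @return `data` with blinks added and a `blink_trials` list (per
#'   condition, integer indices of blink trials).
#' @export
inject_blinks <- function(data, params) {
  validate_sim_params(params)
  rate <- params$blink_rate_per_trial
  time_ms <- data$probe$time_ms
  proj <- c(Fz = 0.12, Cz = 0.05, Pz = 0.02)
  out <- data
  out$blink_trials <- list()
  for (ci in seq_along(c("probe", "irrelevant", "target"))) {
    cond <- c("probe", "irrelevant", "target")[ci]
    es <- data[[cond]]
    n_tr <- n_trials(es)
    res <- with_seed(derive_seed(params$seed, data$participant,
                                 salt = 9000 + ci), {
      flagged <- which(stats::runif(n_tr) < rate)
      a <- es$data
      e <- data$eog[[cond]]
      for (tr in flagged) {
        amp <- stats::runif(1, params$blink_amp_uv[1], params$blink_amp_uv[2])
        center <- stats::runif(1, min(time_ms) + 100, max(time_ms) - 100)
        blink <- amp * exp(-(time_ms - center)^2 / (2 * 50^2))
        e[tr, "VEOG", ] <- e[tr, "VEOG", ] + blink
        for (ch in intersect(names(proj), es$channels))
          a[tr, ch, ] <- a[tr, ch, ] + proj[[ch]] * blink
      }
      list(a = a, e = e, flagged = flagged)
    })
    out[[cond]] <- epoch_set(res$a, es$time_ms, es$rate_hz, es$condition,
                             es$channels, es$trial_ids)
    out$eog[[cond]] <- res$e
    out$blink_trials[[cond]] <- res$flagged
  }
  out
}
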