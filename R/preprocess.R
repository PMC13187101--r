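#' Continuous multichannel recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate_hz sampling rate in Hz.
#' @param channels channel labels (defaults to rownames).
#' @param events data.frame with columns `sample` (1-based sample index of
#'   stimulus onset) and `condition` (label); may be empty.
#' @param eog_channels labels treated as EOG (excluded from re-referencing).
#' @param processing character log of applied processing steps.
#' @return an object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, rate_hz, channels = rownames(data),
                                 events = data.frame(sample = integer(),
                                                     condition = character()),
                                 eog_channels = c("VEOG", "HEOG"),
                                 processing = character()) {
  if (!is.matrix(data))
    stop("`data` must be a channels x samples matrix", call. = FALSE)
  if (!is.numeric(rate_hz) || rate_hz <= 0)
    stop("`rate_hz` must be positive", call. = FALSE)
  if (is.null(channels))
    channels <- paste0("ch", seq_len(nrow(data)))
  if (length(channels) != nrow(data))
    stop("`channels` length must match rows of `data`", call. = FALSE)
  if (nrow(events) &&
      (any(events$sample < 1) || any(events$sample > ncol(data))))
    stop("event samples out of bounds", call. = FALSE)
  rownames(data) <- channels
  structure(list(data = data, rate_hz = rate_hz, channels = channels,
                 events = events, eog_channels = eog_channels,
                 processing = processing),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$rate_hz, nrow(x$events)))
  if (length(x$processing))
    cat("  processing:", paste(x$processing, collapse = " | "), "\n")
  invisible(x)
}

filtfilt_channels <- function(rec, filt, label) {
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- signal::filtfilt(filt, rec$data[ch, ])
  out$processing <- c(rec$processing, label)
  out
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, realised as an
#' order-2 high-pass at `low_hz` cascaded with an order-4 low-pass at
#' `high_hz`, each applied with `signal::filtfilt` so component latencies
#' are not shifted. Passband gain is within 1 dB at mid-band.
#'
#' @param rec a `continuous_recording`.
#' @param low_hz high-pass cutoff (default 0.5 Hz).
#' @param high_hz low-pass cutoff (default 45 Hz).
#' @return the filtered recording, with the step appended to its processing
#'   log.
#' @export
bandpass_filter <- function(rec, low_hz = 0.5, high_hz = 45) {
  stopifnot(inherits(rec, "continuous_recording"))
  nyq <- rec$rate_hz / 2
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq))
    stop("band-pass cutoffs must satisfy 0 < low < high < rate/2",
         call. = FALSE)
  hp <- signal::butter(2, low_hz / nyq, "high")
  lp <- signal::butter(4, high_hz / nyq, "low")
  out <- filtfilt_channels(rec, hp, sprintf("highpass butter2 %.3g Hz (zero-phase)", low_hz))
  filtfilt_channels(out, lp, sprintf("lowpass butter4 %.3g Hz (zero-phase)", high_hz))
}

#' Zero-phase notch (band-stop) filter
#'
#' Order-2 Butterworth band-stop applied forward-backward; with the default
#' 7--9 Hz band it removes the ~7.5 Hz SSVEP set up by the RSVP stream
#' (8 Hz attenuated by more than 20 dB) while leaving 3 Hz and 12 Hz
#' essentially untouched (< 3 dB).
#'
#' @param rec a `continuous_recording`.
#' @param low_hz,high_hz stop-band edges (defaults 7 and 9 Hz).
#' @return the filtered recording.
#' @export
notch_filter <- function(rec, low_hz = 7, high_hz = 9) {
  stopifnot(inherits(rec, "continuous_recording"))
  nyq <- rec$rate_hz / 2
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq))
    stop("notch band must lie inside (0, rate/2)", call. = FALSE)
  bs <- signal::butter(2, c(low_hz, high_hz) / nyq, "stop")
  filtfilt_channels(rec, bs,
                    sprintf("notch butter2 %.3g-%.3g Hz (zero-phase)",
                            low_hz, high_hz))
}

#' Zero-phase notch filtering of epoched trials
#'
#' Applies the order-2 Butterworth band-stop of [notch_filter()]
#' forward-backward to every trial and channel of an epoch set. This is the
#' SSVEP-removal stage for data that enters the pipeline already epoched
#' (synthetic cohorts): the steady-state response at the RSVP presentation
#' rate is phase-locked across trials and would otherwise dominate
#' inter-trial coherence near the top of the analysis band.
#'
#' @param epochs an `epoch_set`.
#' @param low_hz,high_hz stop-band edges (defaults 7 and 9 Hz).
#' @return the filtered `epoch_set`.
#' @export
notch_filter_epochs <- function(epochs, low_hz = 7, high_hz = 9) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$rate_hz / 2
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq))
    stop("notch band must lie inside (0, rate/2)", call. = FALSE)
  bs <- signal::butter(2, c(low_hz, high_hz) / nyq, "stop")
  out <- epochs$data
  n <- dim(out)[3]
  # a narrow notch rings for longer than the epoch's own edges allow;
  # reflect the whole trial on both sides before zero-phase filtering
  pad <- n - 1
  for (tr in seq_len(dim(out)[1]))
    for (ch in seq_len(dim(out)[2])) {
      x <- out[tr, ch, ]
      xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
      y <- signal::filtfilt(bs, xp)
      out[tr, ch, ] <- y[(pad + 1):(pad + n)]
    }
  epoch_set(out, epochs$time_ms, epochs$rate_hz, epochs$condition,
            epochs$channels, epochs$trial_ids)
}

#' Fourier-domain resampling of a single channel
#' @keywords internal
resample_fft <- function(x, n_new) {
  n <- length(x)
  if (n_new == n) return(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(n_new), imaginary = numeric(n_new))
  half <- floor(n_new / 2)
  n_keep_low <- floor((n_new - 1) / 2) + 1  # DC .. positive freqs
  Y[seq_len(n_keep_low)] <- X[seq_len(n_keep_low)]
  if (half >= 1) {
    neg <- seq_len(half)
    Y[n_new - neg + 1] <- X[n - neg + 1]
    if (n_new %% 2 == 0)  # fold the split Nyquist bin to keep the signal real
      Y[half + 1] <- X[half + 1] + X[n - half + 1]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample a recording to a lower rate
#'
#' Fourier-domain resampling (spectrum truncation), which is inherently
#' anti-aliased and preserves the recording duration to within one sample.
#' Only downsampling is supported. Event sample indices are remapped to the
#' new grid.
#'
#' @param rec a `continuous_recording`.
#' @param target_hz target rate (default 512), `<=` the current rate.
#' @return the resampled recording.
#' @export
resample_recording <- function(rec, target_hz = 512) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (target_hz > rec$rate_hz)
    stop("upsampling is not supported (target_hz > rate_hz)", call. = FALSE)
  if (target_hz == rec$rate_hz) return(rec)
  n <- ncol(rec$data)
  n_new <- round(n * target_hz / rec$rate_hz)
  out <- rec
  out$data <- t(apply(rec$data, 1, resample_fft, n_new = n_new))
  rownames(out$data) <- rec$channels
  out$rate_hz <- target_hz
  if (nrow(out$events))
    out$events$sample <- pmax(1, pmin(n_new, round(
      (rec$events$sample - 1) * target_hz / rec$rate_hz) + 1))
  out$processing <- c(rec$processing,
                      sprintf("resample %g -> %g Hz (Fourier)", rec$rate_hz,
                              target_hz))
  out
}

#' Re-reference EEG channels to the average of the mastoids
#'
#' Subtracts the per-sample mean of the two mastoid channels from every EEG
#' channel; EOG channels (bipolar derivations) are left untouched.
#'
#' @param rec a `continuous_recording` containing both reference channels.
#' @param ref_labels the mastoid channel labels (default `A1`, `A2`).
#' @return the re-referenced recording.
#' @export
rereference_mastoids <- function(rec, ref_labels = c("A1", "A2")) {
  stopifnot(inherits(rec, "continuous_recording"))
  missing_ref <- setdiff(ref_labels, rec$channels)
  if (length(missing_ref))
    stop("reference channel(s) not found: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  ref <- colMeans(rec$data[ref_labels, , drop = FALSE])
  out <- rec
  eeg <- setdiff(rec$channels, rec$eog_channels)
  for (ch in eeg) out$data[ch, ] <- rec$data[ch, ] - ref
  out$processing <- c(rec$processing,
                      sprintf("rereference to mean(%s)",
                              paste(ref_labels, collapse = ",")))
  out
}

#' Epoch a continuous recording around its events
#'
#' Cuts one trial per event, time-locked to the event sample (time 0), with
#' the half-open sample convention `[start, end)` of [epoch_time_axis()].
#' Events too close to the recording edge are dropped with a warning. EOG
#' channels are split out into per-condition trials x 2 x time arrays.
#'
#' @param rec a `continuous_recording` with events.
#' @param window_ms epoch window in ms (default `c(-200, 1200)`).
#' @return named list, one entry per condition present in the events:
#'   `list(epochs = <epoch_set of the EEG channels>, eog = <array>)`.
#'   Conditions with no surviving events yield an `epochs` entry with zero
#'   trials.
#' @export
epoch_recording <- function(rec, window_ms = c(-200, 1200)) {
  stopifnot(inherits(rec, "continuous_recording"))
  n_pre <- round(-window_ms[1] * rec$rate_hz / 1000)
  n_post <- round(window_ms[2] * rec$rate_hz / 1000)
  time_ms <- epoch_time_axis(rec$rate_hz, window_ms)
  n_len <- n_pre + n_post
  n <- ncol(rec$data)
  eeg <- setdiff(rec$channels, rec$eog_channels)
  eogc <- intersect(rec$eog_channels, rec$channels)
  out <- list()
  for (cond in unique(rec$events$condition)) {
    ev <- rec$events$sample[rec$events$condition == cond]
    ok <- ev - n_pre >= 1 & ev + n_post - 1 <= n
    if (any(!ok))
      warning(sprintf("%d %s event(s) too close to the recording edge; dropped",
                      sum(!ok), cond), call. = FALSE)
    ev <- ev[ok]
    a <- array(0, dim = c(length(ev), length(eeg), n_len),
               dimnames = list(NULL, eeg, NULL))
    e <- array(0, dim = c(length(ev), length(eogc), n_len),
               dimnames = list(NULL, eogc, NULL))
    for (i in seq_along(ev)) {
      idx <- (ev[i] - n_pre):(ev[i] + n_post - 1)
      a[i, , ] <- rec$data[eeg, idx, drop = FALSE]
      if (length(eogc)) e[i, , ] <- rec$data[eogc, idx, drop = FALSE]
    }
    out[[cond]] <- list(
      epochs = epoch_set(a, time_ms, rec$rate_hz, cond, eeg),
      eog = e)
  }
  out
}

#' Reject trials with out-of-range EOG or EEG activity
#'
#' A trial is rejected if any EOG sample exceeds `eog_limit_uv` in magnitude
#' (blinks, eye movements) or any EEG sample exceeds `eeg_limit_uv`
#' (other physiological/environmental artifacts), anywhere in the epoch.
#' Thresholds apply to the signal as supplied at this stage (post-filtering,
#' pre-detrend). Applying the function twice rejects nothing new.
#'
#' @param epochs an `epoch_set` of EEG channels.
#' @param eog trials x n_eog x time array aligned with `epochs` (may have
#'   zero EOG channels).
#' @param eog_limit_uv EOG magnitude threshold (default 100 uV).
#' @param eeg_limit_uv EEG magnitude threshold (default 50 uV).
#' @return list with `epochs` (kept trials) and `report`, a
#'   `rejection_report`: data.frame of per-trial `trial_id`, `keep`,
#'   `reason` (`""`, `"EOG_exceed"` or `"EEG_exceed"`; EOG takes
#'   precedence), plus kept/rejected counts.
#' @export
reject_artifacts <- function(epochs, eog, eog_limit_uv = 100,
                             eeg_limit_uv = 50) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_tr <- n_trials(epochs)
  if (!is.array(eog) || length(dim(eog)) != 3L || dim(eog)[1] != n_tr)
    stop("`eog` must be a trials x channels x time array aligned with `epochs`",
         call. = FALSE)
  eog_bad <- if (dim(eog)[2] > 0)
    apply(abs(eog), 1, max) > eog_limit_uv else rep(FALSE, n_tr)
  eeg_bad <- apply(abs(epochs$data), 1, max) > eeg_limit_uv
  reason <- ifelse(eog_bad, "EOG_exceed", ifelse(eeg_bad, "EEG_exceed", ""))
  keep <- reason == ""
  report <- structure(
    list(flags = data.frame(trial_id = epochs$trial_ids, keep = keep,
                            reason = reason),
         condition = epochs$condition,
         n_total = n_tr, n_kept = sum(keep), n_rejected = sum(!keep),
         eog_limit_uv = eog_limit_uv, eeg_limit_uv = eeg_limit_uv),
    class = "rejection_report")
  list(epochs = subset_trials(epochs, which(keep)),
       eog = eog[keep, , , drop = FALSE],
       report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> %s: kept %d / %d (%d rejected; EOG > %g uV or EEG > %g uV)\n",
              x$condition, x$n_kept, x$n_total, x$n_rejected,
              x$eog_limit_uv, x$eeg_limit_uv))
  tab <- table(x$flags$reason[!x$flags$keep])
  if (length(tab))
    cat("  reasons:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Detrend the Probe/Irrelevant pair against their combined average
#'
#' Drift mitigation for extreme-window selection: per channel, an ordinary
#' least-squares line is fitted to the combined (trial-weighted)
#' Probe+Irrelevant average over the full epoch, and that same line is
#' subtracted from every trial of both conditions. Fitting a line to the
#' detrended combined average returns slope ~ 0 by construction.
#'
#' @param probe,irrelevant `epoch_set`s sharing channels and time axis.
#' @return a `detrend_result`: detrended `probe` and `irrelevant`, and
#'   `fit`, a data.frame of per-channel intercept (uV) and slope (uV/ms).
#' @export
detrend_pair <- function(probe, irrelevant) {
  stopifnot(inherits(probe, "epoch_set"), inherits(irrelevant, "epoch_set"))
  if (!identical(probe$channels, irrelevant$channels) ||
      !isTRUE(all.equal(probe$time_ms, irrelevant$time_ms)))
    stop("probe and irrelevant must share channels and time axis",
         call. = FALSE)
  if (n_trials(probe) == 0 || n_trials(irrelevant) == 0)
    stop("insufficient data: both conditions must contain trials",
         call. = FALSE)
  t_ms <- probe$time_ms
  combined <- aggregate_erp(probe, irrelevant)
  fit <- data.frame(channel = probe$channels, intercept_uv = NA_real_,
                    slope_uv_per_ms = NA_real_)
  out_p <- probe$data
  out_i <- irrelevant$data
  for (ch in seq_along(probe$channels)) {
    cf <- stats::coef(stats::lm(combined$data[ch, ] ~ t_ms))
    fit$intercept_uv[ch] <- cf[1]
    fit$slope_uv_per_ms[ch] <- cf[2]
    line <- cf[1] + cf[2] * t_ms
    out_p[, ch, ] <- sweep(out_p[, ch, , drop = FALSE], 3, line)[, 1, ]
    out_i[, ch, ] <- sweep(out_i[, ch, , drop = FALSE], 3, line)[, 1, ]
  }
  structure(
    list(probe = epoch_set(out_p, t_ms, probe$rate_hz, probe$condition,
                           probe$channels, probe$trial_ids),
         irrelevant = epoch_set(out_i, t_ms, irrelevant$rate_hz,
                                irrelevant$condition, irrelevant$channels,
                                irrelevant$trial_ids),
         fit = fit),
    class = "detrend_result")
}

#' Baseline-correct every trial
#'
#' Per trial and channel, subtracts the mean over the baseline window
#' (default -100..0 ms, half-open). In the standard chain this runs strictly
#' after [detrend_pair()]: baselining first would tilt the data that the
#' detrend line is fitted to.
#'
#' @param epochs an `epoch_set`.
#' @param window_ms baseline window, inside the epoch.
#' @return the baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window_ms = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- time_index(epochs$time_ms, window_ms[1], window_ms[2])
  if (!length(idx) || window_ms[1] < min(epochs$time_ms) - 1e-6)
    stop("baseline window must lie inside the epoch", call. = FALSE)
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  out <- epochs$data - array(base, dim = dim(epochs$data))
  epoch_set(out, epochs$time_ms, epochs$rate_hz, epochs$condition,
            epochs$channels, epochs$trial_ids)
}
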