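#' Aggregated ERP of all trials from both conditions (aERPt)
#'
#' The contrast-orthogonal average used for per-participant window
#' placement: a simple mean over the union of all Probe and Irrelevant
#' trials. The mean is trial-weighted (a condition with more trials
#' contributes proportionally more), not an average of condition averages.
#'
#' @param probe,irrelevant `epoch_set`s sharing channels and time axis.
#' @return an `erp_waveform`: per-channel average (channels x time matrix),
#'   time axis, rate and pooled trial count.
#' @export
aggregate_erp <- function(probe, irrelevant) {
  stopifnot(inherits(probe, "epoch_set"), inherits(irrelevant, "epoch_set"))
  if (!identical(probe$channels, irrelevant$channels) ||
      !isTRUE(all.equal(probe$time_ms, irrelevant$time_ms)))
    stop("conditions must share channels and time axis", call. = FALSE)
  n <- n_trials(probe) + n_trials(irrelevant)
  if (n == 0)
    stop("insufficient data: no trials to aggregate", call. = FALSE)
  s <- apply(probe$data, c(2, 3), sum) + apply(irrelevant$data, c(2, 3), sum)
  structure(list(data = s / n, time_ms = probe$time_ms,
                 rate_hz = probe$rate_hz, channels = probe$channels,
                 n_trials = n),
            class = "erp_waveform")
}

#' Condition ERP (average of one epoch set)
#' @param epochs an `epoch_set` with at least one trial.
#' @return an `erp_waveform`.
#' @export
condition_erp <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_trials(epochs) == 0)
    stop("insufficient data: empty epoch set", call. = FALSE)
  structure(list(data = apply(epochs$data, c(2, 3), mean),
                 time_ms = epochs$time_ms, rate_hz = epochs$rate_hz,
                 channels = epochs$channels, n_trials = n_trials(epochs)),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> %d channels x %d samples (%d trials pooled)\n",
              nrow(x$data), ncol(x$data), x$n_trials))
  invisible(x)
}

#' Aggregated grand average of trials across a cohort (AGAT)
#'
#' Group-level analogue of [aggregate_erp()]: the mean over all trials of
#' all participants and both conditions, trial-weighted, used for
#' group-level contrast-orthogonal window placement.
#'
#' @param cohort list of `participant_data` (or of lists with `probe` and
#'   `irrelevant` epoch sets) sharing axes.
#' @return an `erp_waveform`.
#' @export
aggregate_grand_average <- function(cohort) {
  stopifnot(length(cohort) >= 1)
  ref <- cohort[[1]]$probe
  total <- 0
  n <- 0
  for (pd in cohort) {
    for (cond in c("probe", "irrelevant")) {
      es <- pd[[cond]]
      if (!identical(es$channels, ref$channels) ||
          !isTRUE(all.equal(es$time_ms, ref$time_ms)))
        stop("cohort epoch sets must share channels and time axis",
             call. = FALSE)
      total <- total + apply(es$data, c(2, 3), sum)
      n <- n + n_trials(es)
    }
  }
  structure(list(data = total / n, time_ms = ref$time_ms,
                 rate_hz = ref$rate_hz, channels = ref$channels,
                 n_trials = n),
            class = "erp_waveform")
}

#' Analysis window (region of interest)
#'
#' A fixed-width window found on aggregated data, independent of the tested
#' contrast.
#'
#' @param start_ms,end_ms window bounds in ms (`end - start` = width, to
#'   sample resolution).
#' @param source placement method, e.g. `"aERPt"` or `"AGAT"`.
#' @param channel channel the window was placed on.
#' @param n_samples number of samples the window spans.
#' @return an object of class `roi_window`.
#' @export
roi_window <- function(start_ms, end_ms, source = "aERPt", channel = NA,
                       n_samples = NA) {
  structure(list(start_ms = start_ms, end_ms = end_ms, source = source,
                 channel = channel, n_samples = n_samples),
            class = "roi_window")
}

#' @export
print.roi_window <- function(x, ...) {
  cat(sprintf("<roi_window> %.1f..%.1f ms (%s%s)\n", x$start_ms, x$end_ms,
              x$source,
              if (is.na(x$channel)) "" else paste0(", ", x$channel)))
  invisible(x)
}

#' Find the extreme fixed-width window of an aggregated waveform
#'
#' Exhaustive scan over every start sample within the search bounds for the
#' 100 ms (by default) interval whose mean is maximal (late positivity,
#' P600f) or minimal (face negativity, N400f). Ties are broken by the
#' earliest start. Because the waveform is an aggregate over both
#' conditions, the placement is orthogonal to the Probe-vs-Irrelevant
#' contrast.
#'
#' @param waveform an `erp_waveform`.
#' @param channel channel label to scan.
#' @param polarity `"maximal"` or `"minimal"`.
#' @param bounds_ms search bounds (default 0--1200 ms; a narrower a-priori
#'   late-positivity band such as `c(300, 900)` may be supplied).
#' @param width_ms window width (default 100 ms).
#' @param source label recorded on the returned window.
#' @return a [roi_window()].
#' @export
find_extreme_window <- function(waveform, channel,
                                polarity = c("maximal", "minimal"),
                                bounds_ms = c(0, 1200), width_ms = 100,
                                source = "aERPt") {
  stopifnot(inherits(waveform, "erp_waveform"))
  polarity <- match.arg(polarity)
  if (!channel %in% waveform$channels)
    stop("channel not found: ", channel, call. = FALSE)
  t_ms <- waveform$time_ms
  w <- round(width_ms * waveform$rate_hz / 1000)
  if (bounds_ms[2] - bounds_ms[1] < width_ms)
    stop("search bounds span less than the window width", call. = FALSE)
  x <- waveform$data[match(channel, waveform$channels), ]
  starts <- which(t_ms >= bounds_ms[1] - 1e-6 &
                  t_ms <= bounds_ms[2] - width_ms + 1e-6)
  starts <- starts[starts + w - 1 <= length(x)]
  if (!length(starts))
    stop("no candidate window start inside the search bounds", call. = FALSE)
  cs <- cumsum(c(0, x))
  means <- (cs[starts + w] - cs[starts]) / w
  best <- if (polarity == "maximal") which.max(means) else which.min(means)
  s <- starts[best]
  roi_window(start_ms = t_ms[s], end_ms = t_ms[s] + width_ms,
             source = source, channel = channel, n_samples = w)
}

#' Sample indices of a window inside an epoch time axis
#' @keywords internal
window_index <- function(time_ms, window, rate_hz) {
  w <- if (!is.na(window$n_samples)) window$n_samples
  else round((window$end_ms - window$start_ms) * rate_hz / 1000)
  s <- which.min(abs(time_ms - window$start_ms))
  if (abs(time_ms[s] - window$start_ms) > 1000 / rate_hz)
    stop("window does not lie on this epoch's time axis", call. = FALSE)
  if (s + w - 1 > length(time_ms))
    stop("window extends beyond the epoch", call. = FALSE)
  s:(s + w - 1)
}

#' Mean amplitude of a condition in a window
#'
#' Mean over trials of the per-trial mean over the window samples, which
#' equals the windowed mean of the condition ERP.
#'
#' @param epochs an `epoch_set`.
#' @param window a [roi_window()].
#' @param channel channel label.
#' @return mean amplitude in uV.
#' @export
mean_amplitude <- function(epochs, window, channel) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_trials(epochs) == 0)
    stop("insufficient data: empty epoch set", call. = FALSE)
  if (!channel %in% epochs$channels)
    stop("channel not found: ", channel, call. = FALSE)
  idx <- window_index(epochs$time_ms, window, epochs$rate_hz)
  mean(epochs$data[, match(channel, epochs$channels), idx])
}

#' Per-trial windowed means (the unit the randomisation test permutes)
#' @keywords internal
trial_window_means <- function(epochs, window, channel) {
  idx <- window_index(epochs$time_ms, window, epochs$rate_hz)
  rowMeans(epochs$data[, match(channel, epochs$channels), idx, drop = FALSE],
           dims = 1)
}

#' True observed Probe-minus-Irrelevant difference
#'
#' @param probe,irrelevant `epoch_set`s.
#' @param window a shared [roi_window()].
#' @param channel channel label.
#' @return `mean_amplitude(probe) - mean_amplitude(irrelevant)` in uV.
#' @export
observed_difference <- function(probe, irrelevant, window, channel) {
  mean_amplitude(probe, window, channel) -
    mean_amplitude(irrelevant, window, channel)
}

#' Monte-Carlo randomisation test of the windowed mean-amplitude difference
#'
#' Trial-matrix permutation test for a single participant. With
#' `m = min(n_probe, n_irrelevant)`, m trials are drawn from each condition
#' without replacement, their per-trial windowed means are stacked into a
#' 2m-row matrix, and on each of `n_iter` iterations the rows are permuted
#' and split into surrogate halves whose mean difference is recorded. Both
#' components' surrogate differences are computed from the same permutation.
#' The p-value is directional per component polarity: for a maximal
#' component (P600f) the proportion of surrogates `>=` the observed
#' difference, for a minimal component (N400f) the proportion `<=`; ties
#' count as exceeding (conservative). Optional add-one smoothing
#' `(b + 1) / (n_iter + 1)` is available but off by default.
#'
#' @param probe,irrelevant `epoch_set`s with at least 2 trials each.
#' @param windows named list of [roi_window()]s, e.g.
#'   `list(P600f = ..., N400f = ...)`.
#' @param channel channel label.
#' @param n_iter number of permutations (default 1000).
#' @param seed integer seed for trial selection and permutation.
#' @param polarities named vector giving each component's polarity;
#'   defaults map `P600f` to maximal and `N400f` to minimal.
#' @param smoothing use add-one smoothing for p (default `FALSE`).
#' @return named list of `permutation_result` objects (one per window):
#'   observed difference, surrogate vector, `p`, `n_iter`, matched count
#'   `m`, seed and polarity.
#' @export
randomisation_test <- function(probe, irrelevant, windows, channel,
                               n_iter = 1000, seed = 1,
                               polarities = c(P600f = "maximal",
                                              N400f = "minimal"),
                               smoothing = FALSE) {
  stopifnot(inherits(probe, "epoch_set"), inherits(irrelevant, "epoch_set"))
  m <- min(n_trials(probe), n_trials(irrelevant))
  if (m < 2)
    stop("insufficient data: need at least 2 trials per condition",
         call. = FALSE)
  comp <- names(windows)
  if (is.null(comp)) stop("`windows` must be a named list", call. = FALSE)
  pol <- vapply(comp, function(k) {
    if (!is.na(polarities[k])) polarities[[k]] else "maximal"
  }, "")
  amp_p <- vapply(windows, function(w) trial_window_means(probe, w, channel),
                  numeric(n_trials(probe)))
  amp_i <- vapply(windows,
                  function(w) trial_window_means(irrelevant, w, channel),
                  numeric(n_trials(irrelevant)))
  amp_p <- matrix(amp_p, nrow = n_trials(probe))
  amp_i <- matrix(amp_i, nrow = n_trials(irrelevant))
  with_seed(seed, {
    sel_p <- sample.int(nrow(amp_p), m)
    sel_i <- sample.int(nrow(amp_i), m)
    v <- rbind(amp_p[sel_p, , drop = FALSE], amp_i[sel_i, , drop = FALSE])
    observed <- colMeans(v[seq_len(m), , drop = FALSE]) -
      colMeans(v[m + seq_len(m), , drop = FALSE])
    surrogates <- matrix(NA_real_, n_iter, length(comp))
    tot <- colSums(v)
    for (it in seq_len(n_iter)) {
      half <- colSums(v[sample.int(2 * m, m), , drop = FALSE])
      surrogates[it, ] <- (half - (tot - half)) / m
    }
    out <- lapply(seq_along(comp), function(k) {
      b <- if (pol[k] == "maximal") sum(surrogates[, k] >= observed[k])
      else sum(surrogates[, k] <= observed[k])
      p <- if (smoothing) (b + 1) / (n_iter + 1) else b / n_iter
      structure(list(observed = observed[k], surrogates = surrogates[, k],
                     p = p, n_iter = n_iter, m = m, seed = seed,
                     component = comp[k], polarity = pol[k],
                     channel = channel),
                class = "permutation_result")
    })
    names(out) <- comp
    out
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s (%s): observed %.4g, p = %.4g (m = %d, %d iterations)\n",
              x$component, x$polarity, x$observed, x$p, x$m, x$n_iter))
  invisible(x)
}

#' Paired t-test across participants with pooled-condition-SD effect size
#'
#' Group-level inference on per-participant condition means: differences
#' `d_i = probe_i - irrelevant_i`, `t = mean(d) / (sd(d) / sqrt(n))` with
#' sample SD, two-tailed p on `n - 1` degrees of freedom (via
#' [stats::t.test()]), and Cohen's d in the pooled-condition-SD form
#' `mean(d) / sqrt((sd_probe^2 + sd_irrelevant^2) / 2)`.
#'
#' @param probe_values,irrelevant_values equal-length numeric vectors,
#'   paired by participant (n >= 2).
#' @return a `group_test_result`: differences, `mean_diff`, `sd_diff`, `t`,
#'   `df`, `p`, `d`, and per-condition means/SDs.
#' @export
group_paired_ttest <- function(probe_values, irrelevant_values) {
  if (length(probe_values) != length(irrelevant_values))
    stop("pairing error: condition vectors differ in length", call. = FALSE)
  n <- length(probe_values)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  d_i <- probe_values - irrelevant_values
  sd_diff <- stats::sd(d_i)
  if (sd_diff == 0)
    stop("degenerate variance: all paired differences are equal",
         call. = FALSE)
  tt <- stats::t.test(probe_values, irrelevant_values, paired = TRUE)
  structure(
    list(differences = d_i, mean_diff = mean(d_i), sd_diff = sd_diff,
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value,
         d = cohens_d_pooled(mean(d_i), stats::sd(probe_values),
                             stats::sd(irrelevant_values)),
         mean_probe = mean(probe_values), sd_probe = stats::sd(probe_values),
         mean_irrelevant = mean(irrelevant_values),
         sd_irrelevant = stats::sd(irrelevant_values), n = n),
    class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<group_test_result> M = %.4f, SD = %.4f, t(%d) = %.4f, p = %.4f, d = %.4f\n",
              x$mean_diff, x$sd_diff, x$df, x$t, x$p, x$d))
  invisible(x)
}

#' Paired t statistic from printed summary values
#'
#' Maps a published (mean difference, SD of differences, n) triple to the
#' paired t statistic, its degrees of freedom and two-tailed p, so printed
#' group rows can be recomputed without raw data.
#'
#' @param mean_diff mean paired difference.
#' @param sd_diff sample SD of the differences (> 0).
#' @param n number of pairs (>= 2).
#' @return list with `t`, `df`, `p`.
#' @export
paired_t_from_summary <- function(mean_diff, sd_diff, n) {
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (sd_diff <= 0)
    stop("degenerate variance: sd_diff must be > 0", call. = FALSE)
  t <- mean_diff / (sd_diff / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

#' Cohen's d with the pooled-condition-SD denominator
#'
#' `d = mean_diff / sqrt((sd_probe^2 + sd_irrelevant^2) / 2)`: the mean
#' paired difference standardised by the root mean square of the two
#' condition SDs.
#'
#' @param mean_diff mean paired difference.
#' @param sd_probe,sd_irrelevant condition standard deviations (>= 0, not
#'   both 0).
#' @return the effect size d.
#' @export
cohens_d_pooled <- function(mean_diff, sd_probe, sd_irrelevant) {
  if (sd_probe < 0 || sd_irrelevant < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (sd_probe == 0 && sd_irrelevant == 0)
    stop("degenerate variance: both condition SDs are 0", call. = FALSE)
  mean_diff / sqrt((sd_probe^2 + sd_irrelevant^2) / 2)
}
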