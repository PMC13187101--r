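#' Frequency band specification
#'
#' @param low_hz,high_hz band edges (0 < low < high).
#' @param name band label; the two standard analysis bands are `"narrow"`
#'   (0.5--7 Hz, below the notched-out SSVEP) and `"full"` (0.5--45 Hz).
#' @return object of class `band_spec`.
#' @export
band_spec <- function(low_hz, high_hz, name = sprintf("%g-%g Hz", low_hz,
                                                      high_hz)) {
  if (!(0 < low_hz && low_hz < high_hz))
    stop("band must satisfy 0 < low < high", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz, name = name),
            class = "band_spec")
}

#' @rdname band_spec
#' @export
narrow_band <- function() band_spec(0.5, 7, "narrow")

#' @rdname band_spec
#' @export
full_band <- function() band_spec(0.5, 45, "full")

#' Short-time Fourier decomposition of epoched trials
#'
#' Sliding tapered Fourier transform of one channel, per trial, on a grid of
#' analysis frequencies and frame centers. Each frame applies a Hann taper
#' of length `win_ms`; so that frames near the epoch edges (including the
#' -100..0 ms baseline frames) carry full-length tapers, each trial is
#' reflection-padded by half a taper at both ends — truncating the taper
#' instead would broaden the low-frequency bins exactly where the 1/f
#' background is steepest and tilt the power estimate toward the epoch
#' edges. Coefficients are normalised by the root sum of squared taper
#' weights, so `Mod(coef)^2` is a comparable power estimate across frames.
#' Phase is referenced to absolute epoch time (stimulus locked), which is
#' what inter-trial coherence requires. Frequencies whose period exceeds
#' the taper length are dropped with a warning rather than silently
#' zero-padded. Supply detrended, non-baseline-subtracted epochs:
#' subtracting a per-trial baseline constant suppresses spectral power in
#' frames overlapping the baseline window and biases the ERSP dB baseline.
#'
#' @param epochs an `epoch_set`.
#' @param channel channel label.
#' @param freqs analysis frequencies in Hz, inside (0, rate/2).
#' @param win_ms nominal taper length in ms (default 512).
#' @param step_ms frame step in ms (default 12; snapped to the sample grid).
#' @param time_range_ms frame-center range (default -100..1200 ms, covering
#'   the baseline and the full search window).
#' @param baseline_ms baseline window for [ersp()] (default -100..0 ms).
#' @return a `tf_decomposition`: complex coefficient matrix
#'   (trials x freq*time, frequency varying fastest), `freqs`, `times_ms`
#'   (frame centers), grid sizes, and method metadata.
#' @export
tf_decompose <- function(epochs, channel, freqs, win_ms = 512, step_ms = 12,
                         time_range_ms = c(-100, 1200),
                         baseline_ms = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!channel %in% epochs$channels)
    stop("channel not found: ", channel, call. = FALSE)
  rate <- epochs$rate_hz
  if (any(freqs <= 0) || any(freqs >= rate / 2))
    stop("analysis frequencies must lie inside (0, rate/2)", call. = FALSE)
  keep <- 1000 / freqs <= win_ms
  if (any(!keep)) {
    warning(sprintf(
      "dropping %d frequencies below %.3g Hz whose period exceeds the %g ms taper",
      sum(!keep), 1000 / win_ms, win_ms), call. = FALSE)
    freqs <- freqs[keep]
  }
  if (!length(freqs)) stop("no usable analysis frequencies", call. = FALSE)
  t_ms <- epochs$time_ms
  n <- length(t_ms)
  L <- 2 * floor(win_ms * rate / 2000) + 1  # odd, symmetric about the center
  h <- (L - 1) / 2
  if (h >= n)
    stop("taper length exceeds the epoch; shorten `win_ms`", call. = FALSE)
  w_full <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  step <- max(1L, round(step_ms * rate / 1000))
  cand <- which(t_ms >= time_range_ms[1] - 1e-6 &
                t_ms <= time_range_ms[2] + 1e-6)
  centers <- cand[seq(1, length(cand), by = step)]
  nf <- length(freqs)
  nt <- length(centers)
  # padded sample axis: h reflected samples on each side
  t_pad <- (seq_len(n + 2 * h) - h - 1) * 1000 / rate + t_ms[1]
  norm <- sqrt(sum(w_full^2))
  basis <- matrix(0 + 0i, nrow = nf * nt, ncol = n + 2 * h)
  for (ti in seq_len(nt)) {
    j <- centers[ti]:(centers[ti] + 2 * h)  # padded coords, always full
    blk <- exp(-2i * pi * outer(freqs, t_pad[j] / 1000)) *
      matrix(w_full, nf, L, byrow = TRUE) / norm
    basis[(ti - 1) * nf + seq_len(nf), j] <- blk
  }
  x <- matrix(epochs$data[, match(channel, epochs$channels), ],
              nrow = n_trials(epochs))
  x_pad <- cbind(x[, (h + 1):2, drop = FALSE], x,
                 x[, (n - 1):(n - h), drop = FALSE])
  coef <- x_pad %*% t(basis)
  structure(
    list(coef = coef, freqs = freqs, times_ms = t_ms[centers],
         n_freq = nf, n_time = nt, rate_hz = rate,
         baseline_ms = baseline_ms, channel = channel,
         condition = epochs$condition,
         params = list(win_ms = win_ms, step_ms = step * 1000 / rate,
                       taper = "hann", n_trials = n_trials(epochs))),
    class = "tf_decomposition")
}

#' @export
print.tf_decomposition <- function(x, ...) {
  cat(sprintf("<tf_decomposition> %s @ %s: %d trials x %d freqs x %d frames (%s taper, %g ms)\n",
              x$condition, x$channel, nrow(x$coef), x$n_freq, x$n_time,
              x$params$taper, x$params$win_ms))
  invisible(x)
}

#' Pool the trials of two decompositions on the same grid
#' @param a,b `tf_decomposition`s with identical frequency/time grids.
#' @return a pooled `tf_decomposition`.
#' @export
combine_decompositions <- function(a, b) {
  stopifnot(inherits(a, "tf_decomposition"), inherits(b, "tf_decomposition"))
  if (!isTRUE(all.equal(a$freqs, b$freqs)) ||
      !isTRUE(all.equal(a$times_ms, b$times_ms)))
    stop("decompositions are on different grids", call. = FALSE)
  out <- a
  out$coef <- rbind(a$coef, b$coef)
  out$condition <- paste(a$condition, b$condition, sep = "+")
  out$params$n_trials <- a$params$n_trials + b$params$n_trials
  out
}

tf_grid_matrix <- function(values, decomp) {
  matrix(values, nrow = decomp$n_freq, ncol = decomp$n_time,
         dimnames = list(NULL, NULL))
}

#' Event-related spectral perturbation (ERSP), in dB
#'
#' Trial-mean power per (frequency, time) bin, expressed in dB relative to
#' the mean baseline power at that frequency:
#' `10 * log10(P(f, t) / mean_baseline(P(f, .)))`, with the baseline taken
#' over frames centered in `baseline_ms` (divisive baseline, then dB, as in
#' the common toolbox convention). Zero baseline power is floored at a tiny
#' positive value with a warning.
#'
#' @param decomp a `tf_decomposition`.
#' @return a `tf_map` with `kind = "ERSP_dB"`.
#' @export
ersp <- function(decomp) {
  stopifnot(inherits(decomp, "tf_decomposition"))
  P <- tf_grid_matrix(colMeans(Mod(decomp$coef)^2), decomp)
  bidx <- which(decomp$times_ms >= decomp$baseline_ms[1] - 1e-6 &
                decomp$times_ms <= decomp$baseline_ms[2] + 1e-6)
  if (!length(bidx))
    stop("no frames inside the baseline window", call. = FALSE)
  Pb <- rowMeans(P[, bidx, drop = FALSE])
  if (any(Pb <= 0)) {
    warning("zero baseline power at some frequencies; floored", call. = FALSE)
    floor_val <- max(.Machine$double.xmin, min(Pb[Pb > 0], na.rm = TRUE) * 1e-12)
    Pb[Pb <= 0] <- floor_val
  }
  structure(list(values = 10 * log10(P / Pb), freqs = decomp$freqs,
                 times_ms = decomp$times_ms, kind = "ERSP_dB",
                 condition = decomp$condition, channel = decomp$channel),
            class = "tf_map")
}

#' Inter-trial coherence (ITC)
#'
#' Resultant length of the per-trial unit phase vectors at each
#' (frequency, time) bin: `|mean(coef / |coef|)|`, in \[0, 1\]. Bins where a
#' trial has exactly zero magnitude contribute 0 for that trial (counted in
#' the `n_zero` attribute). ITC is invariant to per-trial amplitude scaling.
#'
#' @param decomp a `tf_decomposition` with at least one trial.
#' @return a `tf_map` with `kind = "ITC"`.
#' @export
itc <- function(decomp) {
  stopifnot(inherits(decomp, "tf_decomposition"))
  mag <- Mod(decomp$coef)
  zero <- mag == 0
  mag[zero] <- 1  # unit phasor of a zero coefficient is taken as 0
  U <- decomp$coef / mag
  U[zero] <- 0 + 0i
  R <- Mod(colMeans(U))
  out <- structure(list(values = tf_grid_matrix(R, decomp),
                        freqs = decomp$freqs, times_ms = decomp$times_ms,
                        kind = "ITC", condition = decomp$condition,
                        channel = decomp$channel),
                   class = "tf_map")
  attr(out, "n_zero") <- sum(zero)
  out
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %s (%s @ %s): %d freqs x %d frames, range [%.3g, %.3g]\n",
              x$kind, x$condition, x$channel, length(x$freqs),
              length(x$times_ms), min(x$values), max(x$values)))
  invisible(x)
}

band_rows <- function(freqs, band) {
  rows <- which(freqs >= band$low_hz - 1e-9 & freqs <= band$high_hz + 1e-9)
  if (!length(rows))
    stop("band is empty after intersecting the analysis frequencies",
         call. = FALSE)
  rows
}

#' Contrast-orthogonal time-frequency window placement
#'
#' Pools all trials of both conditions, computes the aggregated measure
#' (ERSP or ITC) on the pooled trials, averages it over the band
#' frequencies (unweighted) to a time course, and scans every 100 ms
#' interval within the search bounds for the highest mean. Ties are broken
#' by the earliest start. Because placement uses the pooled trials it is
#' invariant to condition labels.
#'
#' @param probe,irrelevant `epoch_set`s, or `NULL` if `decomp` is given.
#' @param channel channel label.
#' @param band a [band_spec()].
#' @param measure `"ERSP"` or `"ITC"`.
#' @param width_ms window width (default 100).
#' @param bounds_ms search bounds (default 0--1200 ms; the scan is further
#'   limited to the decomposition's frame range).
#' @param source label recorded on the window (`"aERPt"` per participant,
#'   `"AGAT"` at group level).
#' @param decomp optional precomputed pooled `tf_decomposition` (overrides
#'   `probe`/`irrelevant`).
#' @param freqs analysis frequencies when decomposing here; defaults to
#'   0.5 Hz steps across the band.
#' @param ... passed to [tf_decompose()].
#' @return a [roi_window()].
#' @export
aggregated_tf_window <- function(probe = NULL, irrelevant = NULL, channel,
                                 band, measure = c("ERSP", "ITC"),
                                 width_ms = 100, bounds_ms = c(0, 1200),
                                 source = "aERPt", decomp = NULL,
                                 freqs = NULL, ...) {
  measure <- match.arg(measure)
  if (is.null(decomp)) {
    if (is.null(freqs))
      freqs <- seq(band$low_hz, band$high_hz, by = 0.5)
    decomp <- combine_decompositions(
      tf_decompose(probe, channel, freqs, ...),
      tf_decompose(irrelevant, channel, freqs, ...))
  }
  map <- if (measure == "ERSP") ersp(decomp) else itc(decomp)
  tf_map_window(map, band, width_ms = width_ms, bounds_ms = bounds_ms,
                source = source)
}

#' Scan a time-frequency map for its highest fixed-width window
#'
#' Band-collapses the map (unweighted mean over band frequencies) and runs
#' the exhaustive earliest-tie 100 ms scan on the resulting time course.
#'
#' @param map a `tf_map`.
#' @param band a [band_spec()].
#' @param width_ms window width in ms.
#' @param bounds_ms search bounds in ms.
#' @param source label for the returned window.
#' @return a [roi_window()].
#' @export
tf_map_window <- function(map, band, width_ms = 100, bounds_ms = c(0, 1200),
                          source = "aERPt") {
  stopifnot(inherits(map, "tf_map"))
  rows <- band_rows(map$freqs, band)
  course <- colMeans(map$values[rows, , drop = FALSE])
  t_f <- map$times_ms
  if (length(t_f) < 2)
    stop("need at least two frames to scan", call. = FALSE)
  step <- t_f[2] - t_f[1]
  wf <- max(1L, round(width_ms / step))
  starts <- which(t_f >= bounds_ms[1] - 1e-6 &
                  t_f <= bounds_ms[2] - width_ms + 1e-6)
  starts <- starts[starts + wf - 1 <= length(t_f)]
  if (!length(starts))
    stop("no candidate window start inside the search bounds", call. = FALSE)
  cs <- cumsum(c(0, course))
  means <- (cs[starts + wf] - cs[starts]) / wf
  s <- starts[which.max(means)]
  roi_window(start_ms = t_f[s], end_ms = t_f[s] + width_ms, source = source,
             channel = map$channel)
}

#' Positive-sum statistic of a map in a window and band
#'
#' Sum of `max(value, 0)` over all (frequency, time) bins with frequency in
#' the band and frame center in the half-open window. The contrast
#' statistic of the permutation test is the Probe positive sum minus the
#' Irrelevant positive sum.
#'
#' @param tfmap a `tf_map`.
#' @param window a [roi_window()].
#' @param band a [band_spec()].
#' @return the positive sum (dB for ERSP, coherence units for ITC).
#' @export
positive_sum_statistic <- function(tfmap, window, band) {
  stopifnot(inherits(tfmap, "tf_map"))
  rows <- band_rows(tfmap$freqs, band)
  cols <- which(tfmap$times_ms >= window$start_ms - 1e-6 &
                tfmap$times_ms < window$end_ms - 1e-6)
  if (!length(cols))
    stop("window contains no frames of this map", call. = FALSE)
  sum(pmax(tfmap$values[rows, cols, drop = FALSE], 0))
}

# Positive-sum statistics for surrogate condition assignments.
# `ind` is an iterations x 2m 0/1 matrix selecting each iteration's
# surrogate-Probe rows; power/phasor sums are linear in trials, so all
# iterations reduce to two matrix products over the restricted bins.
surrogate_positive_sums <- function(coef, ind, measure, fcols_window,
                                    fcols_baseline = NULL, nf_band = NULL) {
  m <- sum(ind[1, ])
  n_all <- nrow(coef)
  if (measure == "ITC") {
    U <- coef[, fcols_window, drop = FALSE]
    mag <- Mod(U); zero <- mag == 0; mag[zero] <- 1
    U <- U / mag; U[zero] <- 0 + 0i
    Ur <- Re(U); Ui <- Im(U)
    pr <- ind %*% Ur; pi_ <- ind %*% Ui
    tr <- matrix(colSums(Ur), nrow(ind), ncol(Ur), byrow = TRUE)
    ti <- matrix(colSums(Ui), nrow(ind), ncol(Ui), byrow = TRUE)
    itc_p <- sqrt(pr^2 + pi_^2) / m
    itc_i <- sqrt((tr - pr)^2 + (ti - pi_)^2) / (n_all - m)
    list(probe = rowSums(itc_p), irrelevant = rowSums(itc_i))
  } else {
    cols <- c(fcols_window, fcols_baseline)
    Pw <- Mod(coef[, cols, drop = FALSE])^2
    Sp <- (ind %*% Pw) / m
    Si <- (matrix(colSums(Pw), nrow(ind), ncol(Pw), byrow = TRUE) -
             ind %*% Pw) / (n_all - m)
    nw <- length(fcols_window) / nf_band
    nb <- length(fcols_baseline) / nf_band
    pos_sum <- function(S) {
      out <- numeric(nrow(S))
      for (fi in seq_len(nf_band)) {
        wcols <- seq(fi, length(fcols_window), by = nf_band)
        bcols <- length(fcols_window) +
          seq(fi, length(fcols_baseline), by = nf_band)
        Pb <- rowMeans(S[, bcols, drop = FALSE])
        Pb[Pb <= 0] <- .Machine$double.xmin
        out <- out +
          rowSums(pmax(10 * log10(S[, wcols, drop = FALSE] / Pb), 0))
      }
      out
    }
    list(probe = pos_sum(Sp), irrelevant = pos_sum(Si))
  }
}

#' Permutation test of the time-frequency positive-sum contrast
#'
#' Trial matching and 2m-row label shuffling exactly as in
#' [randomisation_test()]: per permutation the per-condition measure (ERSP
#' or ITC) is recomputed from the permuted trial assignment using the
#' cached per-trial coefficients, the positive-sum statistic is taken in
#' the fixed contrast-orthogonal window, and the surrogate contrast
#' (surrogate-Probe minus surrogate-Irrelevant) is recorded. The p-value is
#' the proportion of surrogates `>=` the observed contrast, ties counting.
#'
#' @param probe,irrelevant `epoch_set`s (>= 2 trials each), or `NULL` when
#'   `decomp_probe`/`decomp_irrelevant` are supplied.
#' @param channel channel label.
#' @param band a [band_spec()].
#' @param measure `"ERSP"` or `"ITC"`.
#' @param window the fixed [roi_window()] (from [aggregated_tf_window()]).
#' @param n_iter permutations (1000 by default; the narrow-band analysis
#'   conventionally uses 10000).
#' @param seed integer seed.
#' @param decomp_probe,decomp_irrelevant optional cached decompositions.
#' @param freqs analysis frequencies if decomposing here.
#' @param ... passed to [tf_decompose()].
#' @return a `permutation_result` (component = measure); also carries the
#'   per-condition observed positive sums as `observed_probe` /
#'   `observed_irrelevant`.
#' @export
tf_permutation_test <- function(probe = NULL, irrelevant = NULL, channel,
                                band, measure = c("ERSP", "ITC"), window,
                                n_iter = 1000, seed = 1,
                                decomp_probe = NULL,
                                decomp_irrelevant = NULL, freqs = NULL,
                                ...) {
  measure <- match.arg(measure)
  if (is.null(decomp_probe)) {
    if (is.null(freqs)) freqs <- seq(band$low_hz, band$high_hz, by = 0.5)
    decomp_probe <- tf_decompose(probe, channel, freqs, ...)
  }
  if (is.null(decomp_irrelevant)) {
    if (is.null(freqs)) freqs <- seq(band$low_hz, band$high_hz, by = 0.5)
    decomp_irrelevant <- tf_decompose(irrelevant, channel, freqs, ...)
  }
  dp <- decomp_probe; di <- decomp_irrelevant
  if (!isTRUE(all.equal(dp$freqs, di$freqs)) ||
      !isTRUE(all.equal(dp$times_ms, di$times_ms)))
    stop("decompositions are on different grids", call. = FALSE)
  n_p <- nrow(dp$coef); n_i <- nrow(di$coef)
  m <- min(n_p, n_i)
  if (m < 2)
    stop("insufficient data: need at least 2 trials per condition",
         call. = FALSE)
  fb <- band_rows(dp$freqs, band)
  nf <- dp$n_freq
  tw <- which(dp$times_ms >= window$start_ms - 1e-6 &
              dp$times_ms < window$end_ms - 1e-6)
  tb <- which(dp$times_ms >= dp$baseline_ms[1] - 1e-6 &
              dp$times_ms <= dp$baseline_ms[2] + 1e-6)
  if (!length(tw)) stop("window contains no frames", call. = FALSE)
  cols_of <- function(frames) as.vector(outer(fb, (frames - 1) * nf, `+`))
  fcols_w <- cols_of(tw)
  fcols_b <- if (measure == "ERSP") cols_of(tb) else NULL
  with_seed(seed, {
    sel_p <- sample.int(n_p, m)
    sel_i <- sample.int(n_i, m)
    coef <- rbind(dp$coef[sel_p, , drop = FALSE],
                  di$coef[sel_i, , drop = FALSE])
    obs_ind <- matrix(0, 1, 2 * m)
    obs_ind[1, seq_len(m)] <- 1
    obs <- surrogate_positive_sums(coef, obs_ind, measure, fcols_w, fcols_b,
                                   length(fb))
    observed <- obs$probe - obs$irrelevant
    ind <- matrix(0, n_iter, 2 * m)
    for (it in seq_len(n_iter)) ind[it, sample.int(2 * m, m)] <- 1
    surr <- surrogate_positive_sums(coef, ind, measure, fcols_w, fcols_b,
                                    length(fb))
    surrogates <- surr$probe - surr$irrelevant
    structure(
      list(observed = observed, surrogates = surrogates,
           p = sum(surrogates >= observed) / n_iter, n_iter = n_iter, m = m,
           seed = seed, component = measure, polarity = "maximal",
           channel = channel, band = band$name,
           observed_probe = obs$probe, observed_irrelevant = obs$irrelevant),
      class = "permutation_result")
  })
}

#' Group-level paired test of per-participant positive-sum measures
#'
#' Identical machinery to [group_paired_ttest()], applied to the
#' participant-level Probe and Irrelevant positive-sum values of one
#' measure and band.
#'
#' @param probe_sums,irrelevant_sums per-participant positive sums, paired.
#' @return a `group_test_result`.
#' @export
group_tf_test <- function(probe_sums, irrelevant_sums) {
  group_paired_ttest(probe_sums, irrelevant_sums)
}
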