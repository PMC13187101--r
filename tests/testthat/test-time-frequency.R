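sine_epochs <- function(n_trials, freq_hz, amp = 1, phase = 0,
                        rate_hz = 512) {
  t_ms <- epoch_time_axis(rate_hz, c(-200, 1200))
  x <- amp * sin(2 * pi * freq_hz * t_ms / 1000 + phase)
  toy_epochs(matrix(x, n_trials, length(t_ms), byrow = TRUE),
             rate_hz = rate_hz)
}

test_that("the short-time transform localises a pure sinusoid in frequency", {
  es <- sine_epochs(1, 4)
  d <- tf_decompose(es, "ch1", freqs = 2:8)
  mag <- matrix(Mod(d$coef[1, ]), d$n_freq, d$n_time)
  interior <- which(d$times_ms > 300 & d$times_ms < 900)
  for (ti in interior)
    expect_equal(d$freqs[which.max(mag[, ti])], 4)
})

test_that("degenerate decompositions behave: zero signal, identical trials", {
  z <- toy_epochs(matrix(0, 2, 716))
  dz <- tf_decompose(z, "ch1", freqs = c(3, 5))
  expect_true(all(Mod(dz$coef) == 0))
  es <- sine_epochs(2, 3)
  d2 <- tf_decompose(es, "ch1", freqs = c(3, 5))
  expect_equal(d2$coef[1, ], d2$coef[2, ])
  expect_error(tf_decompose(es, "ch1", freqs = c(3, 400)), "rate/2")
  expect_warning(tf_decompose(es, "ch1", freqs = c(0.5, 3)), "dropping")
})

test_that("ERSP is a dB ratio against the per-frequency baseline mean", {
  freqs <- c(3, 5); times <- seq(-96, 1200, by = 12)
  nb <- length(freqs) * length(times)
  # equal power everywhere: 0 dB
  d <- toy_decomp(matrix(complex(modulus = 2, argument = 0.3), 4, nb),
                  freqs, times)
  e <- ersp(d)
  expect_true(all(abs(e$values) < 1e-12))
  # a single bin at 10x baseline power reads +10 dB
  coef <- matrix(complex(modulus = 1, argument = 0), 4, nb)
  ti <- which(times > 400)[1]
  bin <- (ti - 1) * 2 + 1   # frequency-fastest column order
  coef[, bin] <- complex(modulus = sqrt(10), argument = 0)
  e2 <- ersp(toy_decomp(coef, freqs, times))
  expect_equal(e2$values[bin], 10, tolerance = 1e-9)
  expect_lt(max(abs(e2$values[-bin])), 1e-9)
  # ERSP is invariant to a global amplitude scale
  e3 <- ersp(toy_decomp(3.7 * coef, freqs, times))
  expect_equal(e3$values, e2$values, tolerance = 1e-9)
})

test_that("a generated burst puts the ERSP maximum inside its time-frequency support", {
  p <- sim_params(n_participants = 1, trials_per_condition = 40,
                  probe_p600_amp_uv = 0, irrelevant_neg_amp_uv = 0,
                  ssvep_amp_uv = 0, drift_slope_uv_per_s = 0,
                  noise_psd = list(one_over_f_exponent = 1, pink_sd_uv = 2,
                                   white_sd_uv = 1, alpha_amp_uv = 0),
                  seed = 17)
  pd <- simulate_participant(p, 1)
  e <- ersp(tf_decompose(pd$probe, "Pz", seq(2, 10, 0.5)))
  peak <- which(e$values == max(e$values), arr.ind = TRUE)[1, ]
  expect_gte(e$times_ms[peak[2]], 280 - 100)
  expect_lte(e$times_ms[peak[2]], 620 + 100)
  expect_lte(abs(e$freqs[peak[1]] - 3.5), 1.5)
})

test_that("ITC is bounded, amplitude-invariant and exact in degenerate cases", {
  es <- sine_epochs(3, 3)
  d <- tf_decompose(es, "ch1", freqs = c(3, 5))
  v <- itc(d)$values
  expect_true(all(v >= 0 & v <= 1 + 1e-12))
  expect_true(all(abs(v - 1) < 1e-9))   # identical trials cohere perfectly

  one <- tf_decompose(sine_epochs(1, 3), "ch1", freqs = c(3, 5))
  expect_true(all(abs(itc(one)$values - 1) < 1e-9))

  # per-trial amplitude scaling leaves ITC unchanged
  es2 <- es
  es2$data[2, , ] <- 5 * es2$data[2, , ]
  d2 <- tf_decompose(es2, "ch1", freqs = c(3, 5))
  expect_equal(itc(d2)$values, v, tolerance = 1e-9)

  # iid uniform phases: resultant length ~ 1/sqrt(n)
  set.seed(2)
  coef <- matrix(complex(modulus = 1, argument = runif(1000 * 6, 0, 2 * pi)),
                 1000, 6)
  r <- itc(toy_decomp(coef, c(3, 5), c(0, 100, 200)))
  expect_true(all(r$values < 0.1))
})

test_that("time-frequency window placement matches its oracle and tie rule", {
  freqs <- c(3, 4, 5)
  times <- seq(0, 1200, by = 12)
  hot <- matrix(0, 3, length(times))
  hot[, times >= 400 & times <= 520] <- 1
  w <- tf_map_window(toy_map(hot, freqs, times), band_spec(2, 7))
  expect_gte(w$start_ms, 390)
  expect_lte(w$end_ms, 530)

  flat <- toy_map(matrix(1, 3, length(times)), freqs, times)
  expect_equal(tf_map_window(flat, band_spec(2, 7))$start_ms, 0)

  set.seed(5)
  for (i in 1:40) {
    m <- toy_map(matrix(rnorm(3 * length(times)), 3), freqs, times)
    got <- tf_map_window(m, band_spec(2, 7))
    want <- oracle_frame_scan(colMeans(m$values), times, 100, c(0, 1200))
    expect_equal(got$start_ms, times[want])
  }
})

test_that("tf window placement is invariant to condition labels", {
  p <- sim_params(n_participants = 1, trials_per_condition = 12, seed = 23)
  pd <- simulate_participant(p, 1)
  pooled <- array(c(pd$probe$data, pd$irrelevant$data),
                  dim = c(24, dim(pd$probe$data)[2:3]))
  place <- function(idx) {
    a <- epoch_set(pooled[idx, , , drop = FALSE], pd$probe$time_ms, 512,
                   "Probe", pd$probe$channels)
    b <- epoch_set(pooled[-idx, , , drop = FALSE], pd$probe$time_ms, 512,
                   "Irrelevant", pd$probe$channels)
    aggregated_tf_window(a, b, "Pz", band_spec(2, 7), "ITC",
                         freqs = seq(2, 7, 1))
  }
  set.seed(6)
  w1 <- place(1:12)
  w2 <- place(sample(24, 12))
  expect_equal(w1$start_ms, w2$start_ms)
})

test_that("the positive-sum statistic rectifies before summing", {
  m <- toy_map(matrix(c(-1, 2, 3, -4), 2, 2), c(3, 5), c(400, 450))
  w <- roi_window(400, 500)
  expect_equal(positive_sum_statistic(m, w, band_spec(2, 7)), 5)
  m2 <- toy_map(matrix(c(-1, -2, -3, -4), 2, 2), c(3, 5), c(400, 450))
  expect_equal(positive_sum_statistic(m2, w, band_spec(2, 7)), 0)
  m3 <- toy_map(matrix(1:4, 2, 2), c(3, 5), c(400, 450))
  expect_equal(positive_sum_statistic(m3, w, band_spec(2, 7)), 10)
  # band restriction drops out-of-band rows
  expect_equal(positive_sum_statistic(m3, w, band_spec(2.5, 3.5)),
               sum(c(1, 3)))
})

test_that("the tf permutation test is degenerate on identical conditions and detects a phase-locked burst", {
  es <- sine_epochs(6, 3)
  r <- tf_permutation_test(es, es, channel = "ch1", band = band_spec(2, 7),
                           measure = "ITC",
                           window = roi_window(400, 500), n_iter = 100,
                           seed = 1, freqs = c(3, 5))
  expect_equal(r$observed, 0, tolerance = 1e-9)
  expect_equal(r$p, 1)

  # phase-locked 3.5 Hz burst vs noise only, m = 60
  t_ms <- epoch_time_axis(512, c(-200, 1200))
  u <- (t_ms - 280) / 340
  burst <- ifelse(u >= 0 & u <= 1,
                  3 * (0.5 - 0.5 * cos(2 * pi * u)) *
                    sin(2 * pi * 3.5 * u * 340 / 1000), 0)
  set.seed(9)
  probe <- toy_epochs(matrix(burst, 60, 716, byrow = TRUE) +
                        matrix(rnorm(60 * 716, sd = 4), 60, 716))
  irr <- toy_epochs(matrix(rnorm(60 * 716, sd = 4), 60, 716),
                    condition = "Irrelevant")
  w <- roi_window(330, 430)
  r2 <- tf_permutation_test(probe, irr, channel = "ch1",
                            band = band_spec(2, 7), measure = "ITC",
                            window = w, n_iter = 1000, seed = 3,
                            freqs = seq(2, 7, 0.5))
  expect_lte(r2$p, 0.01)
  expect_gt(r2$observed_probe, r2$observed_irrelevant)

  expect_error(
    tf_permutation_test(toy_epochs(matrix(0, 1, 716)), irr, channel = "ch1",
                        band = band_spec(2, 7), measure = "ITC",
                        window = w, freqs = c(3)),
    "at least 2 trials")
})

test_that("group tf inference is the paired-t machinery on positive sums", {
  n <- 14
  z <- as.vector(scale(seq_len(n)))
  probe_sums <- 2 / sqrt(n) + z        # mean/(sd/sqrt(n)) = 2 exactly
  g <- group_tf_test(probe_sums, rep(0, n))
  expect_equal(g$t, 2, tolerance = 1e-9)
  expect_equal(g$df, n - 1)
  expect_error(group_tf_test(rep(0, 5), rep(0, 5)), "degenerate")
})
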