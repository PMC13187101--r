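make_rec <- function(x, rate_hz = 512, channels = NULL, ...) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(x)))
  continuous_recording(x, rate_hz, channels, ...)
}

interior <- function(y) {
  n <- length(y)
  y[floor(n / 3):floor(2 * n / 3)]
}

test_that("band-pass filter passes the band and rejects DC and 60 Hz", {
  fs <- 512
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  amp_after <- function(x) max(abs(interior(
    bandpass_filter(make_rec(x, fs))$data[1, ])))
  expect_lt(abs(amp_after(sin(2 * pi * 3 * t)) - 1), 0.05)
  expect_lt(amp_after(rep(10, length(t))), 0.5)
  expect_lt(amp_after(sin(2 * pi * 60 * t)), 0.1)
  # mid-band gain within 1 dB
  expect_gt(amp_after(sin(2 * pi * 10 * t)), 10^(-1 / 20))
  expect_error(bandpass_filter(make_rec(t, fs), 0.5, 300), "rate/2")
})

test_that("notch filter removes 8 Hz and passes the flanks", {
  fs <- 512
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  amp_after <- function(f) max(abs(interior(
    notch_filter(make_rec(sin(2 * pi * f * t), fs))$data[1, ])))
  expect_lt(amp_after(8), 0.1)       # >= 20 dB down
  expect_gt(amp_after(3), 0.7)       # < 3 dB
  expect_gt(amp_after(12), 0.7)
  z <- notch_filter(make_rec(rep(0, 1000), fs))
  expect_true(all(z$data == 0))
})

test_that("filters are linear operators", {
  fs <- 512
  set.seed(1)
  x <- rnorm(2048); y <- rnorm(2048)
  a <- 2.5; b <- -1.25
  for (filt in list(bandpass_filter, notch_filter)) {
    lhs <- filt(make_rec(a * x + b * y, fs))$data[1, ]
    rhs <- a * filt(make_rec(x, fs))$data[1, ] +
      b * filt(make_rec(y, fs))$data[1, ]
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("resampling is anti-aliased, duration-preserving and downsample-only", {
  fs <- 2048
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  rec <- make_rec(sin(2 * pi * 3 * t), fs)
  out <- resample_recording(rec, 512)
  expect_equal(ncol(out$data), 512)
  t_new <- seq(0, 1 - 1 / 512, by = 1 / 512)
  expect_lt(max(abs(out$data[1, ] - sin(2 * pi * 3 * t_new))), 1e-3)
  expect_identical(resample_recording(rec, fs), rec)
  const <- resample_recording(make_rec(rep(4, 2048), fs), 512)
  expect_equal(const$data[1, ], rep(4, 512), tolerance = 1e-9)
  expect_error(resample_recording(rec, 4096), "upsampling")
  # events move to the nearest new-grid sample
  rec_ev <- make_rec(sin(2 * pi * 3 * t), fs,
                     events = data.frame(sample = 1025, condition = "Probe"))
  expect_equal(resample_recording(rec_ev, 512)$events$sample, 257)
})

test_that("mastoid re-referencing subtracts the reference mean from EEG only", {
  n <- 100
  dat <- rbind(Pz = rep(10, n), VEOG = rep(5, n), A1 = rep(2, n),
               A2 = rep(4, n))
  rec <- make_rec(dat, channels = rownames(dat))
  out <- rereference_mastoids(rec)
  expect_equal(out$data["Pz", ], rep(7, n))
  expect_equal(out$data["VEOG", ], rep(5, n))   # EOG untouched
  # zero references change nothing
  dat0 <- dat; dat0["A1", ] <- 0; dat0["A2", ] <- 0
  out0 <- rereference_mastoids(make_rec(dat0, channels = rownames(dat)))
  expect_equal(out0$data["Pz", ], dat0["Pz", ])
  # identical channels collapse to zero
  same <- matrix(3, 4, n, dimnames = list(c("Pz", "Cz", "A1", "A2"), NULL))
  outs <- rereference_mastoids(make_rec(same, channels = rownames(same)))
  expect_true(all(outs$data[c("Pz", "Cz"), ] == 0))
  expect_error(rereference_mastoids(make_rec(dat[1:2, ],
                                             channels = c("Pz", "VEOG"))),
               "A1")
})

test_that("epoching follows the half-open stimulus-locked convention", {
  fs <- 512
  n <- fs * 5
  x <- matrix(seq_len(n), nrow = 1)
  s <- 1500
  rec <- make_rec(x, fs, channels = "Pz",
                  events = data.frame(sample = s, condition = "Probe"))
  ep <- epoch_recording(rec)
  n_pre <- round(0.2 * fs); n_post <- round(1.2 * fs)
  expect_equal(n_trials(ep$Probe$epochs), 1)
  expect_equal(ep$Probe$epochs$data[1, 1, ],
               as.numeric(x[1, (s - n_pre):(s + n_post - 1)]))
  expect_equal(ep$Probe$epochs$time_ms[n_pre + 1], 0)

  # 75 events per condition give 75 trials each
  ev <- data.frame(sample = round(seq(500, n - 1000, length.out = 150)),
                   condition = rep(c("Probe", "Irrelevant"), 75))
  ep2 <- epoch_recording(make_rec(x, fs, channels = "Pz", events = ev))
  expect_equal(n_trials(ep2$Probe$epochs), 75)
  expect_equal(n_trials(ep2$Irrelevant$epochs), 75)

  # an event at the very edge is dropped with a warning
  ev3 <- data.frame(sample = c(50, s), condition = "Probe")
  expect_warning(
    ep3 <- epoch_recording(make_rec(x, fs, channels = "Pz", events = ev3)),
    "dropped")
  expect_equal(n_trials(ep3$Probe$epochs), 1)
})

test_that("artifact rejection applies the EOG and EEG thresholds with precedence", {
  es <- const_epochs(3, 10)
  eog <- array(0, dim = c(3, 2, dim(es$data)[3]))
  clean <- reject_artifacts(es, eog)
  expect_equal(clean$report$n_rejected, 0)

  # one EEG sample at +60 uV trips the 50 uV rule
  es2 <- es; es2$data[2, 1, 100] <- 60
  r2 <- reject_artifacts(es2, eog)
  expect_equal(which(!r2$report$flags$keep), 2L)
  expect_equal(r2$report$flags$reason[2], "EEG_exceed")

  # one VEOG sample at -120 uV trips the 100 uV rule and takes precedence
  eog3 <- eog; eog3[3, 1, 50] <- -120
  es3 <- es2
  r3 <- reject_artifacts(es3, eog3)
  expect_setequal(which(!r3$report$flags$keep), c(2L, 3L))
  expect_equal(r3$report$flags$reason[3], "EOG_exceed")
  expect_equal(r3$report$n_kept + r3$report$n_rejected, r3$report$n_total)

  # idempotence: a second pass rejects nothing
  r4 <- reject_artifacts(r3$epochs, r3$eog)
  expect_equal(r4$report$n_rejected, 0)

  expect_error(reject_artifacts(es, eog[1:2, , , drop = FALSE]), "aligned")
})

test_that("detrending cancels an injected line exactly and recovers slopes", {
  t_ms <- epoch_time_axis(512, c(-200, 1200))
  line <- 1.5 + 0.002 * t_ms
  probe <- toy_epochs(matrix(line, 4, length(t_ms), byrow = TRUE))
  irr <- toy_epochs(matrix(line, 3, length(t_ms), byrow = TRUE),
                    condition = "Irrelevant")
  det <- detrend_pair(probe, irr)
  expect_lt(max(abs(det$probe$data)), 1e-9)
  expect_lt(max(abs(det$irrelevant$data)), 1e-9)
  expect_equal(det$fit$slope_uv_per_ms, 0.002, tolerance = 1e-9)

  # already-flat input: only the intercept is removed
  flat <- toy_epochs(matrix(2, 4, length(t_ms)))
  det2 <- detrend_pair(flat, toy_epochs(matrix(2, 4, length(t_ms)),
                                        condition = "Irrelevant"))
  expect_lt(max(abs(det2$probe$data)), 1e-9)
  expect_equal(det2$fit$slope_uv_per_ms, 0, tolerance = 1e-12)

  # synthetic drift of 2 uV/s with noise on is recovered within 5%
  p <- null_effect_params(n_participants = 1, trials_per_condition = 75,
                          drift_slope_uv_per_s = 2, seed = 9)
  pd <- simulate_participant(p, 1)
  det3 <- detrend_pair(pd$probe, pd$irrelevant)
  sl <- det3$fit$slope_uv_per_ms[det3$fit$channel == "Pz"] * 1000
  expect_lt(abs(sl - 2) / 2, 0.05)

  # the detrended+baselined combined average is slope-free on clean input
  pb <- baseline_correct(det$probe)
  ib <- baseline_correct(det$irrelevant)
  comb <- aggregate_erp(pb, ib)
  refit <- unname(coef(lm(comb$data[1, ] ~ t_ms))[2])
  expect_lt(abs(refit), 1e-9)
})

test_that("baseline correction subtracts the pre-stimulus mean per trial", {
  t_ms <- epoch_time_axis(512, c(-200, 1200))
  x <- matrix(3, 2, length(t_ms))
  es <- toy_epochs(x)
  out <- baseline_correct(es)
  expect_true(all(abs(out$data) < 1e-12))
  # zero baseline leaves the trial unchanged
  x2 <- matrix(0, 1, length(t_ms))
  x2[1, t_ms >= 100] <- 5
  out2 <- baseline_correct(toy_epochs(x2))
  expect_equal(out2$data[1, 1, ], x2[1, ])
  expect_error(baseline_correct(es, c(-400, 0)), "inside the epoch")
})

test_that("detrend-then-baseline differs from baseline-then-detrend on drifting input", {
  t_ms <- epoch_time_axis(512, c(-200, 1200))
  sig <- 0.004 * t_ms + 4 * exp(-(t_ms - 500)^2 / (2 * 80^2))
  probe <- toy_epochs(matrix(sig, 3, length(t_ms), byrow = TRUE))
  irr <- toy_epochs(matrix(0.004 * t_ms, 3, length(t_ms), byrow = TRUE),
                    condition = "Irrelevant")
  a <- baseline_correct(detrend_pair(probe, irr)$probe)
  b <- detrend_pair(baseline_correct(probe), baseline_correct(irr))$probe
  expect_gt(max(abs(a$data - b$data)), 0.01)
})

test_that("the epoch-level notch removes a phase-locked SSVEP", {
  t_ms <- epoch_time_axis(512, c(-200, 1200))
  ssvep <- sin(2 * pi * (1000 / 133) * t_ms / 1000)
  es <- toy_epochs(matrix(ssvep, 2, length(t_ms), byrow = TRUE))
  out <- notch_filter_epochs(es)
  mid <- abs(t_ms) < 400
  expect_lt(max(abs(out$data[1, 1, mid])), 0.1)
})

test_that("epoch sets round-trip through the text container", {
  p <- sim_params(n_participants = 1, trials_per_condition = 3, seed = 2)
  es <- simulate_participant(p, 1)$probe
  path <- tempfile(fileext = ".tsv")
  write_epoch_set(es, path)
  back <- read_epoch_set(path)
  expect_equal(back$data, es$data, tolerance = 1e-8)
  expect_equal(back$time_ms, es$time_ms, tolerance = 1e-9)
  expect_identical(back$condition, es$condition)
  expect_identical(back$channels, es$channels)
  unlink(path)
})
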