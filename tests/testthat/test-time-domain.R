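test_that("aERPt aggregation is trial-weighted over the pooled conditions", {
  probe <- const_epochs(2, 1)
  irr <- const_epochs(2, -1, condition = "Irrelevant")
  expect_true(all(abs(aggregate_erp(probe, irr)$data) < 1e-12))

  # 3 trials of 1 vs 1 trial of 5: trial weighting gives 2, not 3
  probe2 <- const_epochs(3, 1)
  irr2 <- const_epochs(1, 5, condition = "Irrelevant")
  expect_equal(unique(as.vector(aggregate_erp(probe2, irr2)$data)), 2)

  # identical conditions reduce to either condition's average
  p <- sim_params(n_participants = 1, trials_per_condition = 4, seed = 3)
  es <- simulate_participant(p, 1)$probe
  agg <- aggregate_erp(es, es)
  expect_equal(agg$data, condition_erp(es)$data, tolerance = 1e-12)
})

test_that("the AGAT is the trial-weighted mean over the whole cohort", {
  one <- list(list(probe = const_epochs(3, 1),
                   irrelevant = const_epochs(1, 5)))
  expect_equal(aggregate_grand_average(one)$data,
               aggregate_erp(one[[1]]$probe, one[[1]]$irrelevant)$data)

  two <- list(list(probe = const_epochs(5, 1), irrelevant = const_epochs(5, 1)),
              list(probe = const_epochs(5, -1), irrelevant = const_epochs(5, -1)))
  expect_true(all(abs(aggregate_grand_average(two)$data) < 1e-12))

  # unequal trial counts 10 vs 30 of constants 1 and 5 average to 4
  uneq <- list(list(probe = const_epochs(5, 1), irrelevant = const_epochs(5, 1)),
               list(probe = const_epochs(15, 5), irrelevant = const_epochs(15, 5)))
  expect_equal(unique(as.vector(aggregate_grand_average(uneq)$data)), 4)
})

test_that("extreme-window search matches the brute-force oracle and tie rule", {
  rate <- 512
  t_ms <- epoch_time_axis(rate, c(-200, 1200))

  bump <- exp(-(t_ms - 500)^2 / (2 * 40^2))
  wf <- structure(list(data = matrix(bump, 1), time_ms = t_ms,
                       rate_hz = rate, channels = "Pz", n_trials = 1),
                  class = "erp_waveform")
  w <- find_extreme_window(wf, "Pz", "maximal")
  expect_lt(abs((w$start_ms + w$end_ms) / 2 - 500), 1000 / rate + 1e-9)
  expect_equal(w$end_ms - w$start_ms, 100)

  flat <- wf; flat$data[] <- 0
  w0 <- find_extreme_window(flat, "Pz", "maximal")
  expect_equal(w0$start_ms, t_ms[min(which(t_ms >= 0))])

  set.seed(71)
  for (i in 1:50) {
    x <- rnorm(length(t_ms))
    wf$data <- matrix(x, 1)
    pol <- sample(c("maximal", "minimal"), 1)
    bounds <- sort(runif(2, 0, 1200))
    if (diff(bounds) < 150) bounds <- c(0, 1200)
    got <- find_extreme_window(wf, "Pz", pol, bounds)
    want <- oracle_scan(x, t_ms, rate, pol, bounds, 100)
    expect_equal(got$start_ms, t_ms[want$start])
  }
  expect_error(find_extreme_window(wf, "Pz", "maximal", c(0, 50)), "span")
})

test_that("window placement is orthogonal to the condition labels", {
  p <- sim_params(n_participants = 1, trials_per_condition = 20, seed = 13)
  pd <- simulate_participant(p, 1)
  pooled <- abind_trials <- array(c(pd$probe$data, pd$irrelevant$data),
                                  dim = c(40, dim(pd$probe$data)[2:3]))
  relabel <- function(idx) {
    a <- epoch_set(pooled[idx, , , drop = FALSE], pd$probe$time_ms, 512,
                   "Probe", pd$probe$channels)
    b <- epoch_set(pooled[-idx, , , drop = FALSE], pd$probe$time_ms, 512,
                   "Irrelevant", pd$probe$channels)
    find_extreme_window(aggregate_erp(a, b), "Pz", "maximal")
  }
  set.seed(4)
  w1 <- relabel(1:20)
  w2 <- relabel(sample(40, 20))
  w3 <- relabel(sample(40, 13))  # uneven relabelling too
  expect_equal(w1$start_ms, w2$start_ms)
  expect_equal(w1$start_ms, w3$start_ms)
})

test_that("mean amplitude is the windowed mean over trials and samples", {
  w <- roi_window(400, 500, n_samples = 51)
  expect_equal(mean_amplitude(const_epochs(3, 1), w, "ch1"), 1)
  two <- const_epochs(2, 0)
  two$data[2, , ] <- 2
  expect_equal(mean_amplitude(two, w, "ch1"), 1)

  # linear ramp: closed form is the midpoint of first and last window sample
  t_ms <- epoch_time_axis(512, c(-200, 1200))
  ramp <- toy_epochs(matrix(t_ms, 1, length(t_ms), byrow = TRUE))
  got <- mean_amplitude(ramp, w, "ch1")
  idx0 <- min(which(t_ms >= 400 - 1e-6))
  expect_equal(got, (t_ms[idx0] + t_ms[idx0 + 50]) / 2, tolerance = 1e-9)

  expect_error(mean_amplitude(const_epochs(2, 1), roi_window(1150, 1250),
                              "ch1"), "beyond")
})

test_that("observed difference is probe minus irrelevant in the shared window", {
  w <- roi_window(300, 400, n_samples = 51)
  a <- const_epochs(3, 2); b <- const_epochs(3, 2, condition = "Irrelevant")
  expect_equal(observed_difference(a, b, w, "ch1"), 0)
  b2 <- const_epochs(3, 0, condition = "Irrelevant")
  expect_equal(observed_difference(a, b2, w, "ch1"), 2)
  c1 <- const_epochs(3, 1.5); c2 <- const_epochs(3, -1.5, condition = "Irrelevant")
  expect_equal(observed_difference(c1, c2, w, "ch1"), 3)
})

test_that("the randomisation test handles degenerate, separated and directional cases", {
  w <- list(P600f = roi_window(400, 500, n_samples = 51))
  const_p <- const_epochs(5, 1)
  const_i <- const_epochs(5, 1, condition = "Irrelevant")
  r <- randomisation_test(const_p, const_i, w, "ch1", n_iter = 100, seed = 1)
  expect_equal(r$P600f$observed, 0)
  expect_true(all(r$P600f$surrogates == 0))
  expect_equal(r$P600f$p, 1)       # ties count as exceeding
  expect_equal(r$P600f$m, 5)

  # a 10 uV shift with m = 30 separates at p <= 0.005
  t_len <- 716
  set.seed(8)
  base <- matrix(rnorm(30 * t_len), 30, t_len)
  probe <- toy_epochs(base + 10)
  irr <- toy_epochs(matrix(rnorm(30 * t_len), 30, t_len),
                    condition = "Irrelevant")
  ws <- list(P600f = roi_window(400, 500, n_samples = 51),
             N400f = roi_window(400, 500, n_samples = 51))
  r2 <- randomisation_test(probe, irr, ws, "ch1", n_iter = 1000, seed = 2)
  expect_lte(r2$P600f$p, 0.005)
  # the minimal-polarity component sees the same +10 shift as maximally
  # non-significant: every surrogate lies below the observed value
  expect_equal(r2$N400f$p, 1)
  # both components' surrogates come from the same permutations
  expect_equal(r2$P600f$surrogates, r2$N400f$surrogates)

  expect_error(randomisation_test(const_epochs(1, 0), const_i, w, "ch1"),
               "at least 2 trials")
})

test_that("randomisation p-values are near-uniform under the null", {
  w <- list(P600f = roi_window(0, 100, n_samples = 51))
  t_axis <- epoch_time_axis(512, c(-50, 150))
  ps <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    a <- epoch_set(array(rnorm(20 * 103), c(20, 1, 103)), t_axis, 512,
                   "Probe", "ch1")
    b <- epoch_set(array(rnorm(20 * 103), c(20, 1, 103)), t_axis, 512,
                   "Irrelevant", "ch1")
    randomisation_test(a, b, w, "ch1", n_iter = 200, seed = i)$P600f$p
  }, 0)
  # mean of a uniform p is 0.5 within Monte-Carlo error
  expect_lt(abs(mean(ps) - 0.5), 3 * sqrt(1 / 12 / 60))
})

test_that("group paired t machinery reproduces printed summary mappings", {
  # construct condition vectors with exact difference mean and SD
  make_pair <- function(mean_diff, sd_diff, n = 14) {
    z <- as.vector(scale(seq_len(n)))
    list(probe = mean_diff + sd_diff * z, irr = rep(0, n))
  }
  pr <- make_pair(2.4232, 2.7311)
  g <- group_paired_ttest(pr$probe, pr$irr)
  expect_equal(g$t, 3.3198, tolerance = 5e-4)
  expect_equal(g$df, 13)
  expect_equal(g$mean_diff, 2.4232)
  expect_equal(g$sd_diff, 2.7311)
  s <- paired_t_from_summary(2.4232, 2.7311, 14)
  expect_equal(g$t, s$t, tolerance = 1e-9)
  expect_equal(g$p, s$p, tolerance = 1e-9)

  expect_error(group_paired_ttest(rep(1, 5), rep(0, 5)), "degenerate")
  expect_error(group_paired_ttest(1:4, 1:5), "pairing")
})

test_that("pooled-condition-SD effect size matches its definition and anchors", {
  expect_equal(cohens_d_pooled(2.4232, 2.0809, 1.3911), 1.3691,
               tolerance = 1e-4)
  expect_equal(cohens_d_pooled(2.1045, 2.4934, 1.7156), 0.9834,
               tolerance = 1e-4)
  expect_equal(cohens_d_pooled(0, 1.3, 0.7), 0)
  expect_error(cohens_d_pooled(1, 0, 0), "degenerate")
  expect_error(cohens_d_pooled(1, -1, 1), ">= 0")
})
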