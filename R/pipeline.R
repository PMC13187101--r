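#' Configuration of an end-to-end analysis run
#'
#' Bundles the simulation (or input-data) source, the channels and
#' components to analyse, the permutation budgets of each test family, the
#' significance level and the master seed. Defaults mirror the paradigm's
#' standard setup: 14 participants, 75 trials per condition at 512 Hz,
#' midline channels with the parietal channel first, 100 ms windows
#' searched over 0--1200 ms, 1000 permutations for time-domain and
#' full-band tests and 10000 for the narrow-band time-frequency tests.
#'
#' @param params a [sim_params()] object (simulate mode).
#' @param data_dir directory of participant data written by
#'   [write_participant_data()] (data mode; overrides `params` as source).
#' @param channels channels analysed in the time domain.
#' @param components named polarity vector of ERP components.
#' @param search_bounds_ms window search bounds (the a-priori
#'   late-positivity preset `c(300, 900)` may be substituted).
#' @param tf_channel single channel for time-frequency analysis.
#' @param tf_freqs analysis frequencies; the default 2--45 Hz in 0.5 Hz
#'   steps is the widest grid the 512 ms taper supports.
#' @param n_iter_time,n_iter_tf_narrow,n_iter_tf_full permutation counts
#'   (each >= 100).
#' @param alpha significance level.
#' @param run_participant_tests run the per-participant permutation tests
#'   (the group analysis never needs them; disabling saves most of the
#'   runtime).
#' @param run_tf run the time-frequency stage.
#' @param notch_band stop band of the epoch-level SSVEP notch applied
#'   before artifact rejection (`NULL` disables it, e.g. for data that was
#'   notch-filtered while continuous).
#' @param eog_limit_uv,eeg_limit_uv artifact-rejection thresholds.
#' @param out_dir optional output directory for TSV/JSON reports.
#' @param seed master seed for all test-stage randomness.
#' @return object of class `run_config`.
#' @export
run_config <- function(params = sim_params(),
                       data_dir = NULL,
                       channels = c("Pz", "Cz", "Fz"),
                       components = c(P600f = "maximal", N400f = "minimal"),
                       search_bounds_ms = c(0, 1200),
                       tf_channel = "Pz",
                       tf_freqs = seq(2, 45, by = 0.5),
                       n_iter_time = 1000,
                       n_iter_tf_narrow = 10000,
                       n_iter_tf_full = 1000,
                       alpha = 0.05,
                       run_participant_tests = TRUE,
                       run_tf = TRUE,
                       notch_band = c(7, 9),
                       eog_limit_uv = 100,
                       eeg_limit_uv = 50,
                       out_dir = NULL,
                       seed = params$seed) {
  if (!is.null(data_dir) && !dir.exists(data_dir))
    stop("data error: `data_dir` does not exist: ", data_dir, call. = FALSE)
  for (ni in c(n_iter_time, n_iter_tf_narrow, n_iter_tf_full))
    if (ni < 100)
      stop("config error: every n_iter must be >= 100", call. = FALSE)
  if (is.null(data_dir)) validate_sim_params(params)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys map to [run_config()] arguments; a `params` mapping is
#' passed to [sim_params()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("data error: config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (!is.null(y$params)) {
    y$params$epoch_ms <- unlist(y$params$epoch_ms %||% c(-200, 1200))
    y$params <- do.call(sim_params, y$params)
  }
  y$components <- unlist(y$components %||%
                           c(P600f = "maximal", N400f = "minimal"))
  do.call(run_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read one participant's data as a plain-text directory
#'
#' Three epoch-set TSVs (`probe`, `irrelevant`, `target`), matching EOG
#' TSVs, and behavioral trial/rating TSVs.
#'
#' @param pd a `participant_data`.
#' @param dir directory to create/write.
#' @return `dir` (write) or a `participant_data` (read).
#' @export
write_participant_data <- function(pd, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in c("probe", "irrelevant", "target")) {
    write_epoch_set(pd[[cond]], file.path(dir, paste0(cond, ".tsv")))
    es <- pd[[cond]]
    eog <- epoch_set(pd$eog[[cond]], es$time_ms, es$rate_hz,
                     paste0(es$condition, "_EOG"), c("VEOG", "HEOG"),
                     es$trial_ids)
    write_epoch_set(eog, file.path(dir, paste0(cond, "_eog.tsv")))
  }
  write.table(pd$behavior$trials, file.path(dir, "behavior_trials.tsv"),
              sep = "\t", row.names = FALSE)
  write.table(pd$behavior$ratings, file.path(dir, "behavior_ratings.tsv"),
              sep = "\t", row.names = FALSE)
  writeLines(sprintf("%d", pd$participant), file.path(dir, "participant.txt"))
  invisible(dir)
}

#' @rdname write_participant_data
#' @export
read_participant_data <- function(dir) {
  need <- file.path(dir, c("probe.tsv", "irrelevant.tsv", "target.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("data error: missing file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sets <- lapply(c(probe = "probe", irrelevant = "irrelevant",
                   target = "target"),
                 function(cond) read_epoch_set(file.path(dir, paste0(cond, ".tsv"))))
  eog <- lapply(c(probe = "probe", irrelevant = "irrelevant",
                  target = "target"), function(cond) {
    read_epoch_set(file.path(dir, paste0(cond, "_eog.tsv")))$data
  })
  idx_file <- file.path(dir, "participant.txt")
  structure(
    list(probe = sets$probe, irrelevant = sets$irrelevant,
         target = sets$target, eog = eog,
         behavior = list(
           trials = read.table(file.path(dir, "behavior_trials.tsv"),
                               header = TRUE, sep = "\t"),
           ratings = read.table(file.path(dir, "behavior_ratings.tsv"),
                                header = TRUE, sep = "\t")),
         participant = if (file.exists(idx_file))
           as.integer(readLines(idx_file)) else NA_integer_,
         amp_factor = NA_real_),
    class = "participant_data")
}

#' Fraction of significant participants per analysis
#'
#' @param results data.frame with columns `analysis` and `p` (one row per
#'   participant and analysis).
#' @param alpha significance level (default 0.05).
#' @return data.frame with `analysis`, `n_significant`, `n_total`, and
#'   `percent` (rounded to 1 decimal, the conventional reporting format).
#' @export
summarise_counts <- function(results, alpha = 0.05) {
  split_res <- split(results$p, results$analysis)
  out <- data.frame(
    analysis = names(split_res),
    n_significant = vapply(split_res, function(p) sum(p < alpha), 0L),
    n_total = vapply(split_res, length, 0L))
  out$percent <- round(100 * out$n_significant / out$n_total, 1)
  rownames(out) <- NULL
  out
}

preprocess_participant <- function(pd, config) {
  rej <- list()
  kept <- list()
  for (cond in c("probe", "irrelevant", "target")) {
    es <- pd[[cond]]
    if (!is.null(config$notch_band))
      es <- notch_filter_epochs(es, config$notch_band[1],
                                config$notch_band[2])
    r <- reject_artifacts(es, pd$eog[[cond]],
                          eog_limit_uv = config$eog_limit_uv,
                          eeg_limit_uv = config$eeg_limit_uv)
    kept[[cond]] <- r$epochs
    rej[[cond]] <- r$report
  }
  det <- detrend_pair(kept$probe, kept$irrelevant)
  # time-frequency uses the detrended, non-baseline-subtracted trials: a
  # per-trial DC shift is irrelevant to the tapered transform but would
  # bias the ERSP spectral baseline
  list(probe = baseline_correct(det$probe),
       irrelevant = baseline_correct(det$irrelevant),
       target = baseline_correct(kept$target),
       probe_tf = det$probe, irrelevant_tf = det$irrelevant,
       detrend_fit = det$fit, rejection = rej)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in their canonical order — simulate (or load) ->
#' artifact rejection -> detrend of the Probe/Irrelevant pair -> baseline
#' correction -> contrast-orthogonal window placement -> per-participant
#' randomisation tests -> group paired t-tests -> time-frequency analysis
#' in both bands -> behavioral measures — and collects every result table
#' into a `run_report`. Deterministic given the configuration's seeds.
#'
#' @param config a [run_config()].
#' @return a `run_report`: data.frames `participant_time`, `group_time`,
#'   `participant_tf`, `group_tf`, `rejection`, `behavior`, `counts`, plus
#'   the detrend fits, the configuration echo and package version. Written
#'   as TSV/JSON to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (!is.null(config$data_dir)) {
    dirs <- sort(list.dirs(config$data_dir, recursive = FALSE))
    if (!length(dirs))
      stop("data error: no participant directories in ", config$data_dir,
           call. = FALSE)
    lapply(dirs, read_participant_data)
  } else {
    lapply(simulate_cohort(config$params),
           function(pd) inject_blinks(pd, config$params))
  }
  n_part <- length(cohort)
  proc <- lapply(cohort, preprocess_participant, config = config)

  rejection <- do.call(rbind, lapply(seq_len(n_part), function(i) {
    do.call(rbind, lapply(proc[[i]]$rejection, function(r)
      data.frame(participant = i, condition = r$condition,
                 n_total = r$n_total, n_kept = r$n_kept,
                 n_rejected = r$n_rejected)))
  }))
  rownames(rejection) <- NULL

  # ---- time domain ----
  agat <- aggregate_grand_average(proc)
  group_time <- NULL
  participant_time <- NULL
  for (ch in config$channels) {
    for (k in seq_along(config$components)) {
      comp <- names(config$components)[k]
      pol <- config$components[[k]]
      gw <- find_extreme_window(agat, ch, pol, config$search_bounds_ms,
                                source = "AGAT")
      pv <- vapply(proc, function(pp)
        mean_amplitude(pp$probe, gw, ch), 0)
      iv <- vapply(proc, function(pp)
        mean_amplitude(pp$irrelevant, gw, ch), 0)
      gt <- group_paired_ttest(pv, iv)
      group_time <- rbind(group_time, data.frame(
        channel = ch, component = comp, window_start_ms = gw$start_ms,
        window_end_ms = gw$end_ms, mean_probe = gt$mean_probe,
        sd_probe = gt$sd_probe, mean_irrelevant = gt$mean_irrelevant,
        sd_irrelevant = gt$sd_irrelevant, mean_diff = gt$mean_diff,
        sd_diff = gt$sd_diff, t = gt$t, df = gt$df, p = gt$p, d = gt$d))
    }
  }
  for (i in seq_len(n_part)) {
    pp <- proc[[i]]
    aerpt <- aggregate_erp(pp$probe, pp$irrelevant)
    for (ci in seq_along(config$channels)) {
      ch <- config$channels[ci]
      windows <- lapply(seq_along(config$components), function(k)
        find_extreme_window(aerpt, ch, config$components[[k]],
                            config$search_bounds_ms, source = "aERPt"))
      names(windows) <- names(config$components)
      seed_i <- derive_seed(config$seed, i, salt = 100 + ci)
      res <- if (config$run_participant_tests)
        randomisation_test(pp$probe, pp$irrelevant, windows, ch,
                           n_iter = config$n_iter_time, seed = seed_i,
                           polarities = config$components)
      for (comp in names(config$components)) {
        w <- windows[[comp]]
        participant_time <- rbind(participant_time, data.frame(
          participant = i, channel = ch, component = comp,
          window_start_ms = w$start_ms, window_end_ms = w$end_ms,
          mean_probe = mean_amplitude(pp$probe, w, ch),
          mean_irrelevant = mean_amplitude(pp$irrelevant, w, ch),
          observed_diff = observed_difference(pp$probe, pp$irrelevant, w, ch),
          p = if (config$run_participant_tests) res[[comp]]$p else NA_real_,
          n_iter = if (config$run_participant_tests)
            config$n_iter_time else NA_integer_,
          m = min(n_trials(pp$probe), n_trials(pp$irrelevant)),
          seed = seed_i))
      }
    }
  }

  # ---- time frequency ----
  participant_tf <- NULL
  group_tf <- NULL
  if (config$run_tf) {
    bands <- list(narrow = narrow_band(), full = full_band())
    n_iter_band <- c(narrow = config$n_iter_tf_narrow,
                     full = config$n_iter_tf_full)
    maps <- vector("list", n_part)     # per-participant condition measures
    agg_power <- 0; agg_phasor <- 0; agg_n <- 0
    decomp_meta <- NULL
    for (i in seq_len(n_part)) {
      pp <- proc[[i]]
      dp <- tf_decompose(pp$probe_tf, config$tf_channel, config$tf_freqs)
      di <- tf_decompose(pp$irrelevant_tf, config$tf_channel, config$tf_freqs)
      pooled <- combine_decompositions(dp, di)
      decomp_meta <- pooled
      agg_power <- agg_power + colSums(Mod(pooled$coef)^2)
      mag <- Mod(pooled$coef); zero <- mag == 0; mag[zero] <- 1
      U <- pooled$coef / mag; U[zero] <- 0 + 0i
      agg_phasor <- agg_phasor + colSums(U)
      agg_n <- agg_n + nrow(pooled$coef)
      maps[[i]] <- list(
        ersp = list(probe = ersp(dp), irrelevant = ersp(di),
                    pooled = ersp(pooled)),
        itc = list(probe = itc(dp), irrelevant = itc(di),
                   pooled = itc(pooled)))
      for (bn in names(bands)) {
        band <- bands[[bn]]
        for (measure in c("ERSP", "ITC")) {
          mkey <- tolower(measure)
          w <- tf_map_window(maps[[i]][[mkey]]$pooled, band,
                             bounds_ms = config$search_bounds_ms,
                             source = "aERPt")
          ps <- positive_sum_statistic(maps[[i]][[mkey]]$probe, w, band)
          is_ <- positive_sum_statistic(maps[[i]][[mkey]]$irrelevant, w, band)
          seed_tf <- derive_seed(config$seed, i,
                                 salt = 500 + 10 * match(bn, names(bands)) +
                                   match(measure, c("ERSP", "ITC")))
          p <- NA_real_
          if (config$run_participant_tests) {
            tt <- tf_permutation_test(channel = config$tf_channel,
                                      band = band, measure = measure,
                                      window = w,
                                      n_iter = n_iter_band[[bn]],
                                      seed = seed_tf, decomp_probe = dp,
                                      decomp_irrelevant = di)
            p <- tt$p
          }
          participant_tf <- rbind(participant_tf, data.frame(
            participant = i, channel = config$tf_channel, band = bn,
            measure = measure, window_start_ms = w$start_ms,
            window_end_ms = w$end_ms, probe_sum = ps,
            irrelevant_sum = is_, contrast = ps - is_, p = p,
            n_iter = if (config$run_participant_tests)
              n_iter_band[[bn]] else NA_integer_,
            seed = seed_tf))
        }
      }
    }
    # AGAT maps from the pooled accumulators
    agat_power <- tf_grid_matrix(agg_power / agg_n, decomp_meta)
    bidx <- which(decomp_meta$times_ms >= decomp_meta$baseline_ms[1] - 1e-6 &
                  decomp_meta$times_ms <= decomp_meta$baseline_ms[2] + 1e-6)
    pb <- rowMeans(agat_power[, bidx, drop = FALSE])
    agat_maps <- list(
      ersp = structure(list(values = 10 * log10(agat_power / pb),
                            freqs = decomp_meta$freqs,
                            times_ms = decomp_meta$times_ms,
                            kind = "ERSP_dB", condition = "AGAT",
                            channel = config$tf_channel), class = "tf_map"),
      itc = structure(list(values = tf_grid_matrix(Mod(agg_phasor / agg_n),
                                                   decomp_meta),
                           freqs = decomp_meta$freqs,
                           times_ms = decomp_meta$times_ms,
                           kind = "ITC", condition = "AGAT",
                           channel = config$tf_channel), class = "tf_map"))
    for (bn in names(bands)) {
      band <- bands[[bn]]
      for (measure in c("ERSP", "ITC")) {
        mkey <- tolower(measure)
        gw <- tf_map_window(agat_maps[[mkey]], band,
                            bounds_ms = config$search_bounds_ms,
                            source = "AGAT")
        pv <- vapply(maps, function(mm)
          positive_sum_statistic(mm[[mkey]]$probe, gw, band), 0)
        iv <- vapply(maps, function(mm)
          positive_sum_statistic(mm[[mkey]]$irrelevant, gw, band), 0)
        gt <- group_tf_test(pv, iv)
        group_tf <- rbind(group_tf, data.frame(
          channel = config$tf_channel, band = bn, measure = measure,
          window_start_ms = gw$start_ms, window_end_ms = gw$end_ms,
          mean_probe = gt$mean_probe, sd_probe = gt$sd_probe,
          mean_irrelevant = gt$mean_irrelevant,
          sd_irrelevant = gt$sd_irrelevant, mean_diff = gt$mean_diff,
          sd_diff = gt$sd_diff, t = gt$t, df = gt$df, p = gt$p, d = gt$d))
      }
    }
  }

  # ---- behavior ----
  behavior <- do.call(rbind, lapply(seq_len(n_part), function(i) {
    b <- cohort[[i]]$behavior
    dc <- count_detections(b$trials)
    probe_seen <- mean(b$ratings$seen_rating[b$ratings$class == "probe_present"])
    irr_seen <- mean(b$ratings$seen_rating[b$ratings$class == "irrelevant_present"])
    data.frame(participant = i, hits = dc$hits, misses = dc$misses,
               false_alarms = dc$false_alarms,
               correct_rejections = dc$correct_rejections,
               dprime = suppressMessages(as.numeric(dprime(dc))),
               probe_seen_rating = probe_seen,
               irrelevant_seen_rating = irr_seen)
  }))
  rating_test <- tryCatch(
    paired_rating_test(behavior$probe_seen_rating,
                       behavior$irrelevant_seen_rating),
    error = function(e) NULL)

  counts_input <- NULL
  if (!is.null(participant_time) && config$run_participant_tests)
    counts_input <- rbind(counts_input, data.frame(
      analysis = paste0("time_", participant_time$channel, "_",
                        participant_time$component),
      p = participant_time$p))
  if (!is.null(participant_tf) && config$run_participant_tests)
    counts_input <- rbind(counts_input, data.frame(
      analysis = paste0("tf_", participant_tf$band, "_",
                        participant_tf$measure),
      p = participant_tf$p))
  counts <- if (!is.null(counts_input))
    summarise_counts(counts_input, config$alpha)

  report <- structure(
    list(participant_time = participant_time, group_time = group_time,
         participant_tf = participant_tf, group_tf = group_tf,
         rejection = rejection, behavior = behavior,
         rating_test = rating_test, counts = counts,
         detrend_fit = lapply(proc, `[[`, "detrend_fit"),
         config = config,
         version = as.character(utils::packageVersion("fringep3"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Write a run report as TSV tables plus a JSON summary
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("participant_time", "group_time", "participant_tf",
              "group_tf", "rejection", "behavior", "counts")
  for (tb in tables)
    if (!is.null(report[[tb]]))
      write.table(report[[tb]], file.path(dir, paste0(tb, ".tsv")),
                  sep = "\t", row.names = FALSE)
  cfg <- report$config
  summary <- list(
    version = report$version,
    n_participants = length(report$detrend_fit),
    alpha = cfg$alpha, seed = cfg$seed,
    channels = cfg$channels, tf_channel = cfg$tf_channel,
    search_bounds_ms = cfg$search_bounds_ms,
    n_iter = list(time = cfg$n_iter_time,
                  tf_narrow = cfg$n_iter_tf_narrow,
                  tf_full = cfg$n_iter_tf_full),
    thresholds = list(eog_uv = cfg$eog_limit_uv, eeg_uv = cfg$eeg_limit_uv),
    counts = report$counts)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d participants (fringep3 %s)\n",
              length(x$detrend_fit), x$version))
  if (!is.null(x$group_time)) {
    cat("group time-domain results:\n")
    print(x$group_time[, c("channel", "component", "window_start_ms",
                           "window_end_ms", "t", "p", "d")],
          row.names = FALSE, digits = 4)
  }
  if (!is.null(x$group_tf)) {
    cat("group time-frequency results:\n")
    print(x$group_tf[, c("band", "measure", "window_start_ms",
                         "window_end_ms", "t", "p", "d")],
          row.names = FALSE, digits = 4)
  }
  if (!is.null(x$counts)) {
    cat("significant participants per analysis:\n")
    print(x$counts, row.names = FALSE)
  }
  invisible(x)
}
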