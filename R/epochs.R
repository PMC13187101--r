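#' Epoched EEG container
#'
#' An `epoch_set` holds one condition's epoched trials as a numeric array of
#' dimension trials x channels x time (microvolts), together with its time
#' axis in milliseconds, sampling rate and condition label. The time axis is
#' a half-open sample grid `[start, end)` with time 0 at the sample marking
#' critical-stimulus onset.
#'
#' @param data numeric array, trials x channels x time, in microvolts.
#' @param time_ms numeric vector of sample times in milliseconds, strictly
#'   increasing, containing 0.
#' @param rate_hz sampling rate in Hz.
#' @param condition condition label, e.g. `"Probe"`, `"Irrelevant"`,
#'   `"Target"`.
#' @param channels channel labels for the second array dimension; defaults to
#'   `dimnames(data)[[2]]`.
#' @param trial_ids unique identifiers for the first dimension; defaults to
#'   `1:n_trials`.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, rate_hz, condition,
                      channels = dimnames(data)[[2]],
                      trial_ids = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a trials x channels x time array", call. = FALSE)
  if (length(time_ms) != dim(data)[3])
    stop("`time_ms` length must match the time dimension of `data`",
         call. = FALSE)
  if (any(diff(time_ms) <= 0))
    stop("`time_ms` must be strictly increasing", call. = FALSE)
  if (min(abs(time_ms)) > 1e-9)
    stop("`time_ms` must contain the 0 ms sample", call. = FALSE)
  if (!is.numeric(rate_hz) || rate_hz <= 0)
    stop("`rate_hz` must be a positive number", call. = FALSE)
  if (is.null(channels))
    channels <- paste0("ch", seq_len(dim(data)[2]))
  if (length(channels) != dim(data)[2])
    stop("`channels` length must match the channel dimension", call. = FALSE)
  if (is.null(trial_ids)) trial_ids <- seq_len(dim(data)[1])
  if (anyDuplicated(trial_ids))
    stop("`trial_ids` must be unique", call. = FALSE)
  dimnames(data) <- list(NULL, channels, NULL)
  structure(
    list(data = data, time_ms = as.numeric(time_ms), rate_hz = rate_hz,
         condition = condition, channels = channels, trial_ids = trial_ids),
    class = "epoch_set")
}

#' Number of trials in an epoch set
#' @param x an `epoch_set`.
#' @return integer trial count.
#' @export
n_trials <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  dim(x$data)[1]
}

#' Subset trials of an epoch set
#' @param x an `epoch_set`.
#' @param i trial indices to keep.
#' @return an `epoch_set` with the selected trials.
#' @export
subset_trials <- function(x, i) {
  stopifnot(inherits(x, "epoch_set"))
  epoch_set(x$data[i, , , drop = FALSE], x$time_ms, x$rate_hz, x$condition,
            x$channels, x$trial_ids[i])
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$condition, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$rate_hz))
  cat(sprintf("  time %.1f..%.1f ms; channels: %s\n",
              min(x$time_ms), max(x$time_ms),
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Build the epoch time axis used throughout the package
#'
#' Samples run from `round(start_ms * rate / 1000)` (inclusive) to
#' `round(end_ms * rate / 1000)` (exclusive), so 0 ms is always on the grid
#' and the epoch is half-open `[start, end)`.
#'
#' @param rate_hz sampling rate in Hz.
#' @param window_ms length-2 numeric, epoch start and end in ms (start < 0 <
#'   end).
#' @return numeric vector of sample times in ms.
#' @export
epoch_time_axis <- function(rate_hz, window_ms = c(-200, 1200)) {
  n_pre <- round(-window_ms[1] * rate_hz / 1000)
  n_post <- round(window_ms[2] * rate_hz / 1000)
  seq.int(-n_pre, n_post - 1L) * 1000 / rate_hz
}

#' Index of the samples covering a time interval
#'
#' Half-open convention: samples with `from <= t < to` (a small numerical
#' slack of 1e-6 ms absorbs floating-point representation of the grid).
#'
#' @param time_ms time axis.
#' @param from,to interval bounds in ms.
#' @return integer sample indices.
#' @keywords internal
time_index <- function(time_ms, from, to) {
  which(time_ms >= from - 1e-6 & time_ms < to - 1e-6)
}

#' Write an epoch set to a plain-text container
#'
#' One TSV per condition: a header of metadata lines (prefixed `#`) followed
#' by a matrix with one row per (trial, channel) and one column per sample.
#' This is the package's on-disk epoch container.
#'
#' @param x an `epoch_set`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_epoch_set <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# condition\t%s", x$condition),
    sprintf("# rate_hz\t%.10g", x$rate_hz),
    sprintf("# channels\t%s", paste(x$channels, collapse = ",")),
    sprintf("# trial_ids\t%s", paste(x$trial_ids, collapse = ",")),
    sprintf("# time_ms\t%s", paste(sprintf("%.10g", x$time_ms),
                                   collapse = ","))), con)
  m <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  write.table(m, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an epoch set written by [write_epoch_set()]
#' @param path file path.
#' @return an `epoch_set`.
#' @export
read_epoch_set <- function(path) {
  hdr <- readLines(path, n = 5L)
  if (!all(startsWith(hdr, "# ")))
    stop("not an epoch-set container: ", path, call. = FALSE)
  fields <- strsplit(sub("^# ", "", hdr), "\t", fixed = TRUE)
  meta <- stats::setNames(lapply(fields, `[`, 2), vapply(fields, `[`, "", 1))
  channels <- strsplit(meta$channels, ",", fixed = TRUE)[[1]]
  trial_ids <- strsplit(meta$trial_ids, ",", fixed = TRUE)[[1]]
  time_ms <- as.numeric(strsplit(meta$time_ms, ",", fixed = TRUE)[[1]])
  m <- as.matrix(read.table(path, sep = "\t", skip = 5L))
  n_tr <- length(trial_ids); n_ch <- length(channels); n_t <- length(time_ms)
  a <- aperm(array(t(m), dim = c(n_t, n_ch, n_tr)), c(3, 2, 1))
  ids <- suppressWarnings(as.integer(trial_ids))
  if (anyNA(ids)) ids <- trial_ids
  epoch_set(a, time_ms, as.numeric(meta$rate_hz), meta$condition, channels,
            ids)
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded operations do not disturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Counter scheme: `(seed + 104729 * index + salt) mod (2^31 - 1)`, kept
#' strictly positive. Used to give every participant (and every stochastic
#' stage) its own stream while remaining a pure function of the master seed.
#'
#' @param seed master integer seed.
#' @param index counter (participant number, replicate number, ...).
#' @param salt stage offset so different stages at the same index decouple.
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, index, salt = 0) {
  s <- (as.double(seed) + 104729 * as.double(index) + as.double(salt)) %%
    (2^31 - 1)
  as.integer(s + 1)
}
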