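#' Signal-detection counts for the Target task
#'
#' @param hits,misses target-present trials answered yes / no.
#' @param false_alarms,correct_rejections target-absent trials answered
#'   yes / no.
#' @return object of class `detection_counts`.
#' @export
detection_counts <- function(hits, misses, false_alarms,
                             correct_rejections) {
  counts <- c(hits = hits, misses = misses, false_alarms = false_alarms,
              correct_rejections = correct_rejections)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(as.list(counts), class = "detection_counts")
}

#' Tally detection counts from a behavioral trial table
#' @param trials data.frame with logical `target_present` and
#'   `response_yes` columns (as produced by [simulate_behavior()]).
#' @return a [detection_counts()].
#' @export
count_detections <- function(trials) {
  detection_counts(
    hits = sum(trials$target_present & trials$response_yes),
    misses = sum(trials$target_present & !trials$response_yes),
    false_alarms = sum(!trials$target_present & trials$response_yes),
    correct_rejections = sum(!trials$target_present & !trials$response_yes))
}

#' Signal-detection discriminability d'
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with `z` the standard-normal
#' quantile. Extreme rates (0 or 1) are adjusted by the 1/(2N) rule
#' (`0 -> 1/(2N)`, `1 -> 1 - 1/(2N)`, N the trial count of that type)
#' before the transform; when that happens a message notes the adjustment.
#'
#' @param counts a [detection_counts()] with both trial types present.
#' @return d' (numeric), with the adjusted hit/false-alarm rates attached
#'   as attributes `hit_rate` and `fa_rate`.
#' @export
dprime <- function(counts) {
  stopifnot(inherits(counts, "detection_counts"))
  n_present <- counts$hits + counts$misses
  n_absent <- counts$false_alarms + counts$correct_rejections
  if (n_present == 0 || n_absent == 0)
    stop("insufficient data: both target-present and target-absent trials are required",
         call. = FALSE)
  adjust <- function(rate, n, what) {
    if (rate == 0 || rate == 1) {
      message(sprintf("%s rate of %g adjusted by the 1/(2N) rule (N = %d)",
                      what, rate, n))
      rate <- min(max(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
    }
    rate
  }
  hr <- adjust(counts$hits / n_present, n_present, "hit")
  far <- adjust(counts$false_alarms / n_absent, n_absent, "false-alarm")
  out <- stats::qnorm(hr) - stats::qnorm(far)
  attr(out, "hit_rate") <- hr
  attr(out, "fa_rate") <- far
  out
}

#' Map a 1--5 confidence rating to percent of scale
#'
#' Linear map with 1 ("Never") at 0% and 5 ("A lot") at 100%:
#' `(rating - 1) / 4 * 100`. Accepts non-integer values (means of ratings)
#' within the same range.
#'
#' @param rating numeric in \[1, 5\].
#' @return percent of scale.
#' @export
rating_to_percent <- function(rating) {
  if (any(rating < 1 | rating > 5))
    stop("ratings must lie in [1, 5]", call. = FALSE)
  (rating - 1) / 4 * 100
}

#' Paired comparison of Probe vs Irrelevant recognition ratings
#'
#' The group test of end-of-experiment recognition: per-participant mean
#' seen-ratings of the Probes that were presented versus the Irrelevants
#' that were presented, through the same machinery as
#' [group_paired_ttest()]. The t statistic is invariant to the affine
#' rating-to-percent map, so raw 1--5 ratings are used.
#'
#' @param probe_ratings,irrelevant_ratings per-participant mean ratings,
#'   paired.
#' @return a `group_test_result`.
#' @export
paired_rating_test <- function(probe_ratings, irrelevant_ratings) {
  group_paired_ttest(probe_ratings, irrelevant_ratings)
}

#' Holm step-down adjustment of p-values
#'
#' Standard step-down Holm correction (monotone, capped at 1), delegated to
#' [stats::p.adjust()]. Offered as a utility for families of group tests;
#' no claim is made that any published correction used exactly this
#' procedure.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order.
#' @export
holm_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "holm")
}
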