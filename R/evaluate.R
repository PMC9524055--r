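# Surveillance-evaluation statistics: geolocation confusion metrics, general
# and specific PPV, inter-rater agreement, Wald confidence intervals,
# timeliness summaries and the one-sided Wilcoxon signed-rank test.

#' Round half-up for display
#'
#' Presentation rounding on the percentage scale (`round()` in R rounds half
#' to even, which is not how surveillance reports print percentages).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return `x` rounded half away from zero at `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

pct_or_na <- function(num, den) {
  if (is.na(den) || den <= 0) NA_real_ else 100 * num / den
}

#' Confusion-count metrics
#'
#' Standard test-performance metrics from (possibly fractional)
#' true/false-positive/negative counts. Fractional counts arise when results
#' from several raters are averaged. A zero denominator yields `NA`, never an
#' error.
#'
#' @param tp,fp,tn,fn Non-negative (possibly fractional) counts; their sum
#'   must be positive.
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv` (`tn / (tn + fn)`), `prevalence`, all percentages.
#' @export
#' @examples
#' confusion_metrics(tp = 30, fp = 10, tn = 40, fn = 20)
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || sum(counts) <= 0) {
    abort("counts must be non-negative with a positive total")
  }
  total <- tp + fp + tn + fn
  tibble(
    accuracy = pct_or_na(tp + tn, total),
    sensitivity = pct_or_na(tp, tp + fn),
    specificity = pct_or_na(tn, tn + fp),
    ppv = pct_or_na(tp, tp + fp),
    npv = pct_or_na(tn, tn + fn),
    prevalence = pct_or_na(tp + fn, total)
  )
}

#' Overall accuracy from correct-hit counts
#'
#' @param correct_hits Number of records whose predicted location matched the
#'   manually extracted one.
#' @param n Total number of records assessed.
#' @return Percentage `100 * correct_hits / n`.
#' @export
hit_accuracy <- function(correct_hits, n) {
  if (n <= 0) abort("`n` must be positive")
  100 * correct_hits / n
}

#' Geolocation accuracy and confusion metrics against manual annotation
#'
#' Each annotation row holds one rater's gold location for one tweet plus the
#' algorithm's prediction. A tweet is a positive hit for a rater when that
#' rater could extract a location at the requested level. Confusion counts
#' follow the standard assignment (TP: gold and prediction both present; FN:
#' gold present, prediction absent; FP: prediction present, gold absent; TN:
#' both absent) and are averaged across raters, so fractional counts are
#' possible. Per-tweet accuracy is 1 when the predicted location equals the
#' gold location at the requested level, averaged over raters.
#'
#' @param annotations Tibble with columns `tweet_id`, `rater`,
#'   `gold_country`, `gold_admin1`, `pred_country`, `pred_admin1` (`NA` for
#'   "no location"). One row per (tweet, rater).
#' @param level `"national"` (country codes compared) or `"subnational"`
#'   (country and admin1 compared).
#' @return A list with `accuracy` (percent), `counts` (one-row tibble of
#'   averaged `tp`, `fp`, `tn`, `fn`) and `metrics`
#'   ([confusion_metrics()] of those counts).
#' @export
geolocation_accuracy <- function(annotations, level = c("national", "subnational")) {
  level <- match.arg(level)
  need <- c("tweet_id", "rater", "gold_country", "gold_admin1", "pred_country", "pred_admin1")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) abort(paste0("missing annotation columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(annotations[, c("tweet_id", "rater")])) {
    abort("duplicate (tweet_id, rater) pair in annotations")
  }
  present <- function(x) !is.na(x) & nzchar(x)
  if (level == "national") {
    gold_p <- present(annotations$gold_country)
    pred_p <- present(annotations$pred_country)
    match_i <- gold_p & pred_p & annotations$gold_country == annotations$pred_country
  } else {
    gold_p <- present(annotations$gold_admin1)
    pred_p <- present(annotations$pred_admin1)
    match_i <- gold_p & pred_p &
      annotations$gold_country == annotations$pred_country &
      annotations$gold_admin1 == annotations$pred_admin1
  }
  per_rater <- tibble(
    rater = annotations$rater, gold_p = gold_p, pred_p = pred_p,
    match = match_i, tweet_id = annotations$tweet_id
  ) %>%
    group_by(.data$rater) %>%
    summarise(
      tp = sum(.data$gold_p & .data$pred_p),
      fn = sum(.data$gold_p & !.data$pred_p),
      fp = sum(!.data$gold_p & .data$pred_p),
      tn = sum(!.data$gold_p & !.data$pred_p),
      .groups = "drop"
    )
  counts <- tibble(
    tp = mean(per_rater$tp), fp = mean(per_rater$fp),
    tn = mean(per_rater$tn), fn = mean(per_rater$fn)
  )
  per_tweet <- tibble(tweet_id = annotations$tweet_id, match = match_i) %>%
    group_by(.data$tweet_id) %>%
    summarise(match = mean(.data$match), .groups = "drop")
  list(
    accuracy = 100 * mean(per_tweet$match),
    counts = counts,
    metrics = confusion_metrics(counts$tp, counts$fp, counts$tn, counts$fn)
  )
}

#' Specific and general positive predictive value
#'
#' The specific PPV considers only manually evaluated signals
#' (`events / (events + false_signals)`); the general PPV spreads the same
#' numerator over every emitted alert, evaluated or not. `ppv_general()` is
#' therefore never larger than `ppv_specific()`.
#'
#' @param n_events Validated events.
#' @param n_false_signals Evaluated signals discarded on review.
#' @param n_not_evaluated Alerts never evaluated.
#' @return A percentage, `NA` if the denominator is zero.
#' @export
ppv_specific <- function(n_events, n_false_signals) {
  pct_or_na(n_events, n_events + n_false_signals)
}

#' @rdname ppv_specific
#' @export
ppv_general <- function(n_events, n_false_signals, n_not_evaluated) {
  pct_or_na(n_events, n_events + n_false_signals + n_not_evaluated)
}

#' Inter-rater agreement between two detection arms
#'
#' With no gold standard of all true events, the share of jointly evaluated
#' signals picked up by one arm serves as a relative sensitivity.
#'
#' @param n_detected Signals detected by the arm (alone or jointly).
#' @param n_total Total signals evaluated across both arms.
#' @return A percentage, `NA` if `n_total` is zero.
#' @export
ira <- function(n_detected, n_total) {
  if (n_total > 0 && (n_detected < 0 || n_detected > n_total)) {
    abort("`n_detected` must lie in [0, n_total]")
  }
  pct_or_na(n_detected, n_total)
}

#' Wald confidence interval for a proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p (1 - p) / n)` on the
#' percentage scale, clipped to `[0, 100]`.
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level in `(0, 1)`.
#' @return A one-row tibble with `estimate`, `lower`, `upper` (percent).
#' @export
#' @examples
#' wald_ci(334, 448)
wald_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) abort("`n` must be positive")
  if (successes < 0 || successes > n) abort("`successes` must lie in [0, n]")
  if (level <= 0 || level >= 1) abort("`level` must lie strictly between 0 and 1")
  p <- successes / n
  z <- qnorm((1 + level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  tibble(
    estimate = 100 * p,
    lower = max(0, 100 * (p - half)),
    upper = min(100, 100 * (p + half))
  )
}

#' Deduplicate triaged alerts into unique events
#'
#' Validated events are grouped by (topic, manually assigned subtopic); for
#' each group the earliest validation time per detection arm is retained, and
#' a paired validation-time difference (automated minus manual, in hours) is
#' emitted when both arms found the event.
#'
#' @param triage Tibble with columns `alert_id`, `status` (one of
#'   `"not_evaluated"`, `"false_signal"`, `"event"`), `detected_by`
#'   (semicolon-joined subset of `"automated"`, `"manual"`),
#'   `validation_time` (POSIXct, required for events), `topic`, `subtopic`.
#' @return A tibble with one row per unique event: `topic`, `subtopic`,
#'   `n_records`, `first_automated`, `first_manual`, `diff_hours`
#'   (`NA` unless both arms detected it; negative when the automated arm was
#'   earlier).
#' @export
dedup_events <- function(triage) {
  ev <- filter(triage, .data$status == "event")
  if (nrow(ev) == 0) {
    return(tibble(
      topic = character(), subtopic = character(), n_records = integer(),
      first_automated = as.POSIXct(character(), tz = "UTC"),
      first_manual = as.POSIXct(character(), tz = "UTC"),
      diff_hours = numeric()
    ))
  }
  if (any(is.na(ev$subtopic) | !nzchar(ev$subtopic))) {
    abort("every event must carry a subtopic for deduplication")
  }
  if (any(is.na(ev$validation_time))) {
    abort("every event must carry a validation_time")
  }
  arm_time <- function(times, arms, arm) {
    hit <- vapply(arms, function(a) arm %in% strsplit(a, ";", fixed = TRUE)[[1]], logical(1))
    if (any(hit)) min(times[hit]) else as.POSIXct(NA)
  }
  ev %>%
    group_by(.data$topic, .data$subtopic) %>%
    summarise(
      n_records = dplyr::n(),
      first_automated = arm_time(.data$validation_time, .data$detected_by, "automated"),
      first_manual = arm_time(.data$validation_time, .data$detected_by, "manual"),
      .groups = "drop"
    ) %>%
    mutate(diff_hours = as.numeric(difftime(.data$first_automated,
      .data$first_manual,
      units = "hours"
    )))
}

#' Timeliness summary of paired validation-time differences
#'
#' Median and quartiles (linear interpolation between order statistics) of
#' the differences in hours, automated minus manual: negative values mean the
#' automated arm validated the event earlier.
#'
#' @param diffs Numeric vector of paired differences, length `>= 1`.
#' @return A one-row tibble with `n`, `median`, `q1`, `q3`.
#' @export
timeliness <- function(diffs) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) == 0) abort("at least one paired difference is required")
  q <- quantile(diffs, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(n = length(diffs), median = q[2], q1 = q[1], q3 = q[3])
}

#' One-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped; absolute differences are ranked with
#' midranks for ties and the statistic is the sum of ranks of positive
#' differences (`W+`). For `n <= 15` without ties the exact null distribution
#' is used; otherwise a normal approximation with tie and continuity
#' correction.
#'
#' @param diffs Numeric differences; at least one nonzero value.
#' @param alternative `"less"` (the distribution of differences is shifted
#'   below zero — the automated arm earlier), `"greater"`, or `"two.sided"`.
#' @return A one-row tibble with `statistic` (`W+`), `p_value`, `n` (nonzero
#'   differences used) and `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(-5, -4, -3, -2, -1))
wilcoxon_signed_rank <- function(diffs, alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- diffs[!is.na(diffs) & diffs != 0]
  n <- length(d)
  if (n == 0) abort("all differences are zero; the test is undefined")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= 15L) {
    p_less <- psignrank(w, n)
    p_greater <- 1 - if (w >= 1) psignrank(w - 1, n) else 0
    method <- "exact"
  } else {
    e <- n * (n + 1) / 4
    tie_tab <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    p_less <- pnorm((w - e + 0.5) / sqrt(v))
    p_greater <- 1 - pnorm((w - e - 0.5) / sqrt(v))
    method <- "normal"
  }
  p <- switch(alternative,
    less = p_less,
    greater = p_greater,
    two.sided = min(1, 2 * min(p_less, p_greater))
  )
  tibble(statistic = w, p_value = p, n = n, method = method)
}
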