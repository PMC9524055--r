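# Modified EARS detector: prediction-interval threshold over a trailing
# baseline with optional Farrington-style downweighting of outlying baseline
# values, plus alert-record generation.

DOWNWEIGHT_C <- c(low = 3, medium = 2, high = 1.5)

#' Signal-detection configuration
#'
#' @param alpha Nominal false-positive rate in `(0, 1)`; the alert confidence
#'   is `1 - alpha` and sets the predictive-distribution quantile used as
#'   threshold.
#' @param baseline_days Length of the trailing baseline window in days
#'   (`>= 2`, default 7).
#' @param downweight_strength One of `"none"`, `"low"`, `"medium"`, `"high"`:
#'   how aggressively outlying baseline values are downweighted (residual
#'   cut-offs 3, 2 and 1.5 standard deviations).
#' @param same_weekday_only If `TRUE`, the baseline uses the same weekday in
#'   previous weeks instead of consecutive days.
#' @param include_retweets If `TRUE`, detection runs on `count_total` rather
#'   than `count_original`.
#' @param k_top_words Number of top words attached to each alert.
#' @return An object of class `signal_config`.
#' @export
signal_config <- function(alpha = 0.025, baseline_days = 7L,
                          downweight_strength = c("none", "low", "medium", "high"),
                          same_weekday_only = FALSE, include_retweets = FALSE,
                          k_top_words = 20L) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1")
  }
  baseline_days <- as.integer(baseline_days)
  if (is.na(baseline_days) || baseline_days < 2L) {
    abort("`baseline_days` must be an integer >= 2")
  }
  downweight_strength <- match.arg(downweight_strength)
  structure(
    list(
      alpha = alpha, baseline_days = baseline_days,
      downweight_strength = downweight_strength,
      same_weekday_only = isTRUE(same_weekday_only),
      include_retweets = isTRUE(include_retweets),
      k_top_words = as.integer(k_top_words)
    ),
    class = "signal_config"
  )
}

#' Downweight outlying baseline values
#'
#' Flags baseline counts whose standardised residual against the unweighted
#' mean exceeds the strength's cut-off `c` (3, 2, 1.5 for low/medium/high;
#' one-sided, high outliers only, so that a past spike cannot inflate the
#' threshold and mask a new one) and assigns them weight `(c / r)^2`; all
#' other values keep weight 1. A zero-variance baseline is left untouched.
#'
#' @param values Numeric baseline counts, length `>= 2`.
#' @param strength One of `"none"`, `"low"`, `"medium"`, `"high"`.
#' @return Numeric weights in `(0, 1]`, aligned with `values`.
#' @export
downweight_baseline <- function(values, strength = c("none", "low", "medium", "high")) {
  strength <- match.arg(strength)
  if (length(values) < 2L) abort("at least 2 baseline values are required")
  w <- rep(1, length(values))
  if (strength == "none") {
    return(w)
  }
  mu <- mean(values)
  sd0 <- stats::sd(values)
  if (!is.finite(sd0) || sd0 == 0) {
    return(w)
  }
  cc <- DOWNWEIGHT_C[[strength]]
  r <- (values - mu) / sd0
  flag <- r > cc
  w[flag] <- (cc / r[flag])^2
  w
}

#' Prediction-interval threshold for a baseline (modified EARS)
#'
#' The expected count is the weighted baseline mean and the threshold the
#' upper `1 - alpha` bound of a Student-t predictive distribution:
#' `mu_w + t(1 - alpha, N - 1) * sd_w * sqrt(1 + 1/N)`, where `sd_w` is the
#' frequency-weighted sample standard deviation (denominator
#' `sum(w) - 1` when `sum(w) > 1`, else 0).
#'
#' @param values Numeric baseline counts, length `N >= 2`.
#' @param weights Weights aligned with `values`, e.g. from
#'   [downweight_baseline()].
#' @param alpha Nominal false-positive rate in `(0, 1)`.
#' @return A list with elements `expected` and `threshold`
#'   (`threshold >= expected`).
#' @export
#' @examples
#' ears_threshold(c(3, 1, 4, 1, 5, 9, 2), alpha = 0.025)
ears_threshold <- function(values, weights = rep(1, length(values)), alpha = 0.025) {
  n <- length(values)
  if (n < 2L) abort("at least 2 baseline values are required")
  if (length(weights) != n) abort("`weights` must align with `values`")
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1")
  }
  sw <- sum(weights)
  mu <- sum(weights * values) / sw
  var_w <- if (sw > 1) sum(weights * (values - mu)^2) / (sw - 1) else 0
  thr <- mu + qt(1 - alpha, df = n - 1) * sqrt(var_w) * sqrt(1 + 1 / n)
  list(expected = mu, threshold = max(thr, mu))
}

#' Detect signals across all count series
#'
#' For every topic-by-region series in `counts` with at least
#' `config$baseline_days` days of history strictly before the `as_of` date,
#' the trailing baseline (consecutive days, or the same weekday in previous
#' weeks when `same_weekday_only`) is downweighted and passed to
#' [ears_threshold()]; a signal is emitted when the observed count on the
#' `as_of` date strictly exceeds the threshold.
#'
#' @param counts A `tweet_counts` tibble from [aggregate_counts()].
#' @param config A [signal_config()].
#' @param as_of Detection run time (`POSIXct`, or a `Date`, in which case
#'   `hour` is taken as 0).
#' @return A tibble of class `tweet_signals`: one row per emitted signal with
#'   `topic`, `region`, `date`, `hour`, `observed`, `expected`, `threshold`
#'   and the configuration snapshot columns `alpha`, `baseline_days`,
#'   `downweight_strength`.
#' @export
detect_signals <- function(counts, config = signal_config(), as_of) {
  stopifnot(inherits(config, "signal_config"))
  if (inherits(as_of, "Date")) {
    as_of_date <- as_of
    as_of_hour <- 0L
  } else {
    as_of <- lubridate::with_tz(as_of, "UTC")
    as_of_date <- lubridate::as_date(as_of)
    as_of_hour <- lubridate::hour(as_of)
  }
  value_col <- if (config$include_retweets) "count_total" else "count_original"
  baseline_dates <- if (config$same_weekday_only) {
    as_of_date - 7L * seq_len(config$baseline_days)
  } else {
    as_of_date - seq_len(config$baseline_days)
  }
  sig <- counts %>%
    group_by(.data$topic, .data$region) %>%
    dplyr::group_modify(function(df, key) {
      have <- baseline_dates %in% df$date
      if (!all(have)) {
        abort(sprintf(
          "series %s/%s lacks the %d baseline day(s) before %s",
          key$topic, key$region, config$baseline_days, format(as_of_date)
        ))
      }
      baseline <- df[[value_col]][match(baseline_dates, df$date)]
      observed <- df[[value_col]][match(as_of_date, df$date)]
      observed <- if (is.na(observed)) 0 else observed
      w <- downweight_baseline(baseline, config$downweight_strength)
      th <- ears_threshold(baseline, w, config$alpha)
      if (observed > th$threshold) {
        tibble(
          date = as_of_date, hour = as_of_hour, observed = observed,
          expected = th$expected, threshold = th$threshold
        )
      } else {
        tibble(
          date = as.Date(character()), hour = integer(),
          observed = numeric(), expected = numeric(), threshold = numeric()
        )
      }
    }) %>%
    ungroup() %>%
    mutate(
      alpha = config$alpha, baseline_days = config$baseline_days,
      downweight_strength = config$downweight_strength
    )
  structure(sig, class = c("tweet_signals", class(sig)))
}

#' Build alert records for detected signals
#'
#' Joins each signal with the original (non-retweet, non-quote) records of
#' its topic, region and date, and derives the alert fields: top words,
#' tweet count, percentage of tweets from trusted users, and the
#' configuration snapshot.
#'
#' @param signals A `tweet_signals` tibble from [detect_signals()].
#' @param tweets The geolocated tweet tibble the counts were aggregated from.
#' @param config The [signal_config()] used for detection.
#' @param region_map Country-to-continent lookup (bundled default).
#' @param stop_list Stop words removed from top-word summaries.
#' @return A tibble of class `tweet_alerts` with columns `date`, `hour`,
#'   `topic`, `region`, `top_words` (list-column of [top_words()] tibbles),
#'   `top_words_str` (semicolon-joined), `tweet_count`, `trusted_pct`,
#'   `alpha`, `baseline_days`, `downweight_strength`.
#' @export
build_alerts <- function(signals, tweets, config = signal_config(),
                         region_map = country_regions(),
                         stop_list = stop_words()) {
  resolved <- coalesce(
    tweets$geo_country %||% rep(NA_character_, nrow(tweets)),
    tweets$user_country %||% rep(NA_character_, nrow(tweets))
  )
  pos <- match(resolved, region_map$country)
  membership <- function(region) {
    if (region == "WORLD") rep(TRUE, nrow(tweets))
    else if (region %in% region_map$country) !is.na(resolved) & resolved == region
    else {
      (!is.na(pos) & region_map$continent[pos] == region) |
        (!is.na(pos) & !is.na(region_map$super_region[pos]) &
           region_map$super_region[pos] == region)
    }
  }
  tweet_date <- lubridate::as_date(lubridate::with_tz(tweets$created_at, "UTC"))
  rows <- purrr::map_dfr(seq_len(nrow(signals)), function(i) {
    s <- signals[i, ]
    in_cell <- membership(s$region) & tweets$topic == s$topic & tweet_date == s$date
    originals <- tweets[in_cell & !(tweets$is_retweet | tweets$is_quote), ]
    counted <- if (config$include_retweets) sum(in_cell) else nrow(originals)
    if (counted != s$observed) {
      abort(sprintf(
        "records for %s/%s on %s are inconsistent with the signal count (%d vs %g)",
        s$topic, s$region, format(s$date), counted, s$observed
      ))
    }
    tw <- top_words(originals$text, k = config$k_top_words, stop_list = stop_list)
    tibble(
      date = s$date, hour = s$hour, topic = s$topic, region = s$region,
      top_words = list(tw),
      top_words_str = paste(tw$word, collapse = ";"),
      tweet_count = s$observed,
      trusted_pct = if (nrow(originals) == 0) 0 else 100 * sum(originals$trusted) / nrow(originals),
      alpha = s$alpha, baseline_days = s$baseline_days,
      downweight_strength = s$downweight_strength
    )
  })
  if (nrow(signals) == 0) {
    rows <- tibble(
      date = as.Date(character()), hour = integer(), topic = character(),
      region = character(), top_words = list(), top_words_str = character(),
      tweet_count = numeric(), trusted_pct = numeric(), alpha = numeric(),
      baseline_days = integer(), downweight_strength = character()
    )
  }
  structure(rows, class = c("tweet_alerts", class(rows)))
}

#' Write alerts to CSV and JSON Lines
#'
#' Flat columns only (`top_words` joined with `";"`); no e-mail dispatch —
#' alert files are the delivery mechanism.
#'
#' @param alerts A `tweet_alerts` tibble.
#' @param csv_path,jsonl_path Output paths; either may be `NULL` to skip.
#' @return Invisible character vector of the paths written.
#' @export
write_alerts <- function(alerts, csv_path = NULL, jsonl_path = NULL) {
  flat <- alerts %>%
    select(-"top_words") %>%
    rename(top_words = "top_words_str")
  written <- character(0)
  if (!is.null(csv_path)) {
    readr::write_csv(flat, csv_path, progress = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(jsonl_path)) {
    lines <- vapply(seq_len(nrow(flat)), function(i) {
      rec <- as.list(flat[i, ])
      rec$date <- format(rec$date)
      jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null")
    }, character(1))
    writeLines(lines, jsonl_path, useBytes = TRUE)
    written <- c(written, jsonl_path)
  }
  invisible(written)
}
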