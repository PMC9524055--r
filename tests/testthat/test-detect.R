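# The modified EARS detector and alert generation.

test_that("downweighting leaves clean baselines untouched", {
  expect_identical(downweight_baseline(rep(5, 7), "high"), rep(1, 7))
  expect_identical(downweight_baseline(c(5, 5, 5, 5, 5, 5, 50), "none"), rep(1, 7))
  expect_error(downweight_baseline(5, "low"), "2 baseline")
})

test_that("downweighting shrinks high outliers by the inverse-square rule", {
  y <- c(5, 5, 5, 5, 5, 5, 50)
  w <- downweight_baseline(y, "high")
  # hand computation: r = (50 - mean) / sd, weight = (1.5 / r)^2
  r <- (50 - mean(y)) / stats::sd(y)
  expect_equal(w, c(rep(1, 6), (1.5 / r)^2), tolerance = 1e-12)
  expect_lt(w[7], 1)
  mu_w <- sum(w * y) / sum(w)
  expect_lt(mu_w, mean(y))
  # only high outliers are flagged: a low outlier keeps weight 1
  w_low <- downweight_baseline(c(50, 50, 50, 50, 50, 50, 5), "high")
  expect_identical(w_low, rep(1, 7))
  # strengths are ordered: stronger settings downweight at least as hard
  y2 <- c(4, 5, 3, 5, 4, 5, 30)
  w_l <- downweight_baseline(y2, "low")
  w_m <- downweight_baseline(y2, "medium")
  w_h <- downweight_baseline(y2, "high")
  expect_true(all(w_m <= w_l) && all(w_h <= w_m))
})

test_that("the threshold matches an independent prediction-bound computation", {
  y <- c(3, 1, 4, 1, 5, 9, 2)
  th <- ears_threshold(y, alpha = 0.025)
  expect_equal(th$expected, 25 / 7, tolerance = 1e-12)
  oracle <- mean(y) + stats::qt(0.975, 6) * stats::sd(y) * sqrt(1 + 1 / 7)
  expect_equal(th$threshold, oracle, tolerance = 1e-9)
  expect_equal(th$threshold, 10.94768, tolerance = 1e-4)

  flat <- ears_threshold(rep(5, 7), alpha = 0.3)
  expect_identical(flat, list(expected = 5, threshold = 5))
  expect_error(ears_threshold(3), "2 baseline")
  expect_error(ears_threshold(c(1, 2), alpha = 0), "between")
})

test_that("threshold is monotone in alpha and reduced by downweighting", {
  y <- c(2, 3, 2, 4, 3, 2, 12)
  alphas <- c(0.01, 0.025, 0.05, 0.1, 0.4)
  ths <- vapply(alphas, function(a) ears_threshold(y, alpha = a)$threshold, numeric(1))
  expect_true(all(diff(ths) <= 0))
  w <- downweight_baseline(y, "high")
  expect_lt(w[7], 1) # the spike is flagged
  expect_lt(
    ears_threshold(y, w, 0.025)$threshold,
    ears_threshold(y, alpha = 0.025)$threshold
  )
})

make_series <- function(baseline, observed, topic = "measles", region = "FR",
                        end = as.Date("2020-11-10")) {
  days <- seq(end - length(baseline), end, by = "day")
  structure(
    tibble::tibble(
      topic = topic, region = region, date = days,
      count_original = c(baseline, observed),
      count_total = c(baseline, observed),
      trusted_count = 0L
    ),
    class = c("tweet_counts", class(tibble::tibble()))
  )
}

test_that("signals fire on exceedance and respect the strict inequality", {
  counts <- make_series(c(2, 3, 2, 4, 3, 2, 3), 30)
  sig <- detect_signals(counts, signal_config(alpha = 0.025), as.Date("2020-11-10"))
  expect_identical(nrow(sig), 1L)
  expect_identical(sig$observed, 30)
  th <- ears_threshold(c(3, 2, 3, 4, 2, 3, 2), alpha = 0.025)
  expect_equal(sig$threshold, th$threshold, tolerance = 1e-9)

  # observed exactly at the threshold: no signal (flat baseline, threshold 5)
  flat5 <- make_series(rep(5, 7), 5)
  expect_identical(nrow(detect_signals(flat5, signal_config(), as.Date("2020-11-10"))), 0L)
  flat5b <- make_series(rep(5, 7), 6)
  expect_identical(nrow(detect_signals(flat5b, signal_config(), as.Date("2020-11-10"))), 1L)

  # flat zero history with zero observed stays quiet; a single post fires
  zero <- make_series(rep(0, 7), 0)
  expect_identical(nrow(detect_signals(zero, signal_config(), as.Date("2020-11-10"))), 0L)
  one <- make_series(rep(0, 7), 1)
  expect_identical(nrow(detect_signals(one, signal_config(), as.Date("2020-11-10"))), 1L)
})

test_that("insufficient history is an error naming the requirement", {
  counts <- make_series(c(2, 3), 30)
  expect_error(
    detect_signals(counts, signal_config(baseline_days = 7), as.Date("2020-11-10")),
    "7 baseline day"
  )
})

test_that("same-weekday baselines use previous weeks", {
  # Mondays at 10, all other days 0, over 5 weeks
  days <- seq(as.Date("2020-10-05"), as.Date("2020-11-09"), by = "day")
  vals <- ifelse(format(days, "%u") == "1", 10L, 0L)
  counts <- structure(
    tibble::tibble(
      topic = "t", region = "WORLD", date = days,
      count_original = vals, count_total = vals, trusted_count = 0L
    ),
    class = c("tweet_counts", class(tibble::tibble()))
  )
  as_of <- as.Date("2020-11-09") # a Monday, observed 10
  cfg_wd <- signal_config(baseline_days = 4, same_weekday_only = TRUE)
  expect_identical(nrow(detect_signals(counts, cfg_wd, as_of)), 0L)
  cfg_seq <- signal_config(baseline_days = 4)
  expect_identical(nrow(detect_signals(counts, cfg_seq, as_of)), 1L)
})

test_that("retweets can be opted into the detected series", {
  days <- seq(as.Date("2020-11-03"), as.Date("2020-11-10"), by = "day")
  counts <- structure(
    tibble::tibble(
      topic = "t", region = "WORLD", date = days,
      count_original = c(rep(2L, 7), 2L),
      count_total = c(rep(2L, 7), 40L), trusted_count = 0L
    ),
    class = c("tweet_counts", class(tibble::tibble()))
  )
  expect_identical(nrow(detect_signals(counts, signal_config(), as.Date("2020-11-10"))), 0L)
  expect_identical(
    nrow(detect_signals(counts, signal_config(include_retweets = TRUE), as.Date("2020-11-10"))),
    1L
  )
})

test_that("alerts carry counts, trusted share and top words per signal", {
  mk <- function(topic, n, trusted_n) {
    tibble::tibble(
      tweet_id = paste0(topic, seq_len(n)),
      created_at = as.POSIXct("2020-11-10 09:00:00", tz = "UTC"),
      topic = topic, text = paste(topic, "outbreak in paris"), lang = "en",
      is_retweet = FALSE, is_quote = FALSE, origin_text = NA_character_,
      user_geo = NA_character_, user_declared = NA_character_,
      user_profile = NA_character_,
      trusted = seq_len(n) <= trusted_n,
      geo_country = "FR", user_country = NA_character_
    )
  }
  tweets <- dplyr::bind_rows(mk("measles", 4, 1), mk("cholera", 3, 3))
  signals <- structure(
    tibble::tibble(
      topic = c("measles", "cholera"), region = "FR",
      date = as.Date("2020-11-10"), hour = 9L,
      observed = c(4, 3), expected = 0.5, threshold = 2,
      alpha = 0.025, baseline_days = 7L, downweight_strength = "none"
    ),
    class = c("tweet_signals", class(tibble::tibble()))
  )
  alerts <- build_alerts(signals, tweets, signal_config())
  expect_identical(alerts$trusted_pct, c(25, 100))
  expect_identical(alerts$tweet_count, c(4, 3))
  expect_true("paris" %in% alerts$top_words[[1]]$word)
  expect_false("in" %in% alerts$top_words[[1]]$word) # stop word

  # inconsistent record sets are refused
  bad <- signals
  bad$observed <- c(5, 3)
  expect_error(build_alerts(bad, tweets, signal_config()), "inconsistent")

  # wordless texts give an empty top-word list
  tweets2 <- mk("measles", 2, 0)
  tweets2$text <- ""
  sig2 <- signals[1, ]
  sig2$observed <- 2
  a2 <- build_alerts(sig2, tweets2, signal_config())
  expect_identical(nrow(a2$top_words[[1]]), 0L)

  # alert files round-trip through CSV
  csvp <- withr::local_tempfile(fileext = ".csv")
  jlp <- withr::local_tempfile(fileext = ".jsonl")
  write_alerts(alerts, csvp, jlp)
  back <- readr::read_csv(csvp, show_col_types = FALSE)
  expect_identical(nrow(back), 2L)
  expect_identical(back$top_words[1], paste(alerts$top_words[[1]]$word, collapse = ";"))
  expect_identical(length(readLines(jlp)), 2L)
})

test_that("signal configuration is validated eagerly", {
  expect_error(signal_config(alpha = 0), "between")
  expect_error(signal_config(alpha = 1), "between")
  expect_error(signal_config(baseline_days = 1), ">= 2")
  expect_error(signal_config(downweight_strength = "extreme"), "arg")
})
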