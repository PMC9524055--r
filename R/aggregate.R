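# Aggregation of geolocated records into topic-by-region daily count series,
# plus top-word summaries.

#' Aggregate geolocated tweets into daily count series
#'
#' Each record contributes once to its resolved country (tweet location
#' preferred, else the account location), to that country's continent, to the
#' pan-American super-region where applicable, and to `WORLD`; records with
#' no accepted location contribute to `WORLD` only. Retweets and quotes are
#' excluded from `count_original` (the series used for signal detection) but
#' kept in `count_total`. Days with no posts are zero-filled so every series
#' is contiguous over the covered range.
#'
#' @param tweets A tweet tibble carrying `geo_country` / `user_country`
#'   columns from [geolocate_tweets()] (either may be all-`NA`).
#' @param region_map Country-to-continent lookup, by default the bundled
#'   [country_regions()] table.
#' @return A tibble of class `tweet_counts` with columns `topic`, `region`
#'   (ISO country code, continent name, `"America"` or `"WORLD"`), `date`,
#'   `count_original`, `count_total`, `trusted_count`.
#' @export
aggregate_counts <- function(tweets, region_map = country_regions()) {
  if (!"geo_country" %in% names(tweets)) tweets$geo_country <- NA_character_
  if (!"user_country" %in% names(tweets)) tweets$user_country <- NA_character_
  if (nrow(tweets) == 0) {
    return(structure(
      tibble(
        topic = character(), region = character(), date = as.Date(character()),
        count_original = integer(), count_total = integer(),
        trusted_count = integer()
      ),
      class = c("tweet_counts", class(tibble()))
    ))
  }
  resolved <- coalesce(tweets$geo_country, tweets$user_country)
  unknown <- setdiff(unique(resolved[!is.na(resolved)]), region_map$country)
  if (length(unknown)) {
    abort(paste0("unknown country code(s): ", paste(unknown, collapse = ", ")))
  }
  pos <- match(resolved, region_map$country)
  base <- tibble(
    topic = tweets$topic,
    date = lubridate::as_date(lubridate::with_tz(tweets$created_at, "UTC")),
    original = !(tweets$is_retweet | tweets$is_quote),
    trusted = tweets$trusted,
    country = resolved,
    continent = region_map$continent[pos],
    super_region = region_map$super_region[pos]
  )
  long <- bind_rows(
    base %>% filter(!is.na(.data$country)) %>% mutate(region = .data$country),
    base %>% filter(!is.na(.data$continent)) %>% mutate(region = .data$continent),
    base %>% filter(!is.na(.data$super_region)) %>% mutate(region = .data$super_region),
    base %>% mutate(region = "WORLD")
  )
  counts <- long %>%
    group_by(.data$topic, .data$region, .data$date) %>%
    summarise(
      count_original = sum(.data$original),
      count_total = dplyr::n(),
      trusted_count = sum(.data$original & .data$trusted),
      .groups = "drop"
    )
  full_days <- seq(min(base$date), max(base$date), by = "day")
  counts <- counts %>%
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(c("topic", "region"))),
      date = full_days,
      fill = list(count_original = 0L, count_total = 0L, trusted_count = 0L)
    ) %>%
    arrange(.data$topic, .data$region, .data$date)
  structure(counts, class = c("tweet_counts", class(counts)))
}

#' Most frequent words across texts
#'
#' Tokenises, drops stop words, and returns the `k` most frequent tokens.
#' Ties break lexicographically, so the result is deterministic.
#'
#' @param texts Character vector of texts (or a tweet tibble, in which case
#'   the `text` column is used).
#' @param k Number of words requested (`>= 1`); fewer distinct words give a
#'   shorter list.
#' @param stop_list Character vector of casefolded words to exclude, e.g.
#'   [stop_words()].
#' @return A tibble with columns `word` and `n`, ordered by decreasing `n`
#'   then alphabetically.
#' @export
top_words <- function(texts, k = 20L, stop_list = stop_words()) {
  if (is.data.frame(texts)) texts <- texts$text
  stopifnot(k >= 1)
  toks <- unlist(lapply(texts[!is.na(texts)], function(t) tokenize_text(t)$token))
  toks <- toks[!(toks %in% stop_list)]
  if (length(toks) == 0) {
    return(tibble(word = character(), n = integer()))
  }
  tibble(word = toks) %>%
    count(.data$word, name = "n") %>%
    arrange(desc(.data$n), .data$word) %>%
    head(k)
}

#' Read or write count series as tidy CSV
#'
#' Columns: `topic,region,date,count_original,count_total,trusted_count`.
#'
#' @param counts A `tweet_counts` tibble.
#' @param path CSV file path.
#' @return `write_counts()` returns `path` invisibly; `read_counts()` the
#'   `tweet_counts` tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_csv(counts, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  counts <- readr::read_csv(path, col_types = readr::cols(
    topic = readr::col_character(), region = readr::col_character(),
    date = readr::col_date(), count_original = readr::col_integer(),
    count_total = readr::col_integer(), trusted_count = readr::col_integer()
  ), na = character(), progress = FALSE)
  structure(counts, class = c("tweet_counts", class(counts)))
}
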