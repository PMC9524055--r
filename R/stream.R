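# Tweet-record data model, JSON Lines I/O, and the seeded synthetic stream
# generator that stands in for live API collection.

TWEET_KEYS <- c(
  "tweet_id", "created_at", "topic", "text", "lang", "is_retweet", "is_quote",
  "origin_text", "user_geo", "user_declared", "user_profile", "trusted"
)
TWEET_REQUIRED <- c(
  "tweet_id", "created_at", "topic", "text", "lang", "is_retweet", "is_quote",
  "trusted"
)

#' Specify a synthetic tweet stream
#'
#' Defines the generative conditions for [generate_stream()]: per-topic,
#' per-country daily posting rates with negative-binomial overdispersion,
#' retweet/quote/trusted-user fractions, and how often a post embeds a
#' gazetteer place name (which gives per-record geolocation ground truth).
#'
#' @param topics Data frame with columns `topic`, `country` (ISO-3166-1
#'   alpha-2) and `lambda` (mean original posts per day, `>= 0`).
#' @param date_range Length-2 vector of dates (inclusive UTC interval).
#' @param dispersion Negative-binomial size parameter `k > 0`; `Inf` gives
#'   Poisson counts. Daily counts have mean `lambda` and variance
#'   `lambda + lambda^2 / k`.
#' @param retweet_frac,quote_frac,trusted_frac Probabilities in `[0, 1]`;
#'   `retweet_frac + quote_frac <= 1`.
#' @param place_mention_prob Probability that a post's text (or, for
#'   retweets/quotes, its origin text) embeds a gazetteer place name verbatim.
#' @param user_location_prob Probability that the posting account carries a
#'   self-declared location drawn from the gazetteer.
#' @param languages Languages templates are drawn from (subset of
#'   `c("en","fr","es","pt")`).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `stream_spec`.
#' @export
stream_spec <- function(topics, date_range, dispersion = Inf,
                        retweet_frac = 0.15, quote_frac = 0.05,
                        trusted_frac = 0.1, place_mention_prob = 0.8,
                        user_location_prob = 0.3,
                        languages = c("en", "fr", "es", "pt"), seed = 1L) {
  topics <- as_tibble(topics)
  need <- c("topic", "country", "lambda")
  if (!all(need %in% names(topics)) || nrow(topics) == 0) {
    abort("`topics` must have rows and columns topic, country, lambda")
  }
  if (!all(is.finite(topics$lambda)) || any(topics$lambda < 0)) {
    abort("topic rates must be finite and non-negative")
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2L || any(is.na(date_range)) ||
    date_range[1] > date_range[2]) {
    abort("`date_range` must be two ordered dates")
  }
  if (!(is_scalar_number(dispersion) || identical(dispersion, Inf)) ||
    dispersion <= 0) {
    abort("`dispersion` must be a positive number (Inf for Poisson)")
  }
  for (p in list(retweet_frac, quote_frac, trusted_frac, place_mention_prob,
                 user_location_prob)) {
    if (!is_prob(p)) abort("all fractions must be probabilities in [0, 1]")
  }
  if (retweet_frac + quote_frac > 1) {
    abort("retweet_frac + quote_frac must not exceed 1")
  }
  languages <- match.arg(languages, c("en", "fr", "es", "pt"),
    several.ok = TRUE
  )
  structure(
    list(
      topics = topics, date_range = date_range, dispersion = dispersion,
      retweet_frac = retweet_frac, quote_frac = quote_frac,
      trusted_frac = trusted_frac, place_mention_prob = place_mention_prob,
      user_location_prob = user_location_prob, languages = languages,
      seed = as.integer(seed)
    ),
    class = "stream_spec"
  )
}

#' Specify an injected outbreak burst
#'
#' Multiplies the posting rate of one topic in one country by `magnitude`
#' over an inclusive date window. Used as ground truth in detection-power
#' experiments.
#'
#' @param topic,region Topic name and ISO country code the burst applies to.
#' @param window Length-2 inclusive date interval.
#' @param magnitude Multiplicative rate factor, `> 1`.
#' @return An object of class `outbreak_spec`.
#' @export
outbreak_spec <- function(topic, region, window, magnitude) {
  window <- as.Date(window)
  if (length(window) != 2L || any(is.na(window)) || window[1] > window[2]) {
    abort("`window` must be two ordered dates")
  }
  if (!is_scalar_number(magnitude) || magnitude <= 1) {
    abort("`magnitude` must be > 1")
  }
  structure(
    list(
      topic = topic, region = region, window = window,
      magnitude = magnitude
    ),
    class = "outbreak_spec"
  )
}

stream_templates <- list(
  en = c(place = "%s cases reported in %s", none = "%s cases reported today"),
  fr = c(place = "cas de %s signalés à %s", none = "cas de %s signalés aujourd'hui"),
  es = c(place = "casos de %s en %s", none = "casos de %s hoy"),
  pt = c(place = "casos de %s em %s", none = "casos de %s hoje")
)

#' Generate a synthetic tweet stream
#'
#' Draws daily topic-by-country counts from a negative-binomial model
#' (Poisson when `dispersion = Inf`), multiplies rates inside outbreak
#' windows, and renders each post from a language template of the form
#' `"<phrase> in <PlaceName>"` so that geolocation ground truth is known per
#' record. Output is deterministic given `spec$seed`.
#'
#' @param spec A [stream_spec()].
#' @param gazetteer A gazetteer tibble from [load_geonames()]; required when
#'   `place_mention_prob > 0` or `user_location_prob > 0`.
#' @param outbreaks List of [outbreak_spec()] objects.
#' @return A tibble of tweet records (dialect columns, see [write_tweets()])
#'   plus simulation ground-truth columns `sim_place`, `sim_country` (the
#'   embedded place and its country, `NA` when no place was embedded) and
#'   `sim_user_country`. Ground-truth columns are not serialised.
#' @export
generate_stream <- function(spec, gazetteer = NULL, outbreaks = list()) {
  if (!inherits(spec, "stream_spec")) abort("`spec` must be a stream_spec")
  if (inherits(outbreaks, "outbreak_spec")) outbreaks <- list(outbreaks)
  needs_gaz <- spec$place_mention_prob > 0 || spec$user_location_prob > 0
  if (needs_gaz && (is.null(gazetteer) || nrow(gazetteer) == 0)) {
    abort("a non-empty gazetteer is required when place mentions are enabled")
  }
  for (ob in outbreaks) {
    if (!inherits(ob, "outbreak_spec")) abort("outbreaks must be outbreak_spec objects")
    if (ob$window[1] < spec$date_range[1] || ob$window[2] > spec$date_range[2]) {
      abort("outbreak window must lie within the stream date range")
    }
  }

  days <- seq(spec$date_range[1], spec$date_range[2], by = "day")
  grid <- tidyr::expand_grid(spec$topics, date = days)
  mu <- grid$lambda
  for (ob in outbreaks) {
    hit <- grid$topic == ob$topic & grid$country == ob$region &
      grid$date >= ob$window[1] & grid$date <= ob$window[2]
    mu[hit] <- mu[hit] * ob$magnitude
  }

  withr::with_seed(spec$seed, {
    n_day <- if (is.infinite(spec$dispersion)) {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), size = spec$dispersion, mu = mu)
    }
    tw <- grid[rep(seq_len(nrow(grid)), n_day), c("topic", "country", "date")]
    m <- nrow(tw)
    if (m == 0) {
      return(empty_stream())
    }
    lang <- sample(spec$languages, m, replace = TRUE)
    secs <- runif(m, 0, 86399.999)
    u <- runif(m)
    is_retweet <- u < spec$retweet_frac
    is_quote <- !is_retweet & u < spec$retweet_frac + spec$quote_frac
    trusted <- runif(m) < spec$trusted_frac
    has_place <- runif(m) < spec$place_mention_prob
    has_user <- runif(m) < spec$user_location_prob
    # posts mention places in their stream's own country when the gazetteer
    # covers it, so injected outbreaks surface in that country's series
    place_i <- if (needs_gaz) {
      vapply(tw$country, function(cc) {
        home <- which(gazetteer$country == cc)
        if (length(home)) home[sample.int(length(home), 1L)] else sample.int(nrow(gazetteer), 1L)
      }, integer(1))
    } else {
      rep(NA_integer_, m)
    }
    user_i <- if (needs_gaz) sample.int(nrow(gazetteer), m, replace = TRUE) else rep(NA_integer_, m)

    place_name <- if (needs_gaz) gazetteer$name[place_i] else rep(NA_character_, m)
    place_country <- if (needs_gaz) gazetteer$country[place_i] else rep(NA_character_, m)
    tmpl_place <- vapply(lang, function(l) stream_templates[[l]][["place"]], character(1))
    tmpl_none <- vapply(lang, function(l) stream_templates[[l]][["none"]], character(1))
    body <- ifelse(has_place,
      sprintf(tmpl_place, tw$topic, place_name),
      sprintf(tmpl_none, tw$topic)
    )
    shared <- is_retweet | is_quote
    text <- ifelse(shared, paste0("RT ", sprintf(tmpl_none, tw$topic)), body)
    origin_text <- ifelse(shared, body, NA_character_)

    user_declared <- ifelse(has_user & needs_gaz, gazetteer$name[user_i], NA_character_)
    sim_user_country <- ifelse(has_user & needs_gaz, gazetteer$country[user_i], NA_character_)

    tibble(
      tweet_id = sprintf("t%09d", seq_len(m)),
      created_at = as.POSIXct(tw$date, tz = "UTC") + secs,
      topic = tw$topic,
      text = text,
      lang = lang,
      is_retweet = is_retweet,
      is_quote = is_quote,
      origin_text = origin_text,
      user_geo = NA_character_,
      user_declared = user_declared,
      user_profile = NA_character_,
      trusted = trusted,
      sim_place = ifelse(has_place, place_name, NA_character_),
      sim_country = ifelse(has_place, place_country, NA_character_),
      sim_user_country = sim_user_country
    )
  })
}

empty_stream <- function() {
  tibble(
    tweet_id = character(), created_at = as.POSIXct(character(), tz = "UTC"),
    topic = character(), text = character(), lang = character(),
    is_retweet = logical(), is_quote = logical(), origin_text = character(),
    user_geo = character(), user_declared = character(),
    user_profile = character(), trusted = logical(),
    sim_place = character(), sim_country = character(),
    sim_user_country = character()
  )
}

#' Validate a tweet-record tibble
#'
#' Enforces the record invariants: unique `tweet_id`, `is_retweet` and
#' `is_quote` never both set, `origin_text` present only on retweets/quotes,
#' timezone-aware timestamps.
#'
#' @param tweets A tweet tibble.
#' @return `tweets`, invisibly, or an error.
#' @export
validate_tweets <- function(tweets) {
  miss <- setdiff(TWEET_KEYS, names(tweets))
  if (length(miss)) abort(paste0("missing tweet columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(tweets$tweet_id)) abort("tweet_id values must be unique")
  if (any(tweets$is_retweet & tweets$is_quote)) {
    abort("a record cannot be both a retweet and a quote")
  }
  bad_origin <- !is.na(tweets$origin_text) & !(tweets$is_retweet | tweets$is_quote)
  if (any(bad_origin)) abort("origin_text is only allowed on retweets/quotes")
  if (!inherits(tweets$created_at, "POSIXct")) {
    abort("created_at must be a POSIXct timestamp")
  }
  invisible(tweets)
}

#' Read tweets from a JSON Lines file
#'
#' One record per line, UTF-8, keys exactly as documented in
#' [write_tweets()]. Unknown keys are ignored; timestamps are normalised to
#' UTC; absent optionals become `NA`.
#'
#' @param path File path.
#' @return A tibble of tweet records in file order.
#' @export
read_tweets <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_stream()[, TWEET_KEYS])
  }
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) abort(sprintf("malformed JSON on line %d: %s", i, conditionMessage(e)))
    )
    miss <- setdiff(TWEET_REQUIRED, names(rec)[!vapply(rec, is.null, logical(1))])
    if (length(miss)) {
      abort(sprintf("line %d is missing required key(s): %s", i, paste(miss, collapse = ", ")))
    }
    opt <- function(k) {
      v <- rec[[k]]
      if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)
    }
    ts <- lubridate::ymd_hms(rec$created_at, tz = "UTC", quiet = TRUE)
    if (is.na(ts)) abort(sprintf("line %d has an unparseable created_at", i))
    tibble(
      tweet_id = as.character(rec$tweet_id), created_at = ts,
      topic = as.character(rec$topic), text = as.character(rec$text),
      lang = as.character(rec$lang),
      is_retweet = isTRUE(rec$is_retweet), is_quote = isTRUE(rec$is_quote),
      origin_text = opt("origin_text"), user_geo = opt("user_geo"),
      user_declared = opt("user_declared"), user_profile = opt("user_profile"),
      trusted = isTRUE(rec$trusted)
    )
  })
  bind_rows(rows)
}

#' Write tweets to a JSON Lines file
#'
#' Serialises the dialect columns (`tweet_id`, `created_at` as ISO-8601 with
#' offset, `topic`, `text`, `lang`, `is_retweet`, `is_quote`, `origin_text`,
#' `user_geo`, `user_declared`, `user_profile`, `trusted`), one JSON object
#' per line, UTF-8, absent optionals as `null`. Simulation ground-truth
#' columns are dropped. `read_tweets(write_tweets(x))` reproduces `x`
#' field-for-field.
#'
#' @param tweets A valid tweet tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(tweets, path) {
  validate_tweets(tweets)
  lines <- vapply(seq_len(nrow(tweets)), function(i) {
    rec <- list(
      tweet_id = tweets$tweet_id[i],
      created_at = format(tweets$created_at[i], "%Y-%m-%dT%H:%M:%S+00:00", tz = "UTC"),
      topic = tweets$topic[i], text = tweets$text[i], lang = tweets$lang[i],
      is_retweet = tweets$is_retweet[i], is_quote = tweets$is_quote[i],
      origin_text = tweets$origin_text[i], user_geo = tweets$user_geo[i],
      user_declared = tweets$user_declared[i],
      user_profile = tweets$user_profile[i], trusted = tweets$trusted[i]
    )
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
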