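# Two-step tweet geolocation: candidate extraction with the location-word
# classifier, then vector-space matching against the gazetteer index.

#' Build a searchable gazetteer index
#'
#' Token postings over entry names and alternate names with
#' inverse-document-frequency weights (`idf = 1 + log(N / df)`), plus the
#' scoring constants used by [match_candidate()]. The score scale is
#' calibrated so that an exact, full-coverage match of a well-known place
#' lands well above the default acceptance threshold of 10 while a single
#' common-token partial match (e.g. "real" against "Ciudad Real") lands
#' below it.
#'
#' @param entries A gazetteer tibble from [load_geonames()]; must be
#'   non-empty.
#' @param boost_name,boost_alt Field boosts for tokens matched in the primary
#'   name and in alternate names.
#' @param pop_weight Population boost weight; an entry's score is multiplied
#'   by `1 + pop_weight * log10(1 + population)`.
#' @param exact_boost Multiplier applied when the query equals an entry's
#'   full (alternate) name.
#' @return An object of class `gazetteer_index`.
#' @export
build_index <- function(entries, boost_name = 2, boost_alt = 1,
                        pop_weight = 0.1, exact_boost = 2) {
  if (is.null(entries) || nrow(entries) == 0) abort("gazetteer must be non-empty")
  norm <- function(s) paste(tokenize_text(s)$token, collapse = " ")
  post <- purrr::map_dfr(seq_len(nrow(entries)), function(i) {
    name_tok <- tokenize_text(entries$name[i])$token
    alt_tok <- unique(unlist(lapply(entries$alt_names[[i]], function(a) tokenize_text(a)$token)))
    alt_tok <- setdiff(alt_tok, name_tok)
    bind_rows(
      tibble(token = unique(name_tok), field = "name"),
      if (length(alt_tok)) tibble(token = alt_tok, field = "alt")
    ) %>% mutate(entry_id = entries$entry_id[i])
  })
  exact_names <- purrr::map(seq_len(nrow(entries)), function(i) {
    unique(c(norm(entries$name[i]), vapply(entries$alt_names[[i]], norm, character(1))))
  })
  name_len <- vapply(entries$name, function(s) max(1L, nrow(tokenize_text(s))), integer(1))
  df <- post %>%
    distinct(.data$token, .data$entry_id) %>%
    count(.data$token, name = "df")
  idf <- df %>% mutate(idf = 1 + log(nrow(entries) / .data$df))
  structure(
    list(
      entries = entries %>% mutate(name_len = unname(name_len)),
      postings = post, idf = idf, exact_names = exact_names,
      params = list(
        boost_name = boost_name, boost_alt = boost_alt,
        pop_weight = pop_weight, exact_boost = exact_boost
      )
    ),
    class = "gazetteer_index"
  )
}

#' @export
print.gazetteer_index <- function(x, ...) {
  cat(sprintf(
    "<gazetteer_index> %d entries, %d tokens\n",
    nrow(x$entries), nrow(x$idf)
  ))
  invisible(x)
}

#' Match a candidate span against the gazetteer
#'
#' Scores every entry sharing at least one token with the query as the sum
#' over matched query tokens of `idf * field_boost`, normalised by the square
#' root of the entry-name length, times the query coverage fraction (matched
#' tokens / query tokens), times the population factor, times the exact-name
#' boost when the whole query equals the entry's (alternate) name. Ties break
#' by higher population, then lower entry id.
#'
#' @param span The candidate surface string (or a row of
#'   [extract_candidates()] output).
#' @param index A [build_index()] object.
#' @param top_k Maximum number of matches returned.
#' @return A tibble of matches sorted by descending `match_score`, with
#'   columns `entry_id`, `name`, `match_score`, `country`, `admin1`,
#'   `feature`, `population`. Empty when nothing matches.
#' @export
match_candidate <- function(span, index, top_k = 5L) {
  stopifnot(inherits(index, "gazetteer_index"))
  if (is.data.frame(span)) span <- span$surface[1]
  qtok <- unique(tokenize_text(span)$token)
  if (length(qtok) == 0) {
    return(empty_matches())
  }
  qnorm <- paste(tokenize_text(span)$token, collapse = " ")
  p <- index$params
  post_hits <- filter(index$postings, .data$token %in% qtok)
  if (nrow(post_hits) == 0) {
    return(empty_matches())
  }
  hits <- post_hits %>%
    left_join(index$idf[, c("token", "idf")], by = "token") %>%
    mutate(boost = if_else(.data$field == "name", p$boost_name, p$boost_alt)) %>%
    group_by(.data$entry_id, .data$token) %>%
    summarise(w = max(.data$idf * .data$boost), .groups = "drop_last") %>%
    summarise(base = sum(.data$w), n_matched = dplyr::n(), .groups = "drop")
  if (nrow(hits) == 0) {
    return(empty_matches())
  }
  ent <- index$entries
  pos <- match(hits$entry_id, ent$entry_id)
  exact <- vapply(pos, function(i) qnorm %in% index$exact_names[[i]], logical(1))
  hits %>%
    mutate(
      name = ent$name[pos], country = ent$country[pos],
      admin1 = ent$admin1[pos], feature = ent$feature[pos],
      population = ent$population[pos],
      match_score = .data$base / sqrt(ent$name_len[pos]) *
        (.data$n_matched / length(qtok)) *
        (1 + p$pop_weight * log10(1 + .data$population)) *
        if_else(exact, p$exact_boost, 1)
    ) %>%
    arrange(desc(.data$match_score), desc(.data$population), .data$entry_id) %>%
    select("entry_id", "name", "match_score", "country", "admin1", "feature", "population") %>%
    head(top_k)
}

empty_matches <- function() {
  tibble(
    entry_id = integer(), name = character(), match_score = numeric(),
    country = character(), admin1 = character(), feature = character(),
    population = numeric()
  )
}

#' Extract location-candidate spans from a text
#'
#' Scores each token with the location-word classifier and returns maximal
#' runs of consecutive tokens scoring at least `min_candidate_score`, so that
#' multiword places like "Ciudad Real" form one span.
#'
#' @param text A single string.
#' @param classifier A [train_candidate_classifier()] object.
#' @param min_candidate_score Token acceptance threshold in `[0, 1]`.
#' @return A tibble with columns `start`, `end` (0-based half-open character
#'   offsets), `surface` and `candidate_score` (mean token score), ordered by
#'   descending `candidate_score`.
#' @export
extract_candidates <- function(text, classifier, min_candidate_score = 0.5) {
  empty <- tibble(
    start = integer(), end = integer(), surface = character(),
    candidate_score = numeric()
  )
  toks <- tokenize_text(text %||% "")
  if (nrow(toks) == 0) return(empty)
  sc <- score_tokens(classifier, toks$token)
  keep <- sc >= min_candidate_score
  if (!any(keep)) return(empty)
  run_id <- cumsum(c(TRUE, diff(keep) != 0))
  spans <- purrr::map_dfr(split(seq_len(nrow(toks))[keep], run_id[keep]), function(idx) {
    tibble(
      start = toks$start[idx[1]],
      end = toks$end[idx[length(idx)]],
      surface = substring(text, toks$start[idx[1]] + 1L, toks$end[idx[length(idx)]]),
      candidate_score = mean(sc[idx])
    )
  })
  arrange(spans, desc(.data$candidate_score))
}

# Best gazetteer match for one free-text string: top-1 over all candidate
# spans (optionally also the whole string, used for user-location metadata
# which is already a location field). Returns a one-row tibble or NULL.
best_match_for_text <- function(text, classifier, index,
                                min_candidate_score = 0.5,
                                whole_text = FALSE) {
  if (is.null(text) || is.na(text) || !nzchar(text)) return(NULL)
  cand <- extract_candidates(text, classifier, min_candidate_score)
  spans <- cand$surface
  # compound names often carry a connective the classifier rejects
  # ("Castilla-La Mancha", "Ile de France"); bridge span pairs separated by a
  # single token so the full name can still be matched exactly
  if (nrow(cand) >= 2) {
    ord <- cand[order(cand$start), ]
    toks <- tokenize_text(text)
    for (i in seq_len(nrow(ord) - 1)) {
      between <- sum(toks$start >= ord$end[i] & toks$end <= ord$start[i + 1])
      if (between == 1) {
        spans <- c(spans, substring(text, ord$start[i] + 1L, ord$end[i + 1]))
      }
    }
  }
  if (whole_text) spans <- unique(c(spans, text))
  if (length(spans) == 0) return(NULL)
  best <- NULL
  for (s in spans) {
    m <- match_candidate(s, index, top_k = 1L)
    if (nrow(m) && (is.null(best) || m$match_score[1] > best$match_score[1])) best <- m
  }
  best
}

geo_na_row <- function() {
  tibble(
    entry_id = NA_integer_, name = NA_character_, match_score = NA_real_,
    country = NA_character_, admin1 = NA_character_, source = NA_character_
  )
}

as_geo_row <- function(m, source) {
  # a country-level entry carries no subnational location
  tibble(
    entry_id = m$entry_id[1], name = m$name[1], match_score = m$match_score[1],
    country = m$country[1],
    admin1 = if (m$feature[1] %in% c("admin1", "populated_place") &&
      nzchar(m$admin1[1])) m$admin1[1] else NA_character_,
    source = source
  )
}

#' Geolocate a single tweet record
#'
#' Searches the tweet text first; if no match exceeds `min_score` and the
#' record is a retweet or quote, the retweeted/quoted text is searched.
#' Acceptance is strict (`match_score > min_score`).
#'
#' @param record A one-row tweet tibble (or list with the same fields).
#' @param classifier,index Trained classifier and gazetteer index.
#' @param min_score Acceptance threshold on the match score (default 10).
#' @param min_candidate_score Token threshold for candidate extraction.
#' @return A one-row tibble (`entry_id`, `name`, `match_score`, `country`,
#'   `admin1`, `source`) or `NULL` when nothing is accepted. `source` is
#'   `"tweet_text"` or `"origin_text"`.
#' @export
geolocate_tweet <- function(record, classifier, index, min_score = 10,
                            min_candidate_score = 0.5) {
  m <- best_match_for_text(record$text, classifier, index, min_candidate_score)
  if (!is.null(m) && m$match_score[1] > min_score) {
    return(as_geo_row(m, "tweet_text"))
  }
  if (isTRUE(record$is_retweet) || isTRUE(record$is_quote)) {
    m <- best_match_for_text(record$origin_text, classifier, index, min_candidate_score)
    if (!is.null(m) && m$match_score[1] > min_score) {
      return(as_geo_row(m, "origin_text"))
    }
  }
  NULL
}

#' Resolve a user's location with the standard priority order
#'
#' Evaluates `user_geo` (location at posting time), then `user_declared`,
#' then `user_profile`, returning the first field that yields an accepted
#' match. Each field is searched both through candidate extraction and as a
#' whole string, since user-location metadata is already a location field.
#'
#' @inheritParams geolocate_tweet
#' @return A one-row tibble as in [geolocate_tweet()] with `source` one of
#'   `"user_geo"`, `"user_declared"`, `"user_profile"`, or `NULL`.
#' @export
geolocate_user <- function(record, classifier, index, min_score = 10,
                           min_candidate_score = 0.5) {
  for (f in c("user_geo", "user_declared", "user_profile")) {
    m <- best_match_for_text(record[[f]], classifier, index,
      min_candidate_score,
      whole_text = TRUE
    )
    if (!is.null(m) && m$match_score[1] > min_score) {
      return(as_geo_row(m, f))
    }
  }
  NULL
}

#' Geolocate every record in a tweet tibble
#'
#' Vectorised pipeline verb: applies [geolocate_tweet()] and
#' [geolocate_user()] to each record, memoising matches per unique search
#' string, and appends the results as `geo_*` (tweet location) and `user_*`
#' (account location) columns.
#'
#' @param tweets A tweet tibble.
#' @param classifier,index Trained classifier and gazetteer index.
#' @param min_score Strict acceptance threshold on match scores.
#' @param min_candidate_score Token threshold for candidate extraction.
#' @return `tweets` with added columns `geo_country`, `geo_admin1`,
#'   `geo_score`, `geo_source`, `geo_name`, `user_country`, `user_admin1`,
#'   `user_score`, `user_source` (`NA` where nothing was accepted).
#' @export
geolocate_tweets <- function(tweets, classifier, index, min_score = 10,
                             min_candidate_score = 0.5) {
  lookup_env <- new.env(parent = emptyenv())
  memo_match <- function(text, whole_text) {
    if (is.null(text) || is.na(text) || !nzchar(text)) return(NULL)
    key <- paste0(if (whole_text) "w\r" else "t\r", text)
    if (!is.null(lookup_env[[key]])) {
      m <- lookup_env[[key]]
      return(if (is.character(m)) NULL else m)
    }
    m <- best_match_for_text(text, classifier, index, min_candidate_score,
      whole_text = whole_text
    )
    lookup_env[[key]] <- if (is.null(m)) "miss" else m
    m
  }
  one <- function(i) {
    geo <- NULL
    m <- memo_match(tweets$text[i], FALSE)
    if (!is.null(m) && m$match_score[1] > min_score) {
      geo <- as_geo_row(m, "tweet_text")
    } else if (tweets$is_retweet[i] || tweets$is_quote[i]) {
      m <- memo_match(tweets$origin_text[i], FALSE)
      if (!is.null(m) && m$match_score[1] > min_score) geo <- as_geo_row(m, "origin_text")
    }
    usr <- NULL
    for (f in c("user_geo", "user_declared", "user_profile")) {
      m <- memo_match(tweets[[f]][i], TRUE)
      if (!is.null(m) && m$match_score[1] > min_score) {
        usr <- as_geo_row(m, f)
        break
      }
    }
    geo <- geo %||% geo_na_row()
    usr <- usr %||% geo_na_row()
    tibble(
      geo_country = geo$country, geo_admin1 = geo$admin1,
      geo_score = geo$match_score, geo_source = geo$source,
      geo_name = geo$name,
      user_country = usr$country, user_admin1 = usr$admin1,
      user_score = usr$match_score, user_source = usr$source
    )
  }
  res <- purrr::map_dfr(seq_len(nrow(tweets)), one)
  if (nrow(tweets) == 0) {
    res <- tibble(
      geo_country = character(), geo_admin1 = character(),
      geo_score = numeric(), geo_source = character(), geo_name = character(),
      user_country = character(), user_admin1 = character(),
      user_score = numeric(), user_source = character()
    )
  }
  dplyr::bind_cols(tweets, res)
}
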