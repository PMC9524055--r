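# Shared fixtures, built once per test run.

toy_gaz <- load_geonames(toy_gazetteer_path())
toy_index <- build_index(toy_gaz)
toy_comp <- build_geo_components(pipeline_config(tibble::tibble(topic = "measles")))

# the minimal classifier from the documented examples
tiny_clf <- train_candidate_classifier(
  c("paris", "france", "madrid"),
  c("outbreak", "cases", "the")
)

# a minimal three-entry gazetteer (country / admin1 / city) written on the fly
write_mini_gazetteer <- function(path = tempfile(fileext = ".tsv")) {
  rows <- c(
    paste(c("1", "France", "France", "Francia", "46.0", "2.0", "A", "PCLI",
            "FR", "", "00", "", "", "", "66987244", "", "375",
            "Europe/Paris", "2020-01-01"), collapse = "\t"),
    paste(c("2", "Île-de-France", "Ile-de-France", "Region Parisienne",
            "48.5", "2.5", "A", "ADM1", "FR", "", "11", "", "", "",
            "12117132", "", "90", "Europe/Paris", "2020-01-01"), collapse = "\t"),
    paste(c("3", "Paris", "Paris", "Lutetia,Parigi", "48.85", "2.35", "P",
            "PPLC", "FR", "", "11", "", "", "", "2138551", "", "42",
            "Europe/Paris", "2020-01-01"), collapse = "\t")
  )
  writeLines(rows, path, useBytes = TRUE)
  path
}

# independent rescoring of a single-entry match, used as the hand oracle for
# the vector-space scoring formula
hand_score <- function(index, entry_name, q_tokens, matched, exact,
                       all_name_field = TRUE) {
  ent <- index$entries[index$entries$name == entry_name, ]
  p <- index$params
  idf <- index$idf$idf[match(matched, index$idf$token)]
  boost <- if (all_name_field) p$boost_name else p$boost_alt
  sum(idf * boost) / sqrt(ent$name_len) *
    (length(matched) / length(q_tokens)) *
    (1 + p$pop_weight * log10(1 + ent$population)) *
    (if (exact) p$exact_boost else 1)
}

make_stream <- function(lambda = 5, days = 10, seed = 1, countries = "FR",
                        topic = "measles", place_prob = 0, user_prob = 0,
                        dispersion = Inf, start = as.Date("2020-11-01"), ...) {
  topics <- tibble::tibble(
    topic = topic, country = countries,
    lambda = lambda
  )
  stream_spec(topics,
    date_range = c(start, start + days - 1),
    dispersion = dispersion, place_mention_prob = place_prob,
    user_location_prob = user_prob, seed = seed, ...
  )
}

# brute-force Wilcoxon signed-rank: enumerate every sign assignment
brute_wilcoxon_less <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  mean(w_all <= w_obs)
}
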