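# Gazetteer loading, the location-word classifier, and two-step geolocation.

test_that("GeoNames rows map to the expected feature labels", {
  gaz <- load_geonames(write_mini_gazetteer())
  expect_identical(gaz$feature, c("country", "admin1", "populated_place"))
  expect_identical(gaz$country, rep("FR", 3))
  expect_identical(gaz$admin1, c("00", "11", "11"))
  expect_true("Parigi" %in% gaz$alt_names[[3]])
  expect_identical(gaz$population[1], 66987244)
})

test_that("empty or malformed gazetteer files are handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), path)
  expect_identical(nrow(load_geonames(path)), 0L)
  writeLines(paste(letters[1:18], collapse = "\t"), path)
  expect_error(load_geonames(path), "row 1 has 18 columns")
})

test_that("classifier orders held-in words and respects the score range", {
  expect_gt(score_tokens(tiny_clf, "france"), score_tokens(tiny_clf, "cases"))
  expect_gt(score_tokens(tiny_clf, "paris"), 0.5)
  expect_lt(score_tokens(tiny_clf, "outbreak"), 0.5)
  z <- score_tokens(tiny_clf, "zzzz")
  expect_true(z >= 0 && z <= 1)
  # single-item classes still produce a valid scorer
  solo <- train_candidate_classifier("paris", "cases")
  s <- score_tokens(solo, c("paris", "cases", "zzzz"))
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(s[1], s[2])
})

test_that("classifier training is deterministic and validates inputs", {
  a <- train_candidate_classifier(c("paris", "madrid"), c("the", "cases"))
  b <- train_candidate_classifier(c("paris", "madrid"), c("the", "cases"))
  expect_identical(a$beta, b$beta)
  expect_error(train_candidate_classifier(character(0), "x"), "non-empty")
  expect_error(train_candidate_classifier(c("paris", "the"), c("the", "cases")), "disjoint")
})

test_that("candidate spans are maximal runs of accepted tokens", {
  expect_identical(nrow(extract_candidates("", tiny_clf)), 0L)
  spans <- extract_candidates("outbreak in paris", tiny_clf, min_candidate_score = 0.6)
  expect_identical(spans$surface, "paris")
  expect_identical(spans$start, 12L)
  expect_identical(spans$end, 17L)
  # consecutive accepted tokens merge into one multiword span
  clf2 <- train_candidate_classifier(
    c("ciudad", "real", "madrid"), c("update", "cases", "the")
  )
  spans2 <- extract_candidates("ciudad real update", clf2, min_candidate_score = 0.6)
  expect_identical(spans2$surface, "ciudad real")
  expect_identical(c(spans2$start, spans2$end), c(0L, 11L))
})

test_that("offsets index the original text through URL/mention masking", {
  toks <- tokenize_text("Measles outbreak in #Paris https://ex.io @who")
  expect_false(any(c("who", "https") %in% toks$token))
  expect_true("paris" %in% toks$token)
  i <- which(toks$token == "paris")
  expect_identical(substring("Measles outbreak in #Paris https://ex.io @who",
    toks$start[i] + 1L, toks$end[i]
  ), "Paris")
})

test_that("index construction is deterministic with sane idf", {
  one <- load_geonames(write_mini_gazetteer())[3, ]
  idx1 <- build_index(one)
  m <- match_candidate("paris", idx1)
  expect_identical(m$name, "Paris")
  expect_error(build_index(one[0, ]), "non-empty")

  # a token present in every entry gets the minimum idf
  idx3 <- build_index(load_geonames(write_mini_gazetteer()))
  fr_tok <- idx3$idf[idx3$idf$token == "france", ]
  expect_identical(fr_tok$df, 2L) # France + Île-de-France
  expect_true(all(idx3$idf$idf > 0))
  expect_identical(min(idx3$idf$idf), min(idx3$idf$idf[idx3$idf$df == max(idx3$idf$df)]))

  idx3b <- build_index(load_geonames(write_mini_gazetteer()))
  expect_equal(match_candidate("paris", idx3), match_candidate("paris", idx3b))
})

test_that("match scores agree with the hand-computed scoring formula", {
  idx <- build_index(load_geonames(write_mini_gazetteer()))
  m <- match_candidate("paris", idx, top_k = 1)
  expect_identical(m$country, "FR")
  expect_equal(
    m$match_score,
    hand_score(idx, "Paris", "paris", "paris", exact = TRUE),
    tolerance = 1e-12
  )
  # no-hit query
  expect_identical(nrow(match_candidate("zzz", idx)), 0L)
  # full toy index: "paris" resolves to the populated place in FR
  top <- match_candidate("paris", toy_index, top_k = 1)
  expect_identical(top$name, "Paris")
  expect_identical(top$country, "FR")
})

test_that("multiword coverage outranks single common tokens (Ciudad Real)", {
  full <- match_candidate("ciudad real", toy_index, top_k = 1)
  partial <- match_candidate("real", toy_index, top_k = 5)
  expect_identical(full$name, "Ciudad Real")
  expect_gt(full$match_score, max(partial$match_score))
  # the bare common token stays under the default acceptance threshold,
  # the exact multiword query well above it
  expect_lt(max(partial$match_score), 10)
  expect_gt(full$match_score, 10)
})

test_that("tweet geolocation searches text first, then retweet/quote origin", {
  rec <- list(text = "measles outbreak in paris", is_retweet = FALSE, is_quote = FALSE)
  g <- geolocate_tweet(rec, toy_comp$classifier, toy_index, min_score = 10)
  expect_identical(g$country, "FR")
  expect_identical(g$source, "tweet_text")

  rec2 <- list(text = "nothing to see here", is_retweet = FALSE, is_quote = FALSE)
  expect_null(geolocate_tweet(rec2, toy_comp$classifier, toy_index))

  rec3 <- list(
    text = "", is_retweet = TRUE, is_quote = FALSE,
    origin_text = "cholera in france"
  )
  g3 <- geolocate_tweet(rec3, toy_comp$classifier, toy_index, min_score = 10)
  expect_identical(g3$country, "FR")
  expect_identical(g3$source, "origin_text")
  # same origin text on a plain original is never searched
  rec4 <- list(
    text = "nothing to see here", is_retweet = FALSE, is_quote = FALSE,
    origin_text = "cholera in france"
  )
  expect_null(geolocate_tweet(rec4, toy_comp$classifier, toy_index))
})

test_that("user location honours the priority order with fallback", {
  rec <- list(user_geo = "Madrid", user_declared = "Paris", user_profile = NA)
  g <- geolocate_user(rec, toy_comp$classifier, toy_index)
  expect_identical(g$country, "ES")
  expect_identical(g$source, "user_geo")

  rec2 <- list(user_geo = NA, user_declared = NA, user_profile = NA)
  expect_null(geolocate_user(rec2, toy_comp$classifier, toy_index))

  rec3 <- list(user_geo = "xqzwv qqq", user_declared = NA, user_profile = "France")
  g3 <- geolocate_user(rec3, toy_comp$classifier, toy_index)
  expect_identical(g3$country, "FR")
  expect_identical(g3$source, "user_profile")
})

test_that("country-level matches carry no subnational location", {
  g <- geolocate_tweet(
    list(text = "cholera in france", is_retweet = FALSE, is_quote = FALSE),
    toy_comp$classifier, toy_index
  )
  expect_identical(g$country, "FR")
  expect_true(is.na(g$admin1))
  g2 <- geolocate_tweet(
    list(text = "measles outbreak in paris", is_retweet = FALSE, is_quote = FALSE),
    toy_comp$classifier, toy_index
  )
  expect_identical(g2$admin1, "11")
})

test_that("raising min_score never adds accepted geolocations", {
  spec <- make_stream(
    lambda = 2, days = 6, seed = 31, place_prob = 0.7,
    countries = c("FR", "ES", "BR")
  )
  tw <- generate_stream(spec, toy_gaz)
  accepted <- lapply(c(0, 10, 25), function(s) {
    g <- geolocate_tweets(tw, toy_comp$classifier, toy_index, min_score = s)
    tw$tweet_id[!is.na(g$geo_country)]
  })
  expect_true(all(accepted[[2]] %in% accepted[[1]]))
  expect_true(all(accepted[[3]] %in% accepted[[2]]))
  expect_gt(length(accepted[[1]]), 0)
})

test_that("closed loop: gazetteer-covered places geolocate to the right country", {
  spec <- make_stream(
    lambda = 4, days = 6, seed = 19, place_prob = 1,
    countries = c("FR", "ES", "BR", "US")
  )
  tw <- generate_stream(spec, toy_gaz)
  g <- geolocate_tweets(tw, toy_comp$classifier, toy_index, min_score = 10)
  originals <- g[!(g$is_retweet | g$is_quote), ]
  expect_gt(nrow(originals), 50)
  expect_true(all(!is.na(originals$geo_country)))
  expect_true(all(originals$geo_country == originals$sim_country))
})
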