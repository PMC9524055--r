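# Pipeline orchestration: structured configuration, the end-to-end run
# (geolocate -> aggregate -> detect -> alerts, with file outputs in place of
# e-mail dispatch), and the evaluation report.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Defaults mirror the
#' operational tool this pipeline emulates: four study languages, geolocation
#' acceptance score 10, a 7-day detection baseline, 20 top words per alert.
#'
#' @param topics Data frame with at least a `topic` column; for stream
#'   simulation also `country` and `lambda`. May carry per-topic `alpha` /
#'   `downweight_strength` override columns.
#' @param languages Subset of `c("en","fr","es","pt")`.
#' @param min_score Geolocation acceptance threshold (strict `>`).
#' @param min_candidate_score Token threshold for candidate extraction.
#' @param signal A [signal_config()].
#' @param gazetteer_path GeoNames-format gazetteer file.
#' @param out_dir Output directory for count-series and alert files.
#' @param seed Integer seed used by every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(topics, languages = c("en", "fr", "es", "pt"),
                            min_score = 10, min_candidate_score = 0.5,
                            signal = signal_config(),
                            gazetteer_path = toy_gazetteer_path(),
                            out_dir = NULL, seed = 1L) {
  topics <- as_tibble(topics)
  if (!"topic" %in% names(topics) || nrow(topics) == 0) {
    abort("`topics` must have rows and a `topic` column")
  }
  if (!is_scalar_number(min_score) || min_score < 0) {
    abort("`min_score` must be a non-negative number")
  }
  stopifnot(inherits(signal, "signal_config"))
  if (!file.exists(gazetteer_path)) {
    abort(paste0("gazetteer file not found: ", gazetteer_path))
  }
  if ("alpha" %in% names(topics) || "downweight_strength" %in% names(topics)) {
    # validate per-topic overrides eagerly, before any processing
    for (i in seq_len(nrow(topics))) {
      override_config(signal, topics[i, ])
    }
  }
  structure(
    list(
      topics = topics,
      languages = match.arg(languages, c("en", "fr", "es", "pt"), several.ok = TRUE),
      min_score = min_score, min_candidate_score = min_candidate_score,
      signal = signal, gazetteer_path = gazetteer_path,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

override_config <- function(signal, topic_row) {
  alpha <- if ("alpha" %in% names(topic_row)) topic_row[["alpha"]] else NA
  dw <- if ("downweight_strength" %in% names(topic_row)) topic_row[["downweight_strength"]] else NA
  signal_config(
    alpha = if (!is.na(alpha)) alpha else signal$alpha,
    baseline_days = signal$baseline_days,
    downweight_strength = if (!is.na(dw)) dw else signal$downweight_strength,
    same_weekday_only = signal$same_weekday_only,
    include_retweets = signal$include_retweets,
    k_top_words = signal$k_top_words
  )
}

#' Read or write a pipeline configuration as YAML
#'
#' A single human-editable file holding the [pipeline_config()] fields; the
#' `topics` entry is a list of records, and per-topic `alpha` /
#' `downweight_strength` overrides are supported.
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @return `read_pipeline_config()` a `pipeline_config`;
#'   `write_pipeline_config()` the path, invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sig <- y$signal %||% list()
  pipeline_config(
    topics = bind_rows(lapply(y$topics, as_tibble)),
    languages = y$languages %||% c("en", "fr", "es", "pt"),
    min_score = y$min_score %||% 10,
    min_candidate_score = y$min_candidate_score %||% 0.5,
    signal = signal_config(
      alpha = sig$alpha %||% 0.025,
      baseline_days = sig$baseline_days %||% 7L,
      downweight_strength = sig$downweight_strength %||% "none",
      same_weekday_only = sig$same_weekday_only %||% FALSE,
      include_retweets = sig$include_retweets %||% FALSE,
      k_top_words = sig$k_top_words %||% 20L
    ),
    gazetteer_path = y$gazetteer_path %||% toy_gazetteer_path(),
    out_dir = y$out_dir,
    seed = y$seed %||% 1L
  )
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  y <- list(
    topics = lapply(seq_len(nrow(config$topics)), function(i) as.list(config$topics[i, ])),
    languages = config$languages, min_score = config$min_score,
    min_candidate_score = config$min_candidate_score,
    signal = unclass(config$signal),
    gazetteer_path = config$gazetteer_path, out_dir = config$out_dir,
    seed = config$seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[", stage, "] ", conditionMessage(e)))
  })
}

#' Train the default geolocation components for a configuration
#'
#' Loads the gazetteer, builds its index, and trains the location-word
#' classifier on gazetteer name tokens (positives) against the bundled
#' common-word lists (negatives, with any gazetteer token removed first).
#'
#' @param config A [pipeline_config()].
#' @return A list with `gazetteer`, `index`, `classifier`.
#' @export
build_geo_components <- function(config) {
  gazetteer <- load_geonames(config$gazetteer_path)
  index <- build_index(gazetteer)
  loc_words <- unique(unlist(c(
    lapply(gazetteer$name, function(s) tokenize_text(s)$token),
    lapply(gazetteer$alt_names, function(a) unlist(lapply(a, function(s) tokenize_text(s)$token)))
  )))
  neg <- union(common_words(config$languages), stop_words(config$languages))
  # short function words inside compound place names ("Ile de France") make
  # poor positives; let the stop/common lists keep them as negatives
  loc_words <- setdiff(loc_words[nchar(loc_words) >= 3], neg)
  neg <- setdiff(neg, loc_words)
  classifier <- train_candidate_classifier(
    loc_words, neg, classifier_params(seed = config$seed)
  )
  list(gazetteer = gazetteer, index = index, classifier = classifier)
}

#' Run the full pipeline on a tweet stream
#'
#' Executes geolocate, aggregate, detect and alert-building in sequence,
#' logging record counts per stage to stderr, and writes `counts.csv`,
#' `alerts.csv` and `alerts.jsonl` to `config$out_dir` when set. Outputs are
#' deterministic given the configuration and input.
#'
#' @param config A [pipeline_config()].
#' @param input A tweet tibble or a JSON Lines file path.
#' @param as_of Detection run time (`POSIXct` or `Date`).
#' @return A list of class `pipeline_result` with `tweets` (geolocated),
#'   `counts`, `signals`, `alerts` and `paths`.
#' @export
run_pipeline <- function(config, input, as_of) {
  stopifnot(inherits(config, "pipeline_config"))
  tweets <- with_stage("read", {
    tw <- if (is.character(input)) read_tweets(input) else as_tibble(input)
    validate_tweets(tw)
    tw
  })
  message(sprintf("[read] %d records", nrow(tweets)))

  comp <- with_stage("train", build_geo_components(config))
  message(sprintf(
    "[train] %d gazetteer entries, %d n-gram features",
    nrow(comp$gazetteer), length(comp$classifier$vocab)
  ))

  tweets <- with_stage("geolocate", geolocate_tweets(
    tweets, comp$classifier, comp$index,
    min_score = config$min_score,
    min_candidate_score = config$min_candidate_score
  ))
  message(sprintf("[geolocate] %d records located", sum(!is.na(tweets$geo_country))))

  counts <- with_stage("aggregate", aggregate_counts(tweets))
  message(sprintf("[aggregate] %d series cells", nrow(counts)))

  signals <- with_stage("detect", {
    if (nrow(counts) == 0) {
      detect_empty_signals(config$signal)
    } else {
      detect_with_overrides(counts, config, as_of)
    }
  })
  message(sprintf("[detect] %d signals", nrow(signals)))

  alerts <- with_stage("alerts", build_alerts(
    signals, tweets, config$signal,
    stop_list = stop_words(config$languages)
  ))
  message(sprintf("[alerts] %d alerts", nrow(alerts)))

  paths <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    counts_path <- file.path(config$out_dir, "counts.csv")
    write_counts(counts, counts_path)
    alert_paths <- write_alerts(
      alerts,
      csv_path = file.path(config$out_dir, "alerts.csv"),
      jsonl_path = file.path(config$out_dir, "alerts.jsonl")
    )
    paths <- c(counts_path, alert_paths)
  }
  structure(
    list(
      tweets = tweets, counts = counts, signals = signals, alerts = alerts,
      paths = paths
    ),
    class = "pipeline_result"
  )
}

detect_empty_signals <- function(config) {
  structure(
    tibble(
      topic = character(), region = character(), date = as.Date(character()),
      hour = integer(), observed = numeric(), expected = numeric(),
      threshold = numeric(), alpha = numeric(), baseline_days = integer(),
      downweight_strength = character()
    ),
    class = c("tweet_signals", class(tibble()))
  )
}

detect_with_overrides <- function(counts, config, as_of) {
  topics <- config$topics
  has_override <- ("alpha" %in% names(topics) && any(!is.na(topics$alpha))) ||
    ("downweight_strength" %in% names(topics) && any(!is.na(topics$downweight_strength)))
  if (!has_override) {
    return(detect_signals(counts, config$signal, as_of))
  }
  parts <- lapply(unique(topics$topic), function(tp) {
    row <- topics[topics$topic == tp, ][1, ]
    cfg <- override_config(config$signal, row)
    detect_signals(filter(counts, .data$topic == tp), cfg, as_of)
  })
  leftover <- filter(counts, !(.data$topic %in% topics$topic))
  if (nrow(leftover)) {
    parts <- c(parts, list(detect_signals(leftover, config$signal, as_of)))
  }
  out <- bind_rows(parts) %>% arrange(.data$topic, .data$region)
  structure(out, class = c("tweet_signals", class(out)))
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")))
  }
  df
}

#' Produce the evaluation report
#'
#' Recomputes every evaluation statistic from annotation and triage tables:
#' geolocation accuracy and confusion metrics at national and subnational
#' level, both over all records and excluding predictions scoring at or
#' below `min_score`; general and specific PPV; per-arm inter-rater
#' agreement with Wald confidence intervals; and timeliness of unique paired
#' events with the one-sided Wilcoxon signed-rank p-value.
#'
#' @param annotations `NULL`, a tibble, or a CSV path: columns `tweet_id`,
#'   `rater`, `gold_country`, `gold_admin1`, `pred_country`, `pred_admin1`,
#'   `pred_score`.
#' @param triage `NULL`, a tibble, or a CSV path: columns `alert_id`,
#'   `status`, `detected_by`, `validation_time`, `topic`, `subtopic`.
#' @param min_score Geolocation score threshold defining the high-score
#'   stratum.
#' @param ci_level Confidence level for Wald intervals.
#' @param out_dir If set, writes `evaluation_report.csv` (tidy metrics) and
#'   `evaluation_report.txt` (human-readable) there.
#' @return A list of class `evaluation_report` with elements `geolocation`
#'   (tidy tibble of metrics by level and stratum), `ppv`, `agreement`,
#'   `timeliness` (each a tibble, possibly empty).
#' @export
run_evaluation <- function(annotations = NULL, triage = NULL, min_score = 10,
                           ci_level = 0.95, out_dir = NULL) {
  geo_tab <- tibble()
  if (!is.null(annotations)) {
    if (is.character(annotations)) {
      annotations <- readr::read_csv(annotations,
        col_types = readr::cols(.default = readr::col_character()),
        progress = FALSE
      ) %>% mutate(pred_score = as.numeric(.data$pred_score))
    }
    require_columns(annotations, c(
      "tweet_id", "rater", "gold_country", "gold_admin1",
      "pred_country", "pred_admin1", "pred_score"
    ), "annotations")
    high <- filter(annotations, is.na(.data$pred_score) | .data$pred_score > min_score)
    strata <- list(all = annotations, high_score = high)
    geo_tab <- purrr::map_dfr(names(strata), function(sname) {
      purrr::map_dfr(c("national", "subnational"), function(level) {
        res <- geolocation_accuracy(strata[[sname]], level)
        dplyr::bind_cols(
          tibble(
            stratum = sname, level = level,
            n = length(unique(strata[[sname]]$tweet_id)),
            accuracy = res$accuracy
          ),
          res$counts, res$metrics[, -1]
        )
      })
    })
  }
  ppv_tab <- tibble()
  agree_tab <- tibble()
  time_tab <- tibble()
  if (!is.null(triage)) {
    if (is.character(triage)) {
      triage <- readr::read_csv(triage,
        col_types = readr::cols(
          validation_time = readr::col_datetime(),
          .default = readr::col_character()
        ), progress = FALSE
      )
    }
    require_columns(triage, c(
      "alert_id", "status", "detected_by", "validation_time", "topic", "subtopic"
    ), "triage")
    n_event <- sum(triage$status == "event")
    n_false <- sum(triage$status == "false_signal")
    n_not <- sum(triage$status == "not_evaluated")
    ppv_tab <- tibble(
      n_events = n_event, n_false_signals = n_false, n_not_evaluated = n_not,
      ppv_specific = ppv_specific(n_event, n_false),
      ppv_general = ppv_general(n_event, n_false, n_not)
    )
    evaluated <- filter(triage, .data$status != "not_evaluated")
    if (nrow(evaluated)) {
      arm_detected <- function(arm) {
        sum(vapply(evaluated$detected_by, function(a) {
          arm %in% strsplit(a, ";", fixed = TRUE)[[1]]
        }, logical(1)))
      }
      agree_tab <- purrr::map_dfr(c("automated", "manual"), function(arm) {
        det <- arm_detected(arm)
        ci <- wald_ci(det, nrow(evaluated), ci_level)
        tibble(
          arm = arm, detected = det, total = nrow(evaluated),
          ira = ira(det, nrow(evaluated)), lower = ci$lower, upper = ci$upper
        )
      })
      events <- dedup_events(triage)
      diffs <- events$diff_hours[!is.na(events$diff_hours)]
      if (length(diffs)) {
        wt <- if (any(diffs != 0)) {
          wilcoxon_signed_rank(diffs, alternative = "less")
        } else {
          tibble(statistic = NA_real_, p_value = NA_real_, method = "undefined")
        }
        time_tab <- dplyr::bind_cols(timeliness(diffs), wt[, c("statistic", "p_value", "method")])
      }
    }
  }
  report <- structure(
    list(
      geolocation = geo_tab, ppv = ppv_tab, agreement = agree_tab,
      timeliness = time_tab
    ),
    class = "evaluation_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tidy_rows <- report_as_rows(report)
    readr::write_csv(tidy_rows, file.path(out_dir, "evaluation_report.csv"), progress = FALSE)
    writeLines(format_report(report), file.path(out_dir, "evaluation_report.txt"))
  }
  report
}

report_as_rows <- function(report) {
  rows <- list()
  g <- report$geolocation
  if (nrow(g)) {
    for (i in seq_len(nrow(g))) {
      for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv", "prevalence")) {
        rows[[length(rows) + 1]] <- tibble(
          section = "geolocation",
          item = paste(g$level[i], g$stratum[i], m, sep = "_"),
          value = round_half_up(g[[m]][i], 1)
        )
      }
    }
  }
  if (nrow(report$ppv)) {
    rows[[length(rows) + 1]] <- tibble(
      section = "ppv", item = c("ppv_specific", "ppv_general"),
      value = round_half_up(c(report$ppv$ppv_specific, report$ppv$ppv_general), 1)
    )
  }
  a <- report$agreement
  if (nrow(a)) {
    rows[[length(rows) + 1]] <- tibble(
      section = "agreement",
      item = paste0("ira_", a$arm),
      value = round_half_up(a$ira, 1)
    )
  }
  t <- report$timeliness
  if (nrow(t)) {
    rows[[length(rows) + 1]] <- tibble(
      section = "timeliness",
      item = c("median_hours", "q1_hours", "q3_hours", "wilcoxon_p"),
      value = c(
        round_half_up(c(t$median, t$q1, t$q3), 1),
        signif(t$p_value, 3)
      )
    )
  }
  bind_rows(rows)
}

format_report <- function(report) {
  out <- c("Surveillance evaluation report", "==============================")
  g <- report$geolocation
  if (nrow(g)) {
    out <- c(out, "", "Geolocation (percent):")
    for (i in seq_len(nrow(g))) {
      out <- c(out, sprintf(
        "  %s / %s (n=%d): accuracy %.1f, sens %.1f, spec %.1f, PPV %.1f, NPV %.1f, prevalence %.1f",
        g$level[i], g$stratum[i], g$n[i], g$accuracy[i], g$sensitivity[i],
        g$specificity[i], g$ppv[i], g$npv[i], g$prevalence[i]
      ))
    }
  }
  if (nrow(report$ppv)) {
    p <- report$ppv
    out <- c(out, "", sprintf(
      "Signal review: %d events, %d false signals, %d not evaluated; PPV_s %.1f%%, PPV_g %.1f%%",
      p$n_events, p$n_false_signals, p$n_not_evaluated, p$ppv_specific, p$ppv_general
    ))
  }
  a <- report$agreement
  if (nrow(a)) {
    out <- c(out, "", "Inter-rater agreement:")
    for (i in seq_len(nrow(a))) {
      out <- c(out, sprintf(
        "  %s: %d/%d = %.1f%% (%.1f-%.1f)",
        a$arm[i], a$detected[i], a$total[i], a$ira[i], a$lower[i], a$upper[i]
      ))
    }
  }
  t <- report$timeliness
  if (nrow(t)) {
    out <- c(out, "", sprintf(
      "Timeliness (automated - manual, hours): median %.1f (IQR %.1f to %.1f, n=%d); Wilcoxon W+=%g, one-sided p=%.4g",
      t$median, t$q1, t$q3, t$n, t$statistic, t$p_value
    ))
  }
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d tweets, %d series cells, %d signals, %d alerts\n",
    nrow(x$tweets), nrow(x$counts), nrow(x$signals), nrow(x$alerts)
  ))
  invisible(x)
}
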