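# Shared text handling and bundled-resource loaders.

#' Tokenise a short text with character offsets
#'
#' Splits a post into word tokens using Unicode letter/digit runs (hyphens
#' separate tokens, so hyphenated place names match their parts), after
#' masking URLs and `@`-mentions and stripping `#` characters in place so that
#' reported offsets still index the original string. Tokens are casefolded.
#'
#' @param text A single character string (may be `NA` or empty).
#' @return A tibble with columns `token` (casefolded surface form), `start`
#'   and `end`: 0-based, half-open character offsets into `text`.
#' @export
#' @examples
#' tokenize_text("Measles outbreak in #Paris https://e.x @who")
tokenize_text <- function(text) {
  empty <- tibble(token = character(), start = integer(), end = integer())
  if (length(text) != 1L) abort("`text` must be a single string")
  if (is.na(text) || !nzchar(text)) return(empty)
  masked <- mask_pattern(text, "https?://\\S+")
  masked <- mask_pattern(masked, "(?<!\\w)@\\w+")
  masked <- gsub("#", " ", masked, fixed = TRUE)
  m <- gregexpr("[\\p{L}\\p{N}][\\p{L}\\p{N}'’]*", masked, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  tok <- stringr::str_to_lower(substring(masked, start + 1L, end))
  tibble(token = tok, start = start, end = end)
}

# Replace every match of a perl regex with spaces of equal length, so that
# character positions of the remaining text are unchanged.
mask_pattern <- function(x, pattern) {
  m <- gregexpr(pattern, x, perl = TRUE)
  regmatches(x, m) <- lapply(regmatches(x, m), function(s) strrep(" ", nchar(s)))
  x
}

ts_extdata <- function(file) {
  path <- system.file("extdata", file, package = "tweetsignal")
  if (!nzchar(path)) abort(paste0("bundled file not found: ", file))
  path
}

#' Bundled country-to-continent lookup
#'
#' ISO-3166-1 alpha-2 country codes mapped to a continent name and, for the
#' Americas, the super-region alias `"America"` so that continental and
#' pan-American series can both be aggregated.
#'
#' @return A tibble with columns `country`, `continent`, `super_region`
#'   (`NA` outside the Americas).
#' @export
country_regions <- function() {
  tab <- readr::read_csv(ts_extdata("country_continents.csv"),
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  tab$super_region[!nzchar(tab$super_region)] <- NA_character_
  tab
}

#' Bundled stop-word and common-word lists
#'
#' Plain-text, one token per line, one file per study language (English,
#' French, Spanish, Portuguese). `stop_words()` feeds top-word summaries;
#' `common_words()` supplies the non-location negatives used to train the
#' location-word classifier.
#'
#' @param languages ISO-639-1 codes; any subset of `c("en","fr","es","pt")`.
#' @return A character vector of unique, casefolded tokens.
#' @export
stop_words <- function(languages = c("en", "fr", "es", "pt")) {
  read_word_lists("stopwords_", languages)
}

#' @rdname stop_words
#' @export
common_words <- function(languages = c("en", "fr", "es", "pt")) {
  read_word_lists("common_words_", languages)
}

read_word_lists <- function(prefix, languages) {
  languages <- match.arg(languages, c("en", "fr", "es", "pt"),
    several.ok = TRUE
  )
  words <- unlist(lapply(languages, function(l) {
    readr::read_lines(ts_extdata(paste0(prefix, l, ".txt")), progress = FALSE)
  }))
  unique(stringr::str_to_lower(words[nzchar(words)]))
}

#' Path to the bundled toy gazetteer
#'
#' A 31-entry GeoNames-format dump (countries, first-level divisions and
#' cities across the four study languages) used by examples and tests.
#'
#' @return A file path.
#' @export
toy_gazetteer_path <- function() ts_extdata("toy_geonames.tsv")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_prob <- function(x) is_scalar_number(x) && x >= 0 && x <= 1
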