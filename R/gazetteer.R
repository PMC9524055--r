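# GeoNames main-dump reader.

#' Load a GeoNames-format gazetteer
#'
#' Parses the tab-delimited 19-column GeoNames main dump. The feature label is
#' derived from feature class/code: `A`/`PCL*` becomes `country`, `A`/`ADM1`
#' becomes `admin1`, class `P` becomes `populated_place`, anything else
#' `other`. Alternate names are split on commas.
#'
#' @param path Path to a GeoNames dump (the bundled toy fixture is at
#'   [toy_gazetteer_path()]).
#' @return A tibble with columns `entry_id`, `name`, `alt_names`
#'   (list-column), `country`, `admin1`, `feature`, `population`, `lat`,
#'   `lon`.
#' @export
#' @examples
#' gaz <- load_geonames(toy_gazetteer_path())
load_geonames <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      entry_id = integer(), name = character(), alt_names = list(),
      country = character(), admin1 = character(), feature = character(),
      population = numeric(), lat = numeric(), lon = numeric()
    ))
  }
  # column count from tab count (strsplit drops trailing empty fields)
  nf <- stringr::str_count(lines, stringr::fixed("\t")) + 1L
  bad <- which(nf != 19L)
  if (length(bad)) {
    abort(sprintf(
      "row %d has %d columns; expected 19 (GeoNames main dump)",
      bad[1], nf[bad[1]]
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) c(f, rep("", 19L - length(f))))
  col <- function(i) vapply(fields, `[[`, character(1), i)
  fclass <- col(7)
  fcode <- col(8)
  feature <- dplyr::case_when(
    fclass == "A" & startsWith(fcode, "PCL") ~ "country",
    fclass == "A" & fcode == "ADM1" ~ "admin1",
    fclass == "P" ~ "populated_place",
    TRUE ~ "other"
  )
  alt <- strsplit(col(4), ",", fixed = TRUE)
  alt <- lapply(alt, function(a) a[nzchar(a)])
  tibble(
    entry_id = as.integer(col(1)),
    name = col(2),
    alt_names = alt,
    country = col(9),
    admin1 = col(11),
    feature = feature,
    population = as.numeric(col(15)),
    lat = as.numeric(col(5)),
    lon = as.numeric(col(6))
  )
}
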