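#' Validate a data frame of occurrence records
#'
#' Coerces a data frame to the package's canonical occurrence tibble:
#' columns `species`, `lon`, `lat` (decimal degrees, WGS84, lon/lat order).
#' Rows with an empty species label, unparseable or out-of-range coordinates
#' are dropped with a warning (or abort under `strict = TRUE`); exact
#' duplicate (species, lon, lat) triples are collapsed to a single record —
#' a record means at least one individual collected, so multiplicity carries
#' no information for the method.
#'
#' @param df A data frame with species / longitude / latitude columns.
#' @param species,lon,lat Column names (or positions) holding the species
#'   label, longitude and latitude. Defaults `"species"`, `"lon"`, `"lat"`.
#' @param strict If `TRUE`, invalid rows abort instead of being dropped.
#' @return A tibble with columns `species` (character), `lon`, `lat`
#'   (double), one row per unique record, with a `cleaning` attribute
#'   (list: `n_input`, `n_dropped`, `n_duplicates`, `dropped` tibble).
#' @examples
#' occ <- as_occurrences(data.frame(
#'   species = c("sp1", "sp1", "sp2"), lon = c(0, 0, 10), lat = c(0, 1, 10)
#' ))
#' @export
as_occurrences <- function(df, species = "species", lon = "lon", lat = "lat",
                           strict = FALSE) {
  pick <- function(col, what) {
    if (is.numeric(col)) {
      if (col < 1 || col > ncol(df)) abort(paste0("No column ", col, " for ", what))
      return(df[[col]])
    }
    if (!col %in% names(df)) {
      abort(paste0("Column '", col, "' (", what, ") not found in input"))
    }
    df[[col]]
  }
  out <- tibble::tibble(
    species = trimws(as.character(pick(species, "species"))),
    lon = suppressWarnings(as.numeric(pick(lon, "longitude"))),
    lat = suppressWarnings(as.numeric(pick(lat, "latitude")))
  )
  bad <- is.na(out$species) | out$species == "" |
    !is.finite(out$lon) | !is.finite(out$lat) |
    out$lon < -180 | out$lon > 180 | out$lat < -90 | out$lat > 90
  dropped <- out[bad, , drop = FALSE]
  if (any(bad)) {
    msg <- paste0(sum(bad), " invalid row(s): empty species, unparseable or ",
                  "out-of-range coordinates")
    if (strict) abort(msg) else warn(paste(msg, "- dropped"))
    out <- out[!bad, , drop = FALSE]
  }
  n_before <- nrow(out)
  out <- dplyr::distinct(out, .data$species, .data$lon, .data$lat)
  n_dup <- n_before - nrow(out)
  if (n_dup > 0) inform(paste0(n_dup, " exact duplicate record(s) collapsed"))
  if (nrow(out) == 0) abort("No valid occurrence records")
  attr(out, "cleaning") <- list(
    n_input = nrow(df), n_dropped = nrow(dropped),
    n_duplicates = n_dup, dropped = dropped
  )
  out
}

#' Read a delimited occurrence table
#'
#' Reads CSV/TSV point-occurrence records and validates them with
#' [as_occurrences()]. Re-reading a table written by [write_occurrences()]
#' reproduces it exactly.
#'
#' @param path Path to a delimited text file.
#' @param species,lon,lat Column names or 1-based positions; positions are
#'   required when `header = FALSE`.
#' @param delim Field delimiter; `NULL` (default) lets `readr` guess
#'   between comma and tab.
#' @param header Does the file have a header row? Default `TRUE`.
#' @inheritParams as_occurrences
#' @return A validated occurrence tibble (see [as_occurrences()]).
#' @export
read_occurrences <- function(path, species = "species", lon = "lon",
                             lat = "lat", delim = NULL, header = TRUE,
                             strict = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim,
    col_names = header, col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  if (nrow(raw) == 0) abort("No rows in input file")
  as_occurrences(raw, species = species, lon = lon, lat = lat, strict = strict)
}

#' Write an occurrence table as CSV
#'
#' @param occ An occurrence tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  readr::write_csv(occ[c("species", "lon", "lat")], path, progress = FALSE)
  invisible(path)
}

# the record-count bins used throughout for data-profile summaries
.COUNT_BINS <- c("1", "2-15", "16-60", "61-100", ">100")

.bin_counts <- function(n) {
  cut(n, breaks = c(0, 1, 15, 60, 100, Inf), labels = .COUNT_BINS)
}

#' Record-count profile of an occurrence table
#'
#' Summarizes how records are distributed across species: per-species record
#' counts, the fraction of singleton species, and the fraction of species in
#' the count bins 1, 2–15, 16–60, 61–100, >100. The bins partition the
#' species, so the fractions always sum to 1.
#'
#' @param occ An occurrence tibble.
#' @return A tibble with one row per bin (`bin`, `n_species`, `fraction`),
#'   plus attributes `counts` (per-species tibble `species`, `n_records`)
#'   and `singleton_fraction`.
#' @export
occ_summary <- function(occ) {
  if (nrow(occ) == 0) abort("Empty occurrence table")
  counts <- dplyr::count(occ, .data$species, name = "n_records")
  bins <- tibble::tibble(bin = factor(.COUNT_BINS, levels = .COUNT_BINS)) |>
    dplyr::left_join(
      dplyr::count(counts, bin = .bin_counts(.data$n_records), name = "n_species"),
      by = "bin"
    ) |>
    dplyr::mutate(
      n_species = tidyr::replace_na(.data$n_species, 0L),
      fraction = .data$n_species / sum(.data$n_species)
    )
  attr(bins, "counts") <- counts
  attr(bins, "singleton_fraction") <- bins$fraction[1]
  bins
}
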