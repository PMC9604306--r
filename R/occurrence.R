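#' Occurrence tables
#'
#' Occurrence sets are ordinary tibbles with one row per species-labelled
#' point observation and columns `species` (character), `lat`, `lon` (decimal
#' degrees WGS84), `event_date` (`Date`), `source` (character platform tag)
#' and optionally `grade`. Two attributes ride along: `deduplicated` (logical;
#' set by [deduplicate()] and preserved by the filters) and `validation` (the
#' row-drop report from [read_occurrences()]).
#'
#' `as_occurrences()` validates and stamps a plain data frame;
#' `is_deduplicated()` reads the flag.
#'
#' @param x A data frame with at least `species`, `lat`, `lon`, `event_date`.
#' @param deduplicated Logical flag to stamp on the result.
#'
#' @return A tibble of occurrences.
#' @export
as_occurrences <- function(x, deduplicated = FALSE) {
  x <- as_tibble(x)
  required <- c("species", "lat", "lon", "event_date")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("occurrence table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"source" %in% names(x)) x$source <- NA_character_
  x$species <- trimws(as.character(x$species))
  if (!inherits(x$event_date, "Date")) x$event_date <- as.Date(x$event_date)
  bad <- !is.finite(x$lat) | !is.finite(x$lon) |
    x$lat < -90 | x$lat > 90 | x$lon < -180 | x$lon > 180 |
    is.na(x$species) | x$species == "" | is.na(x$event_date)
  if (any(bad)) {
    abort(sprintf("%d occurrence row(s) violate coordinate/species/date invariants; use read_occurrences() to drop and report them.",
                  sum(bad)))
  }
  attr(x, "deduplicated") <- isTRUE(deduplicated)
  x
}

#' @rdname as_occurrences
#' @export
is_deduplicated <- function(x) {
  isTRUE(attr(x, "deduplicated"))
}

# Subset rows of an occurrence tibble, carrying the set-level attributes that
# plain tibble subsetting would drop.
occ_subset <- function(occ, keep, deduplicated = attr(occ, "deduplicated")) {
  out <- occ[keep, , drop = FALSE]
  attr(out, "deduplicated") <- deduplicated
  attr(out, "validation") <- attr(occ, "validation")
  out
}

#' Default Darwin-Core column mapping
#'
#' Maps the required occurrence fields onto the column names used by GBIF
#' Darwin-Core exports. Override individual entries to read other dialects.
#'
#' @param species,lat,lon,event_date,source,grade Column names in the CSV.
#'   `source` and `grade` are optional: if the named column is absent the
#'   field is filled with `NA`.
#' @return A named character vector understood by [read_occurrences()].
#' @export
dwc_columns <- function(species = "scientificName",
                        lat = "decimalLatitude",
                        lon = "decimalLongitude",
                        event_date = "eventDate",
                        source = "datasetName",
                        grade = "identificationVerificationStatus") {
  c(species = species, lat = lat, lon = lon, event_date = event_date,
    source = source, grade = grade)
}

#' Read point-occurrence records from CSV
#'
#' Reads a UTF-8, comma-separated, header-row CSV of species-labelled point
#' observations (Darwin-Core column names by default), validates every row,
#' and drops rows that fail the invariants: coordinates must lie in
#' latitude \[-90, 90\] / longitude \[-180, 180\], the species name must be
#' non-empty after whitespace trimming, and the event date must parse to a
#' full ISO-8601 calendar date (year-only or year-month records are dropped,
#' since de-duplication keys on the full date). Dropped rows are counted by
#' reason in a validation report attached as the `"validation"` attribute
#' (see [validation_report()]); a warning summarises any drops.
#'
#' @param path Path to a CSV file.
#' @param columns Column mapping, as produced by [dwc_columns()].
#' @param quiet If `TRUE`, suppress the dropped-row warning.
#'
#' @return A tibble of occurrences (see [as_occurrences()]) with
#'   `deduplicated = FALSE` and a `"validation"` attribute.
#' @export
read_occurrences <- function(path, columns = dwc_columns(), quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("species", "lat", "lon", "event_date")
  missing <- setdiff(unname(columns[required]), names(raw))
  if (length(missing) > 0) {
    abort(paste0("required column(s) missing from ", path, ": ",
                 paste(missing, collapse = ", ")))
  }
  n_input <- nrow(raw)

  out <- tibble(
    species = trimws(raw[[columns[["species"]]]]),
    lat = suppressWarnings(as.numeric(raw[[columns[["lat"]]]])),
    lon = suppressWarnings(as.numeric(raw[[columns[["lon"]]]])),
    event_date_raw = raw[[columns[["event_date"]]]]
  )
  out$source <- if (columns[["source"]] %in% names(raw)) {
    raw[[columns[["source"]]]]
  } else NA_character_
  if (columns[["grade"]] %in% names(raw)) {
    out$grade <- raw[[columns[["grade"]]]]
  }

  # Full ISO dates only; anything else (year, year-month, junk) fails to parse.
  out$event_date <- as.Date(suppressWarnings(
    readr::parse_date(substr(out$event_date_raw, 1, 10), format = "%Y-%m-%d")
  ))

  bad_coord <- !is.finite(out$lat) | !is.finite(out$lon) |
    out$lat < -90 | out$lat > 90 | out$lon < -180 | out$lon > 180
  bad_species <- is.na(out$species) | out$species == ""
  bad_date <- !bad_coord & !bad_species & is.na(out$event_date)

  keep <- !(bad_coord | bad_species | is.na(out$event_date))
  report <- list(
    path = path,
    n_input = n_input,
    n_kept = sum(keep),
    n_dropped = sum(!keep),
    dropped_bad_coordinates = sum(bad_coord),
    dropped_empty_species = sum(bad_species & !bad_coord),
    dropped_unparseable_date = sum(bad_date)
  )
  if (report$n_dropped > 0 && !quiet) {
    warn(sprintf("read_occurrences: dropped %d of %d row(s) (%d bad coordinates, %d empty species, %d unparseable dates).",
                 report$n_dropped, n_input, report$dropped_bad_coordinates,
                 report$dropped_empty_species, report$dropped_unparseable_date))
  }

  out <- out[keep, c("species", "lat", "lon", "event_date",
                     intersect(c("source", "grade"), names(out)))]
  attr(out, "deduplicated") <- FALSE
  attr(out, "validation") <- report
  out
}

#' Validation report of a read
#'
#' @param occ An occurrence tibble from [read_occurrences()].
#' @return A list of row counts by drop reason, or `NULL` if `occ` was not
#'   produced by [read_occurrences()].
#' @export
validation_report <- function(occ) {
  attr(occ, "validation")
}

#' Write occurrences to CSV
#'
#' Writes the same CSV dialect that [read_occurrences()] reads, using
#' Darwin-Core column names (dates as ISO-8601), so generated or filtered
#' sets round-trip. A JSON validation report is written alongside when the
#' set carries one and `report` is `TRUE`.
#'
#' @param occ An occurrence tibble.
#' @param path Output CSV path.
#' @param columns Column mapping, as in [read_occurrences()].
#' @param report Also write `<path>.validation.json` if a report is attached.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path, columns = dwc_columns(), report = FALSE) {
  out <- tibble(
    !!columns[["species"]] := occ$species,
    !!columns[["lat"]] := occ$lat,
    !!columns[["lon"]] := occ$lon,
    !!columns[["event_date"]] := format(occ$event_date, "%Y-%m-%d")
  )
  if ("source" %in% names(occ)) out[[columns[["source"]]]] <- occ$source
  if ("grade" %in% names(occ)) out[[columns[["grade"]]]] <- occ$grade
  readr::write_csv(out, path, progress = FALSE)
  if (report && !is.null(attr(occ, "validation"))) {
    jsonlite::write_json(attr(occ, "validation"),
                         paste0(path, ".validation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Remove cross-platform duplicate records
#'
#' Community-science records reported to two platforms surface twice in a
#' combined download. A duplicate is a record identical to an earlier one in
#' the exact tuple (lat, lon, event_date, species); the first record in input
#' order is retained. The source tag is deliberately not part of the key —
#' the same observation carries a different tag on each platform.
#'
#' Coordinates are compared exactly as parsed by default. `round_coords`
#' optionally rounds coordinates to that many decimal places for the key
#' only (output coordinates are untouched), for noisy cross-platform
#' duplicates whose coordinates disagree in trailing digits.
#'
#' @param occ An occurrence tibble.
#' @param round_coords Optional integer: decimal places for the dedup key.
#' @return The occurrence tibble with duplicates removed and
#'   `deduplicated = TRUE`. Idempotent.
#' @export
deduplicate <- function(occ, round_coords = NULL) {
  key_lat <- occ$lat
  key_lon <- occ$lon
  if (!is.null(round_coords)) {
    key_lat <- round(key_lat, round_coords)
    key_lon <- round(key_lon, round_coords)
  }
  key <- paste(format(key_lat, digits = 17), format(key_lon, digits = 17),
               occ$event_date, occ$species, sep = "\r")
  occ_subset(occ, !duplicated(key), deduplicated = TRUE)
}

#' Restrict occurrences to a bounding box
#'
#' Keeps records whose coordinates fall inside `box`, with closed bounds on
#' all four edges ([bbox_contains()]). Order and the `deduplicated` flag are
#' preserved.
#'
#' @param occ An occurrence tibble.
#' @param box A [bbox()].
#' @return The filtered occurrence tibble.
#' @export
filter_bbox <- function(occ, box) {
  occ_subset(occ, bbox_contains(box, occ$lon, occ$lat))
}

#' Restrict occurrences to a date window
#'
#' Keeps records with `start <= event_date <= end` (both ends inclusive).
#' The defaults are the community-science study window of 1 January 2000 to
#' 21 June 2022.
#'
#' @param occ An occurrence tibble.
#' @param start,end Window bounds (`Date` or ISO-8601 strings).
#' @return The filtered occurrence tibble.
#' @export
filter_date_range <- function(occ, start = "2000-01-01", end = "2022-06-21") {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) abort("start and end must be valid dates.")
  if (start > end) abort("start date is after end date.")
  occ_subset(occ, occ$event_date >= start & occ$event_date <= end)
}

#' Restrict occurrences by vetting grade
#'
#' Optional convenience for sets that carry a `grade` column (e.g.
#' "research" for research-grade records): keeps records whose grade is in
#' `grades`. Sets without a `grade` column pass through unchanged.
#'
#' @param occ An occurrence tibble.
#' @param grades Character vector of grades to keep.
#' @return The filtered occurrence tibble.
#' @export
filter_grade <- function(occ, grades = "research") {
  if (!"grade" %in% names(occ)) return(occ)
  occ_subset(occ, !is.na(occ$grade) & occ$grade %in% grades)
}
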