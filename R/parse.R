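# Parsing and validation of DIISE-dialect event tables.

# logical field -> default column header (canonical dialect)
canonical_columns <- function() {
  flds <- event_fields()
  setNames(flds, flds)
}

event_fields <- function() {
  c("island_id", "island_name", "country", "area_ha", "habitation",
    "target_species", "status", "end_year", "primary_method",
    "data_quality", "whole_island", "feral", "purpose_eradication")
}

habitation_levels <- function() {
  c("0", "1-10", "11-100", "101-1000", "1001-10000", ">10000", "not_found")
}

method_levels <- function() c("Tx", "Tr", "H", "O", "unknown")

#' Read a column map from a plain-text config
#'
#' The config is a YAML-style `logical_field: column header` mapping binding
#' the canonical event fields to the headers used by a particular CSV export.
#' Fields absent from the file keep their canonical header.
#'
#' @param path path to the config file.
#' @return Named character vector: names are logical fields, values headers.
#' @export
read_column_map <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw) || is.null(names(raw))) {
    stop("column map must be a key: value mapping")
  }
  bad <- setdiff(names(raw), event_fields())
  if (length(bad)) stop("unknown logical fields in column map: ",
                        paste(bad, collapse = ", "))
  cm <- canonical_columns()
  cm[names(raw)] <- vapply(raw, as.character, character(1))
  cm
}

parse_bool <- function(x) {
  key <- normalize_token(x)
  out <- rep(NA, length(x))
  out[key %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[key %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

parse_habitation <- function(x) {
  key <- gsub("–", "-", trimws(as.character(x)))  # en-dash exports
  key <- gsub(",", "", key)
  key[normalize_token(key) %in% c("not found", "notfound", "na", "")] <- "not_found"
  key <- gsub("[[:space:]]", "", key)
  key[key == "1001-10,000"] <- "1001-10000"
  ifelse(key %in% habitation_levels(), key, NA_character_)
}

#' Parse a DIISE-dialect event CSV
#'
#' Reads a comma-delimited UTF-8 table with a header row, maps columns to the
#' canonical event fields via `column_map`, and validates each row. Rows with
#' unparseable or out-of-range values (negative areas, years outside
#' 1800--2030, unknown statuses/methods/quality codes) are excluded from the
#' returned event collection and recorded as row-level issues -- never
#' silently dropped or coerced.
#'
#' @param path path to the CSV file (or a connection).
#' @param column_map named character vector (logical field -> column header)
#'   or path to a column-map config; `NULL` uses canonical headers.
#' @param strict if `TRUE` (default), a status string outside the documented
#'   alias table is a hard error; if `FALSE` the row is dropped with an issue.
#' @return A list with `events` (tibble of valid [event rows]) and `issues`
#'   (tibble with `row`, `field`, `value`, `message`).
#' @export
parse_events <- function(path, column_map = NULL, strict = TRUE) {
  if (is.character(column_map) && length(column_map) == 1 &&
      is.null(names(column_map)) && file.exists(column_map)) {
    column_map <- read_column_map(column_map)
  }
  cm <- canonical_columns()
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), event_fields())
    if (length(bad)) stop("unknown logical fields in column map: ",
                          paste(bad, collapse = ", "))
    cm[names(column_map)] <- column_map
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("empty event file: ", paste(path, collapse = ""))
  missing_cols <- cm[!cm %in% names(raw)]
  # optional context columns may be absent; the core record fields may not
  mandatory <- setdiff(event_fields(), c("island_name"))
  missing_mand <- intersect(names(missing_cols), mandatory)
  if (length(missing_mand)) {
    stop("missing mandatory columns: ",
         paste(sprintf("%s (header '%s')", missing_mand, cm[missing_mand]),
               collapse = ", "))
  }

  n <- nrow(raw)
  get <- function(field) {
    if (cm[[field]] %in% names(raw)) raw[[cm[[field]]]] else rep(NA_character_, n)
  }
  issues <- list()
  note <- function(rows, field, values, message) {
    if (!length(rows)) return()
    issues[[length(issues) + 1L]] <<- tibble(
      row = rows, field = field, value = as.character(values), message = message)
  }

  area_raw <- get("area_ha")
  area <- suppressWarnings(as.numeric(area_raw))
  bad_area <- which(is.na(area) | area < 0)
  note(bad_area, "area_ha", area_raw[bad_area],
       "area must be a non-negative number of hectares")

  year_raw <- get("end_year")
  year_missing <- is.na(year_raw) | trimws(year_raw) == "" |
    normalize_token(year_raw) == "na"
  year <- suppressWarnings(as.integer(year_raw))
  bad_year <- which(!year_missing & (is.na(year) | year < 1800 | year > 2030))
  note(bad_year, "end_year", year_raw[bad_year],
       "end year must be a calendar year in [1800, 2030] or missing")
  year[year_missing] <- NA_integer_

  status_raw <- get("status")
  status <- canonical_status(status_raw)
  bad_status <- which(is.na(status))
  if (length(bad_status) && strict) {
    stop("unrecognized status value(s): ",
         paste(unique(status_raw[bad_status]), collapse = ", "),
         " (rows ", paste(head(bad_status, 5), collapse = ", "), ")")
  }
  note(bad_status, "status", status_raw[bad_status],
       "status not in the documented alias table")

  quality <- normalize_token(get("data_quality"))
  bad_quality <- which(!quality %in% c("good", "satisfactory", "poor"))
  note(bad_quality, "data_quality", get("data_quality")[bad_quality],
       "data quality must be good, satisfactory, or poor")

  method_raw <- trimws(get("primary_method"))
  method <- ifelse(method_raw %in% method_levels(), method_raw, NA_character_)
  method[is.na(method) & normalize_token(method_raw) %in%
           c("", "na", "unknown")] <- "unknown"
  bad_method <- which(is.na(method))
  note(bad_method, "primary_method", method_raw[bad_method],
       "primary method must be one of Tx, Tr, H, O, unknown")

  habitation <- parse_habitation(get("habitation"))
  bad_hab <- which(is.na(habitation))
  note(bad_hab, "habitation", get("habitation")[bad_hab],
       "habitation must be one of the ordinal bins or not_found")

  bools <- lapply(c("whole_island", "purpose_eradication"),
                  function(f) parse_bool(get(f)))
  names(bools) <- c("whole_island", "purpose_eradication")
  for (f in names(bools)) {
    bad <- which(is.na(bools[[f]]))
    note(bad, f, get(f)[bad], "must be a true/false value")
  }

  # feral accepts true/false and the textual population labels; semi-feral
  # and feral populations count as feral, domestic as not
  feral_raw <- normalize_token(get("feral"))
  feral <- parse_bool(get("feral"))
  feral[feral_raw %in% c("feral", "semi feral", "semiferal")] <- TRUE
  feral[feral_raw == "domestic"] <- FALSE
  bad_feral <- which(is.na(feral))
  note(bad_feral, "feral", get("feral")[bad_feral],
       "must be true/false or feral/semi-feral/domestic")
  bools$feral <- feral

  issues <- if (length(issues)) bind_rows(issues) else
    tibble(row = integer(), field = character(), value = character(),
           message = character())
  issues <- issues[order(issues$row), , drop = FALSE]
  bad_rows <- unique(issues$row)

  events <- tibble(
    island_id = trimws(get("island_id")),
    island_name = trimws(get("island_name")),
    country = toupper(trimws(get("country"))),
    area_ha = area,
    habitation = habitation,
    target_species = trimws(get("target_species")),
    status = status,
    end_year = year,
    primary_method = method,
    data_quality = quality,
    whole_island = bools$whole_island,
    feral = bools$feral,
    purpose_eradication = bools$purpose_eradication
  )
  if (length(bad_rows)) events <- events[-bad_rows, , drop = FALSE]
  list(events = events, issues = as_tibble(issues))
}

#' Write events in the canonical CSV dialect
#'
#' Writes an event collection with canonical column names so that
#' [parse_events()] round-trips it field-by-field.
#'
#' @param events event tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- events[, intersect(event_fields(), names(events)), drop = FALSE]
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
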