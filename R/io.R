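# column alias map: canonical name -> accepted spellings (matched after
# lower-casing and stripping non-alphanumerics)
HERD_ALIASES <- list(
  tmr_dm_pct = c("tmr_dm_pct", "tmrdmpct", "tmrdrymatter", "tmrdrymatterpct",
                 "tmrdrymatterdm", "tmr", "drymatterratio"),
  lactation_number = c("lactationnumber", "lactationno", "parity"),
  lactation_day = c("lactationday", "lactationdaynumber", "daysinmilk", "dim"),
  gestation_day = c("gestationday", "gestationdaynumber", "pregnancyday",
                    "pregnancydaynumber"),
  age_months = c("agemonths", "age", "agemonth", "cowage"),
  temperature_c = c("temperaturec", "temperature", "airtemperature", "temp"),
  milk_yield = c("milkyield", "milkyieldl", "dailymilkyield", "milk"),
  dm_intake = c("dmintake", "drymatterintake", "drymatter", "dm",
                "dmintakeunits")
)

normalise_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a herd-record CSV
#'
#' Reads a CSV of cow-day records, matching headers against the
#' canonical column names case-insensitively through a documented alias
#' map (e.g. `"Daily Milk Yield"` -> `milk_yield`). Parsing uses the
#' `.` decimal point regardless of locale. Unknown extra columns are
#' kept and flagged with a warning; a missing required column or a
#' non-numeric cell is an error naming the offender.
#'
#' @param path CSV file path (header row required).
#' @param required Canonical columns that must be present; default all
#'   eight (see [herd_columns()]).
#' @return A tibble with canonical column names first.
#' @export
read_herd_records <- function(path, required = herd_columns()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         locale = readr::locale(decimal_mark = "."),
                         name_repair = "minimal")
  norm <- normalise_header(names(raw))
  canon <- names(raw)
  for (target in names(HERD_ALIASES)) {
    hit <- which(norm %in% normalise_header(HERD_ALIASES[[target]]))
    if (length(hit) >= 1L) canon[hit[1]] <- target
  }
  names(raw) <- canon
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(raw), names(HERD_ALIASES))
  if (length(extra)) {
    warn(paste0("ignoring unrecognised column(s): ",
                paste(extra, collapse = ", ")))
  }
  for (col in intersect(names(HERD_ALIASES), names(raw))) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad)) {
        abort(sprintf("non-numeric value '%s' in column '%s', row %d",
                      v[bad[1]], col, bad[1]))
      }
      raw[[col]] <- parsed
    }
    if (anyNA(raw[[col]])) {
      abort(sprintf("missing value in column '%s', row %d",
                    col, which(is.na(raw[[col]]))[1]))
    }
  }
  dplyr::relocate(as_tibble(raw),
                  dplyr::any_of(names(HERD_ALIASES)))
}

#' Write a herd-record table as CSV
#'
#' RFC-4180 CSV, UTF-8, `.` decimal point, canonical column names.
#'
#' @param table Herd-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_herd_records <- function(table, path) {
  readr::write_csv(as_tibble(table), path, progress = FALSE)
  invisible(path)
}
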