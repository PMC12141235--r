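#' Packaged name dictionaries and geographic reference
#'
#' `vegetable_dictionary()` and `pesticide_dictionary()` return the packaged
#' synonym tables (columns `alias`, `canonical`) used to harmonize free-text
#' names from heterogeneous provincial disclosures into one canonical
#' vocabulary. `province_capitals()` returns the provincial capital
#' coordinates (decimal degrees) used as geographic reference points for the
#' spatial centre-of-gravity analysis.
#'
#' The dictionaries are deliberately editable inputs, not an implementation
#' of the national fresh-vegetable classification standard: pass your own
#' table with the same columns to extend coverage.
#'
#' @return A tibble.
#' @name reference-tables
NULL

#' @rdname reference-tables
#' @export
vegetable_dictionary <- function() {
  readr::read_csv(vegrisk_example("vegetable_synonyms.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference-tables
#' @export
pesticide_dictionary <- function() {
  readr::read_csv(vegrisk_example("pesticide_synonyms.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference-tables
#' @export
province_capitals <- function() {
  read_geo_table(vegrisk_example("province_capitals.csv"))
}

#' Canonicalize vegetable or pesticide names
#'
#' Maps raw names onto a canonical vocabulary through a synonym dictionary.
#' Matching is case- and whitespace-insensitive. Names absent from the
#' dictionary are returned as `NA` (an explicit "unmapped" marker), never
#' passed through silently; the mapping is idempotent on its own output.
#'
#' @param x Character vector of raw names.
#' @param dictionary A data frame with columns `alias` and `canonical`, or
#'   `NULL` to accept any non-empty name as already canonical (after case
#'   and whitespace normalization).
#' @return Character vector of canonical names, `NA` where unmapped.
#' @export
#' @examples
#' canonicalize_names(c("Chilli", "tomatoes", "dragonfruit"),
#'                    vegetable_dictionary())
canonicalize_names <- function(x, dictionary = vegetable_dictionary()) {
  key <- squish_name(x)
  if (is.null(dictionary)) {
    return(key)
  }
  stopifnot(all(c("alias", "canonical") %in% names(dictionary)))
  map <- setNames(squish_name(dictionary$canonical),
                  squish_name(dictionary$alias))
  out <- unname(map[key])
  # canonical names map to themselves even when not listed as an alias
  self <- is.na(out) & key %in% map
  out[self] <- key[self]
  out
}

# supported concentration unit dialects -> factor to mg/kg
unit_to_mg_per_kg <- function(unit) {
  u <- squish_name(unit)
  u <- gsub("µ|μ", "u", u)   # micro sign / mu -> "u"
  factor <- rep(NA_real_, length(u))
  factor[u %in% c("mg/kg", "mg kg-1", "ppm")] <- 1
  factor[u %in% c("ug/kg", "ug kg-1")] <- 1e-3
  factor
}

#' Normalize residue concentrations to mg/kg
#'
#' Converts detected concentrations to mg/kg. Supported unit dialects are
#' `mg/kg` (and `ppm`, identical for a mass fraction) and `ug/kg`
#' (mu-spelled variants included). Any other unit yields `NA` with a
#' warning: silent guessing would corrupt the audit trail, so unknown units
#' are a counted, row-level drop upstream.
#'
#' @param value Numeric concentrations.
#' @param unit Character vector of unit strings, recycled if length 1.
#' @return Numeric vector in mg/kg (`NA` for unsupported units).
#' @export
#' @examples
#' normalize_concentration(c(0.5, 500, 2), c("mg/kg", "μg/kg", "ppm"))
normalize_concentration <- function(value, unit) {
  if (length(unit) == 1) unit <- rep(unit, length(value))
  stopifnot(length(value) == length(unit))
  factor <- unit_to_mg_per_kg(unit)
  bad <- !is.na(unit) & is.na(factor)
  if (any(bad)) {
    warn(paste0("unsupported concentration unit(s): ",
                paste(unique(unit[bad]), collapse = ", ")))
  }
  as.numeric(value) * factor
}

#' Clean and harmonize raw inspection rows
#'
#' Core cleaning engine behind [read_inspection_records()], usable directly
#' on an in-memory table (e.g. the synthetic generator's output). One input
#' row is one (batch, pesticide) measurement; rows sharing a `batch_id`
#' form one sampled batch, and a row with an empty pesticide and
#' concentration records a batch with no detected residue.
#'
#' Cleaning rules, each drop counted once under the first failing rule:
#' rows missing a required field, with exactly one of pesticide and
#' concentration present, or with a negative concentration are dropped as
#' missing/invalid; years outside `study_years` are dropped; names that the
#' dictionaries cannot map are dropped (never silently passed through);
#' unknown concentration units are dropped with a warning. Units are
#' normalized to mg/kg. Optionally, measurements whose concentration-to-MRL
#' ratio exceeds `outlier_cap` are dropped as extreme outliers; this rule is
#' off by default because no published rule defines "extreme", and data are
#' never altered silently.
#'
#' The returned records carry a cleaning report (see [cleaning_report()])
#' whose counts always reconcile: `n_read = n_kept + sum of drops`.
#' A `batch_id` observed with more than one (province, vegetable, year) is
#' an error: sampling protocols guarantee batch non-duplication.
#'
#' @param data A data frame with columns `province`, `vegetable`, `year`,
#'   `batch_id`, `pesticide`, `concentration`, `unit` (rename via `schema`).
#' @param schema Optional named character vector mapping those standard
#'   names to the columns actually present, e.g.
#'   `c(batch_id = "sample_no")`.
#' @param vegetable_synonyms,pesticide_synonyms Synonym dictionaries passed
#'   to [canonicalize_names()]; `NULL` accepts any non-empty name.
#' @param study_years Years retained (default 2021:2023); `NULL` keeps all.
#' @param outlier_cap Optional maximum concentration/MRL ratio; requires
#'   `mrl`.
#' @param mrl MRL table (see [read_mrl_table()]), only used by the outlier
#'   rule.
#' @return A tibble of cleaned measurements (`province`, `vegetable`,
#'   `year`, `batch_id`, `pesticide`, `concentration` in mg/kg) with
#'   attribute `cleaning_report`.
#' @export
clean_inspection_records <- function(data,
                                     schema = NULL,
                                     vegetable_synonyms = vegetable_dictionary(),
                                     pesticide_synonyms = pesticide_dictionary(),
                                     study_years = 2021:2023,
                                     outlier_cap = NULL,
                                     mrl = NULL) {
  std <- c("province", "vegetable", "year", "batch_id",
           "pesticide", "concentration", "unit")
  if (!is.null(schema)) {
    for (nm in names(schema)) {
      if (!schema[[nm]] %in% names(data)) {
        abort(paste0("schema column not found: ", schema[[nm]]))
      }
      names(data)[names(data) == schema[[nm]]] <- nm
    }
  }
  missing_cols <- setdiff(std, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("required column(s) missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(outlier_cap) && is.null(mrl)) {
    abort("outlier_cap requires an `mrl` table")
  }

  d <- tibble::as_tibble(data)[std]
  n_read <- nrow(d)
  d$province <- squish_name(d$province)
  d$year <- suppressWarnings(as.integer(d$year))
  d$batch_id <- as.character(d$batch_id)
  d$batch_id[!is.na(d$batch_id) & !nzchar(trimws(d$batch_id))] <- NA
  pest_raw <- squish_name(d$pesticide)
  conc_raw <- suppressWarnings(as.numeric(d$concentration))
  has_pest <- !is.na(pest_raw)
  has_conc <- !is.na(conc_raw)

  drop <- rep(NA_character_, n_read)
  mark <- function(cond, reason) {
    hit <- is.na(drop) & cond
    drop[hit] <<- reason
  }
  mark(is.na(d$province) | is.na(d$vegetable) | is.na(d$year) |
         is.na(d$batch_id), "missing")
  mark(xor(has_pest, has_conc), "missing")
  mark(has_conc & conc_raw < 0, "missing")
  if (!is.null(study_years)) {
    mark(!d$year %in% study_years, "out_of_window")
  }

  veg_canon <- canonicalize_names(d$vegetable, vegetable_synonyms)
  pest_canon <- canonicalize_names(pest_raw, pesticide_synonyms)
  mark(is.na(veg_canon) & !is.na(squish_name(d$vegetable)), "unmapped_name")
  mark(has_pest & is.na(pest_canon), "unmapped_name")

  factor <- unit_to_mg_per_kg(d$unit)
  bad_unit <- has_conc & is.na(factor)
  if (any(bad_unit & is.na(drop))) {
    warn(paste0("dropping ", sum(bad_unit & is.na(drop)),
                " row(s) with unsupported concentration unit"))
  }
  mark(bad_unit, "bad_unit")
  conc_mg <- conc_raw * factor

  n_outlier <- 0L
  if (!is.null(outlier_cap)) {
    lim <- dplyr::select(tibble::as_tibble(mrl), "vegetable", "pesticide",
                         "mrl_mg_per_kg")
    key <- tibble::tibble(vegetable = veg_canon, pesticide = pest_canon,
                          conc = conc_mg)
    key <- dplyr::left_join(key, lim, by = c("vegetable", "pesticide"))
    extreme <- !is.na(key$conc) & !is.na(key$mrl_mg_per_kg) &
      key$conc / key$mrl_mg_per_kg > outlier_cap
    mark(extreme, "outlier")
  }

  keep <- is.na(drop)
  out <- tibble::tibble(
    province = d$province[keep],
    vegetable = veg_canon[keep],
    year = d$year[keep],
    batch_id = d$batch_id[keep],
    pesticide = pest_canon[keep],
    concentration = conc_mg[keep]
  )

  dup <- dplyr::distinct(out, .data$batch_id, .data$province,
                         .data$vegetable, .data$year)
  dup <- dup$batch_id[duplicated(dup$batch_id)]
  if (length(dup) > 0) {
    abort(paste0("batch_id assigned to more than one batch: ",
                 paste(head(unique(dup), 5), collapse = ", ")))
  }

  report <- tibble::tibble(
    n_read = n_read,
    n_kept = nrow(out),
    n_dropped_missing = sum(drop == "missing", na.rm = TRUE),
    n_dropped_unmapped_name = sum(drop == "unmapped_name", na.rm = TRUE),
    n_dropped_bad_unit = sum(drop == "bad_unit", na.rm = TRUE),
    n_dropped_out_of_window = sum(drop == "out_of_window", na.rm = TRUE),
    n_dropped_outlier = sum(drop == "outlier", na.rm = TRUE),
    n_unit_converted = sum(keep & !is.na(factor) & factor != 1 & has_conc)
  )
  attr(out, "cleaning_report") <- report
  class(out) <- c("vegrisk_records", class(out))
  out
}

#' Read inspection records from a delimited file
#'
#' Reads a delimiter-separated inspection-record table (one row per batch ×
#' pesticide measurement) and applies the full cleaning protocol of
#' [clean_inspection_records()], which documents the row dialect, cleaning
#' rules and report.
#'
#' @param path Path to the table file.
#' @param delim Field delimiter (default comma).
#' @inheritParams clean_inspection_records
#' @param ... Passed on to [clean_inspection_records()].
#' @return A tibble of cleaned measurements with a `cleaning_report`
#'   attribute.
#' @export
read_inspection_records <- function(path, delim = ",", ...) {
  if (!file.exists(path)) {
    abort(paste0("inspection record file not found: ", path))
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  clean_inspection_records(raw, ...)
}

#' Retrieve the cleaning report of a record set
#'
#' @param records Records returned by [read_inspection_records()] or
#'   [clean_inspection_records()].
#' @return A one-row tibble of row counts; `n_read` always equals `n_kept`
#'   plus the sum of the drop counters.
#' @export
cleaning_report <- function(records) {
  rep <- attr(records, "cleaning_report")
  if (is.null(rep)) abort("no cleaning report attached to this object")
  rep
}

#' Write cleaned inspection records back to disk
#'
#' Emits the same row dialect [read_inspection_records()] consumes
#' (canonical names, all concentrations in mg/kg), so a write/read
#' round-trip reproduces the record set exactly.
#'
#' @param records Cleaned records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_inspection_records <- function(records, path) {
  out <- tibble::as_tibble(records)
  out$unit <- ifelse(is.na(out$concentration), "", "mg/kg")
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a maximum residue limit (MRL) table
#'
#' The table is keyed by (vegetable, pesticide) and gives the legal limit in
#' mg/kg plus a banned flag. Banned pesticides may lack a limit (any
#' detection is then a violation); a present limit must be positive.
#'
#' @param path Path to a delimited file with columns `vegetable`,
#'   `pesticide`, `mrl_mg_per_kg` (blank allowed), `banned` (0/1).
#' @param delim Field delimiter.
#' @return A tibble with columns `vegetable`, `pesticide`, `mrl_mg_per_kg`,
#'   `banned`.
#' @export
read_mrl_table <- function(path, delim = ",") {
  if (!file.exists(path)) abort(paste0("MRL table not found: ", path))
  d <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    vegetable = readr::col_character(),
    pesticide = readr::col_character(),
    mrl_mg_per_kg = readr::col_double(),
    banned = readr::col_character()
  ), progress = FALSE)
  validate_mrl_table(d)
}

validate_mrl_table <- function(d) {
  d <- tibble::as_tibble(d)
  need <- c("vegetable", "pesticide", "mrl_mg_per_kg", "banned")
  if (!all(need %in% names(d))) {
    abort(paste0("MRL table must have columns: ", paste(need, collapse = ", ")))
  }
  d$vegetable <- squish_name(d$vegetable)
  d$pesticide <- squish_name(d$pesticide)
  # accept 0/1, TRUE/FALSE and yes/no spellings of the banned flag
  if (is.character(d$banned)) {
    d$banned <- squish_name(d$banned) %in% c("1", "true", "t", "yes")
  } else {
    d$banned <- !is.na(d$banned) & as.logical(d$banned)
  }
  if (any(is.na(d$banned))) abort("banned flag must be 0/1")
  if (any(!is.na(d$mrl_mg_per_kg) & d$mrl_mg_per_kg <= 0)) {
    abort("MRL values must be positive when present")
  }
  if (any(is.na(d$mrl_mg_per_kg) & !d$banned)) {
    abort("only banned pesticides may lack an MRL")
  }
  d[c("vegetable", "pesticide", "mrl_mg_per_kg", "banned")]
}

#' Read a province-to-capital coordinate table
#'
#' @param path Path to a delimited file with columns `province`,
#'   `longitude_e`, `latitude_n` (decimal degrees).
#' @param delim Field delimiter.
#' @return A tibble with validated coordinate ranges.
#' @export
read_geo_table <- function(path, delim = ",") {
  if (!file.exists(path)) abort(paste0("geo table not found: ", path))
  d <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    province = readr::col_character(),
    longitude_e = readr::col_double(),
    latitude_n = readr::col_double()
  ), progress = FALSE)
  d$province <- squish_name(d$province)
  if (any(abs(d$longitude_e) > 180 | abs(d$latitude_n) > 90)) {
    abort("coordinates out of range: longitude in [-180, 180], latitude in [-90, 90]")
  }
  d
}

#' Bind each measurement to its residue limit
#'
#' Left-joins the MRL table onto the measurement rows by (vegetable,
#' pesticide) and classifies every measurement into one binding state:
#' `"limit"` (a numeric MRL applies), `"banned"` (banned pesticide with no
#' limit — any detection violates), `"no_limit"` (pesticide absent from the
#' table; the compliance policy decides), or `"none"` (a batch row with no
#' detection). Nothing is dropped here; unmatched measurements are flagged
#' for the compliance module.
#'
#' @param records Cleaned measurement rows.
#' @param mrl_table An MRL table (see [read_mrl_table()]).
#' @return `records` with added columns `mrl`, `banned`, `binding`.
#' @export
match_mrl <- function(records, mrl_table) {
  mrl_table <- validate_mrl_table(mrl_table)
  out <- dplyr::left_join(
    tibble::as_tibble(records),
    dplyr::rename(mrl_table, mrl = "mrl_mg_per_kg"),
    by = c("vegetable", "pesticide")
  )
  out$banned <- !is.na(out$banned) & out$banned
  out$binding <- dplyr::case_when(
    is.na(out$pesticide) ~ "none",
    !is.na(out$mrl) ~ "limit",
    out$banned ~ "banned",
    TRUE ~ "no_limit"
  )
  out
}
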