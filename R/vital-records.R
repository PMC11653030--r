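# Domain schemas and delimited-text IO for vital-statistics records and
# hospital episodes. Files are comma-separated UTF-8 with a header; dates are
# ISO-8601; the missing-value token is the empty string; zip codes are kept
# as strings to preserve leading zeros. Multi-valued ICD code fields are
# semicolon-separated with a per-code system prefix, e.g.
# "icd10:O24.4;icd9:6480".

PAYER_LEVELS <- c("private", "public", "self_pay", "other", "unknown")
RACE_LEVELS <- c(
  "amer_indian_alaska_native", "asian", "black", "hawaiian_pacific_islander",
  "hispanic", "white_nh", "other", "multiple", "unknown"
)
SEX_LEVELS <- c("M", "F", "unknown")
PLURALITY_LEVELS <- c("singleton", "twin", "multiple")
EDUCATION_LEVELS <- c("lt12", "12", "gt12", "unknown")

dict_row <- function(name, type, allowed = NULL, required = FALSE) {
  tibble(name = name, type = type, allowed = list(allowed), required = required)
}

#' Column dictionaries for the packaged schemas
#'
#' A column dictionary is a tibble with one row per column giving its name,
#' type (`string`, `integer`, `date`, `logical`, `category`, `codes`),
#' allowed values for categories, and whether a non-missing value is
#' required. Readers validate files against it; writers emit files that
#' round-trip losslessly through the matching reader.
#'
#' @return A tibble with columns `name`, `type`, `allowed`, `required`.
#' @export
vital_dictionary <- function() {
  bind_rows(
    dict_row("record_id", "string", required = TRUE),
    dict_row("year", "integer", required = TRUE),
    dict_row("is_fetal_death", "logical", required = TRUE),
    dict_row("mother_dob", "date"),
    dict_row("infant_dob", "date", required = TRUE),
    dict_row("hospital_id", "string"),
    dict_row("zip", "string"),
    dict_row("county", "string"),
    dict_row("payer", "category", PAYER_LEVELS),
    dict_row("race_eth", "category", RACE_LEVELS),
    dict_row("infant_sex", "category", SEX_LEVELS),
    dict_row("gestational_age_wk", "integer"),
    dict_row("birthweight_g", "integer"),
    dict_row("plurality", "category", PLURALITY_LEVELS, required = TRUE),
    dict_row("birth_order", "integer", required = TRUE),
    dict_row("cesarean", "logical"),
    dict_row("previous_cesarean", "logical"),
    dict_row("sga_lga", "logical"),
    dict_row("infant_death", "logical"),
    dict_row("gestational_diabetes", "logical"),
    dict_row("preexisting_diabetes", "logical"),
    dict_row("prepregnancy_hypertension", "logical"),
    dict_row("gestational_hypertension", "logical"),
    dict_row("eclampsia", "logical"),
    dict_row("placental_abruption", "logical"),
    dict_row("chorioamnionitis", "logical"),
    dict_row("neural_tube_defect", "logical"),
    dict_row("gastroschisis_omphalocele", "logical"),
    dict_row("cleft_lip_palate", "logical"),
    dict_row("major_heart_defect", "logical"),
    dict_row("education_yrs", "category", EDUCATION_LEVELS),
    dict_row("mother_age_yrs", "integer"),
    dict_row("sibling_set_id", "string", required = TRUE)
  )
}

#' @rdname vital_dictionary
#' @export
hospital_dictionary <- function() {
  bind_rows(
    dict_row("episode_id", "string", required = TRUE),
    dict_row("person_role", "category", c("mother", "infant", "unknown")),
    dict_row("record_type", "category", c("PDD", "ED", "AS"), required = TRUE),
    dict_row("hospital_id", "string"),
    dict_row("admit_date", "date", required = TRUE),
    dict_row("discharge_date", "date", required = TRUE),
    dict_row("patient_dob", "date"),
    dict_row("zip", "string"),
    dict_row("county", "string"),
    dict_row("payer", "category", PAYER_LEVELS),
    dict_row("race_eth", "category", RACE_LEVELS),
    dict_row("sex", "category", SEX_LEVELS),
    dict_row("diagnosis_codes", "codes"),
    dict_row("procedure_codes", "codes"),
    dict_row("mdc", "integer"),
    dict_row("discharge_status", "category", c("routine", "died", "other")),
    dict_row("enc_ssn", "string"),
    dict_row("age_at_admission_yrs", "integer")
  )
}

parse_column <- function(x, type, allowed) {
  x[!is.na(x) & x == ""] <- NA_character_
  bad <- rep(FALSE, length(x))
  val <- switch(type,
    string = x,
    codes = {
      ok <- is.na(x) |
        vapply(strsplit(x, ";", fixed = TRUE), function(toks) {
          all(grepl("^icd(9|10):\\S+", trimws(toks)))
        }, TRUE)
      bad <- !ok
      x
    },
    integer = {
      v <- suppressWarnings(as.integer(x))
      bad <- !is.na(x) & is.na(v)
      v
    },
    date = {
      v <- as.Date(rep(NA, length(x)))
      has <- !is.na(x)
      ok <- has & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
      v[ok] <- suppressWarnings(as.Date(x[ok], format = "%Y-%m-%d"))
      bad <- has & (!ok | (ok & is.na(v)))
      v
    },
    logical = {
      lo <- tolower(x)
      v <- ifelse(lo %in% c("true", "1"), TRUE,
        ifelse(lo %in% c("false", "0"), FALSE, NA)
      )
      bad <- !is.na(x) & is.na(v)
      v
    },
    category = {
      bad <- !is.na(x) & !(x %in% allowed)
      ifelse(bad, NA_character_, x)
    },
    abort(paste0("unknown column type '", type, "'"))
  )
  list(value = val, bad = bad)
}

read_records <- function(path, dictionary, strict = FALSE, what = "record") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(dictionary$name, names(raw))
  unknown_cols <- setdiff(names(raw), dictionary$name)
  if (length(missing_cols) || length(unknown_cols)) {
    abort(paste0(
      "schema mismatch in ", path,
      if (length(missing_cols)) paste0("; missing: ", toString(missing_cols)) else "",
      if (length(unknown_cols)) paste0("; unknown: ", toString(unknown_cols)) else ""
    ))
  }

  out <- vector("list", nrow(dictionary))
  names(out) <- dictionary$name
  diags <- list()
  for (i in seq_len(nrow(dictionary))) {
    col <- dictionary$name[i]
    p <- parse_column(raw[[col]], dictionary$type[i], dictionary$allowed[[i]])
    req_bad <- dictionary$required[i] & is.na(p$value) & !p$bad
    for (r in which(p$bad)) {
      diags[[length(diags) + 1L]] <- tibble(
        row = r, column = col, value = raw[[col]][r],
        problem = paste0("unparseable ", dictionary$type[i])
      )
    }
    for (r in which(req_bad)) {
      diags[[length(diags) + 1L]] <- tibble(
        row = r, column = col, value = "",
        problem = "required value missing"
      )
    }
    p$bad <- p$bad | req_bad
    out[[col]] <- p
  }
  diagnostics <- if (length(diags)) bind_rows(diags) else {
    tibble(row = integer(), column = character(), value = character(), problem = character())
  }

  id_col <- dictionary$name[1]
  ids <- out[[id_col]]$value
  dup <- !is.na(ids) & duplicated(ids)
  for (r in which(dup)) {
    diagnostics <- bind_rows(diagnostics, tibble(
      row = r, column = id_col, value = ids[r], problem = "duplicate id"
    ))
  }

  if (strict && nrow(diagnostics) > 0) {
    abort(paste0(
      "validation failed for ", path, " (", nrow(diagnostics), " problem",
      if (nrow(diagnostics) > 1) "s" else "", "); first: row ",
      diagnostics$row[1], " column ", diagnostics$column[1], ": ",
      diagnostics$problem[1]
    ))
  }

  bad_rows <- sort(unique(diagnostics$row))
  tbl <- as_tibble(purrr::map(out, "value"))
  if (length(bad_rows)) tbl <- tbl[-bad_rows, , drop = FALSE]
  attr(tbl, "diagnostics") <- diagnostics
  tbl
}

#' Read a vital-statistics file
#'
#' Parses and validates a delimited vital-records file against a column
#' dictionary. In lenient mode (default) rows violating the dictionary are
#' dropped and reported in the `diagnostics` attribute (a tibble of row,
#' column, offending value and problem); in strict mode any violation is an
#' error. Unknown or missing columns are always a schema error.
#'
#' @param path CSV file path.
#' @param dictionary Column dictionary, default [vital_dictionary()].
#' @param strict Fail on any row-level problem (default `FALSE`).
#' @return Tibble of vital records with typed columns; row diagnostics in
#'   `attr(, "diagnostics")`.
#' @export
read_vital_file <- function(path, dictionary = vital_dictionary(), strict = FALSE) {
  read_records(path, dictionary, strict, "vital record")
}

#' Read a hospital-episode file
#'
#' @inheritParams read_vital_file
#' @return Tibble of hospital episodes; row diagnostics in
#'   `attr(, "diagnostics")`.
#' @export
read_hospital_file <- function(path, dictionary = hospital_dictionary(), strict = FALSE) {
  tbl <- read_records(path, dictionary, strict, "hospital episode")
  swap <- !is.na(tbl$admit_date) & !is.na(tbl$discharge_date) &
    tbl$admit_date > tbl$discharge_date
  if (any(swap)) {
    d <- tibble(
      row = which(swap), column = "admit_date",
      value = as.character(tbl$admit_date[swap]),
      problem = "admit_date after discharge_date"
    )
    if (strict) abort("validation failed: admit_date after discharge_date")
    attr(tbl, "diagnostics") <- bind_rows(attr(tbl, "diagnostics"), d)
    tbl <- tbl[!swap, , drop = FALSE]
  }
  tbl
}

format_column <- function(x, type) {
  out <- switch(type,
    date = format(x, "%Y-%m-%d"),
    logical = ifelse(x, "true", "false"),
    as.character(x)
  )
  out[is.na(x)] <- ""
  out
}

write_records <- function(tbl, dictionary, path) {
  cols <- purrr::map2(
    dictionary$name, dictionary$type,
    function(nm, ty) format_column(tbl[[nm]], ty)
  )
  names(cols) <- dictionary$name
  readr::write_csv(as_tibble(cols), path, na = "")
  invisible(path)
}

#' Write vital or hospital files
#'
#' Inverse of the readers: emits CSV that reads back bit-identically for all
#' non-float fields.
#'
#' @param tbl Tibble of records.
#' @param path Output CSV path.
#' @param dictionary Column dictionary.
#' @return `path`, invisibly.
#' @export
write_vital_file <- function(tbl, path, dictionary = vital_dictionary()) {
  write_records(tbl, dictionary, path)
}

#' @rdname write_vital_file
#' @export
write_hospital_file <- function(tbl, path, dictionary = hospital_dictionary()) {
  write_records(tbl, dictionary, path)
}

linked_cohort_dictionary <- function() {
  bind_rows(
    vital_dictionary(),
    dict_row("mother_episode_id", "string"),
    dict_row("mother_pass", "string"),
    dict_row("mother_score", "integer"),
    dict_row("mother_tiebreak", "logical"),
    dict_row("infant_episode_id", "string"),
    dict_row("infant_pass", "string"),
    dict_row("infant_score", "integer"),
    dict_row("infant_tiebreak", "logical"),
    dict_row("twin_ambiguous", "logical")
  )
}

#' Write / read a linked cohort file
#'
#' One row per vital record carrying the linked maternal and infant episode
#' ids, the blocking pass that made each link, the link score, and the
#' tie-break/twin-ambiguity provenance flags. Unlinked records keep empty
#' link columns.
#'
#' @param result A `natalink_linkage` result (see [link_cohort()]).
#' @param vitals The vital-records tibble the linkage ran on.
#' @param path Output CSV path.
#' @return `write_linked_cohort()` returns `path` invisibly;
#'   `read_linked_cohort()` returns the cohort tibble.
#' @export
write_linked_cohort <- function(result, vitals, path) {
  cohort <- linked_cohort(result, vitals)
  write_records(cohort, linked_cohort_dictionary(), path)
}

#' @rdname write_linked_cohort
#' @export
read_linked_cohort <- function(path) {
  read_records(path, linked_cohort_dictionary(), strict = FALSE)
}

#' Join linkage assignments onto the vital records
#'
#' @inheritParams write_linked_cohort
#' @return Tibble: vitals plus assignment columns.
#' @export
linked_cohort <- function(result, vitals) {
  stopifnot(inherits(result, "natalink_linkage"))
  left_join(vitals, result$assignments, by = "record_id")
}
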