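# ICD-9 / ICD-10 prefix code sets behind the clinical indicators used by the
# link-score comparators, and the pregnancy/birth record filter applied
# before infant-side linkage.

#' Construct an ICD prefix code set
#'
#' A code set maps one clinical indicator label to lists of ICD-9 and ICD-10
#' code prefixes. Matching is prefix-based on normalized codes (dot stripped,
#' uppercased), separately for diagnosis and procedure axes.
#'
#' @param name Indicator label (single string).
#' @param icd9_dx,icd10_dx Character vectors of diagnosis code prefixes.
#' @param icd9_proc,icd10_proc Character vectors of procedure code prefixes.
#' @return An object of class `natalink_code_set`.
#' @examples
#' code_set("diabetes_any", icd9_dx = c("648.0", "648.8", "250"), icd10_dx = "O24")
#' @export
code_set <- function(name, icd9_dx = character(), icd10_dx = character(),
                     icd9_proc = character(), icd10_proc = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  prefixes <- c(icd9_dx, icd10_dx, icd9_proc, icd10_proc)
  if (length(prefixes) == 0L) {
    abort(paste0("code_set '", name, "' has no prefixes"))
  }
  if (any(!nzchar(prefixes))) {
    abort(paste0("code_set '", name, "' contains an empty prefix"))
  }
  structure(
    list(
      name = name,
      icd9_dx = vapply(icd9_dx, normalize_code, "", system = "icd9", USE.NAMES = FALSE),
      icd10_dx = vapply(icd10_dx, normalize_code, "", system = "icd10", USE.NAMES = FALSE),
      icd9_proc = vapply(icd9_proc, normalize_code, "", system = "icd9", USE.NAMES = FALSE),
      icd10_proc = vapply(icd10_proc, normalize_code, "", system = "icd10", USE.NAMES = FALSE)
    ),
    class = "natalink_code_set"
  )
}

#' Normalize a raw ICD code
#'
#' Uppercases, strips dots and surrounding whitespace. The code system tag is
#' validated but does not alter the normalized string.
#'
#' @param code Raw ICD code string.
#' @param system `"icd9"` or `"icd10"`.
#' @return Normalized code string.
#' @examples
#' normalize_code("O24.4", "icd10") # "O244"
#' @export
normalize_code <- function(code, system = c("icd10", "icd9")) {
  match.arg(system)
  if (length(code) != 1L || is.na(code) || !nzchar(trimws(code))) {
    abort("`code` must be a single non-empty string")
  }
  toupper(gsub("[.[:space:]]", "", code))
}

#' Default indicator code sets
#'
#' The packaged code sets used by the comparators: gestational-age bands,
#' birthweight bands, cesarean and previous cesarean delivery, small/large
#' for gestational age, hypertension during pregnancy, diabetes, and
#' plurality. The ascertainment-only sets (eclampsia, placental abruption,
#' chorioamnionitis and the birth-defect groups) are editable defaults for
#' the dual-source evaluation; they are reasonable prefix groups but are not
#' part of the scoring table and should be reviewed before substantive use.
#'
#' @param ascertainment Include the ascertainment-only sets (default `TRUE`).
#' @return Named list of [code_set()] objects.
#' @export
default_code_sets <- function(ascertainment = TRUE) {
  sets <- list(
    ga_lt29 = code_set("ga_lt29",
      icd9_dx = c("765.21", "765.22", "765.23", "765.24"),
      icd10_dx = "P07.2"
    ),
    ga_29to36 = code_set("ga_29to36",
      icd9_dx = c("765.25", "765.26", "765.27", "765.28"),
      icd10_dx = c("O60.1", "O60.3", "P07.3")
    ),
    ga_37to42 = code_set("ga_37to42", icd9_dx = "765.29"),
    ga_gt42 = code_set("ga_gt42", icd10_dx = c("P08.22", "O48")),
    cesarean = code_set("cesarean",
      icd9_proc = "74", icd9_dx = c("669.7", "763.4"),
      icd10_proc = "10D",
      icd10_dx = c("O82", "P03.4", "Z38.01", "Z38.31", "Z38.62")
    ),
    previous_cesarean = code_set("previous_cesarean",
      icd9_dx = "654.2", icd10_dx = "O34.2"
    ),
    bw_lt2500 = code_set("bw_lt2500",
      icd9_dx = c(
        "765.01", "765.02", "765.03", "765.04", "765.05", "765.06",
        "765.07", "765.08", "765.11", "765.12", "765.13", "765.14",
        "765.15", "765.16", "765.17", "765.18"
      ),
      icd10_dx = c(
        "P07.0", "P07.1", "P05.01", "P05.02", "P05.03", "P05.04",
        "P05.05", "P05.07", "P05.08", "P05.11", "P05.12", "P05.13",
        "P05.14", "P05.15", "P05.17", "P05.18"
      )
    ),
    bw_2500to4499 = code_set("bw_2500to4499",
      icd9_dx = c("765.09", "765.19"),
      icd10_dx = c("P05.09", "P05.19")
    ),
    bw_ge4500 = code_set("bw_ge4500", icd10_dx = "P08.0"),
    sga_lga = code_set("sga_lga",
      icd9_dx = c("656.5", "764.0", "764.1", "764.9"),
      icd10_dx = c("P05", "O36.5")
    ),
    hypertension_preg = code_set("hypertension_preg",
      icd9_dx = "642", icd10_dx = "O1"
    ),
    diabetes_any = code_set("diabetes_any",
      icd9_dx = c("648.0", "648.8", "250"), icd10_dx = "O24"
    ),
    plurality_singleton = code_set("plurality_singleton",
      icd9_dx = "V27.0", icd10_dx = c("Z38.0", "Z38.1", "Z38.2")
    ),
    plurality_twin = code_set("plurality_twin",
      icd9_dx = "651.0", icd10_dx = c("O30.0", "Z38.3", "Z38.4", "Z38.5")
    ),
    plurality_multiple = code_set("plurality_multiple",
      icd9_dx = c("651.1", "651.2"),
      icd10_dx = c("O30.1", "O30.2", "O38.8", "O38.9", "Z38.6", "Z38.7", "Z38.8")
    )
  )
  if (ascertainment) {
    sets <- c(sets, list(
      gestational_diabetes = code_set("gestational_diabetes",
        icd9_dx = "648.8", icd10_dx = "O24.4"
      ),
      preexisting_diabetes = code_set("preexisting_diabetes",
        icd9_dx = c("648.0", "250"),
        icd10_dx = c("O24.0", "O24.1", "O24.3")
      ),
      prepregnancy_hypertension = code_set("prepregnancy_hypertension",
        icd9_dx = c("642.0", "642.1", "642.2"), icd10_dx = c("O10", "O11")
      ),
      gestational_hypertension = code_set("gestational_hypertension",
        icd9_dx = c("642.3", "642.4", "642.5", "642.7"),
        icd10_dx = c("O13", "O14")
      ),
      eclampsia = code_set("eclampsia", icd9_dx = "642.6", icd10_dx = "O15"),
      placental_abruption = code_set("placental_abruption",
        icd9_dx = "641.2", icd10_dx = "O45"
      ),
      chorioamnionitis = code_set("chorioamnionitis",
        icd9_dx = c("658.4", "762.7"), icd10_dx = c("O41.12", "P02.7")
      ),
      neural_tube_defect = code_set("neural_tube_defect",
        icd9_dx = c("740", "741", "742.0"), icd10_dx = c("Q00", "Q01", "Q05")
      ),
      gastroschisis_omphalocele = code_set("gastroschisis_omphalocele",
        icd9_dx = c("756.72", "756.73"), icd10_dx = c("Q79.2", "Q79.3")
      ),
      cleft_lip_palate = code_set("cleft_lip_palate",
        icd9_dx = "749", icd10_dx = c("Q35", "Q36", "Q37")
      ),
      major_heart_defect = code_set("major_heart_defect",
        icd9_dx = c("745", "746"),
        icd10_dx = c("Q20", "Q21", "Q22", "Q23", "Q24", "Q25", "Q26")
      )
    ))
  }
  sets
}

#' Write / read code sets as a YAML config
#'
#' One block per indicator with `icd9_dx`, `icd10_dx`, `icd9_proc`,
#' `icd10_proc` prefix lists, so the sets can be audited and overridden
#' without touching code.
#'
#' @param sets Named list of [code_set()] objects.
#' @param path File path.
#' @return `write_code_sets()` returns `path` invisibly; `read_code_sets()`
#'   returns a named list of code sets.
#' @export
write_code_sets <- function(sets, path) {
  blocks <- purrr::map(sets, function(s) {
    purrr::compact(list(
      icd9_dx = as.list(s$icd9_dx), icd10_dx = as.list(s$icd10_dx),
      icd9_proc = as.list(s$icd9_proc), icd10_proc = as.list(s$icd10_proc)
    ))
  })
  yaml::write_yaml(blocks, path)
  invisible(path)
}

#' @rdname write_code_sets
#' @export
read_code_sets <- function(path) {
  blocks <- yaml::read_yaml(path)
  purrr::imap(blocks, function(b, nm) {
    code_set(nm,
      icd9_dx = unlist(b$icd9_dx) %||% character(),
      icd10_dx = unlist(b$icd10_dx) %||% character(),
      icd9_proc = unlist(b$icd9_proc) %||% character(),
      icd10_proc = unlist(b$icd10_proc) %||% character()
    )
  })
}

# parse "icd10:O24.4;icd9:6480" fields into a long (row, system, code) tibble;
# `axis` labels diagnosis vs procedure
parse_code_field <- function(x, axis) {
  keep <- !is.na(x) & x != ""
  if (!any(keep)) {
    return(tibble(
      row = integer(), system = character(),
      code = character(), axis = character()
    ))
  }
  parts <- strsplit(x[keep], ";", fixed = TRUE)
  row <- rep(which(keep), lengths(parts))
  toks <- trimws(unlist(parts, use.names = FALSE))
  sys <- ifelse(startsWith(toks, "icd10:"), "icd10",
    ifelse(startsWith(toks, "icd9:"), "icd9", NA_character_)
  )
  code <- sub("^icd(9|10):", "", toks)
  ok <- !is.na(sys) & nzchar(code)
  tibble(
    row = row[ok], system = sys[ok],
    code = toupper(gsub("[.[:space:]]", "", code[ok])), axis = axis
  )
}

# long code table for a set of episodes: episode row index, system,
# normalized code, axis in {dx, proc}
episode_code_table <- function(episodes) {
  bind_rows(
    parse_code_field(episodes$diagnosis_codes, "dx"),
    parse_code_field(episodes$procedure_codes, "proc")
  )
}

# rows of `codes` long table matching a code_set (prefix match per
# system/axis); returns logical over nrow(episodes) given the row index
match_code_set <- function(codes, set, n_rows) {
  hit <- rep(FALSE, nrow(codes))
  for (slot in c("icd9_dx", "icd10_dx", "icd9_proc", "icd10_proc")) {
    prefixes <- set[[slot]]
    if (length(prefixes) == 0L) next
    sys <- if (startsWith(slot, "icd9")) "icd9" else "icd10"
    axis <- if (endsWith(slot, "proc")) "proc" else "dx"
    sel <- codes$system == sys & codes$axis == axis
    if (!any(sel)) next
    sub <- codes$code[sel]
    m <- rep(FALSE, length(sub))
    for (p in prefixes) m <- m | startsWith(sub, p)
    hit[sel] <- hit[sel] | m
  }
  out <- rep(FALSE, n_rows)
  out[unique(codes$row[hit])] <- TRUE
  out
}

# resolve a set of band flags into one band label; `priority` lists bands
# worst-first, so conflicting codes collapse to the most extreme category
resolve_band <- function(flags, priority) {
  out <- rep("unknown", length(flags[[1]]))
  for (band in rev(priority)) out[flags[[band]]] <- band
  out
}

#' Derive clinical indicators from ICD codes on hospital episodes
#'
#' Maps the diagnosis and procedure codes of each episode to the indicator
#' flags and bands used by the link-score comparators and the dual-source
#' ascertainment evaluation. Matching is prefix-based on normalized codes;
#' both ICD-9 and ICD-10 prefixes are tested on every episode regardless of
#' discharge date (the study window spans the 2015 coding transition, and
#' prefix sets make dual matching harmless). When codes on one episode imply
#' conflicting bands, the band resolves to the most extreme category
#' (gestational age: shortest; birthweight: lowest; plurality: highest
#' order), mirroring worst-first clinical coding. Unrecognized codes are
#' ignored; `infant_died` is true iff `discharge_status == "died"`.
#'
#' @param episodes Hospital-episode tibble (see [read_hospital_file()]).
#' @param code_sets Named list of code sets, default [default_code_sets()].
#' @return Tibble keyed by `episode_id` with band columns (`ga_band`,
#'   `birthweight_band`, `plurality_band`) and logical indicator columns.
#' @examples
#' eps <- tibble::tibble(
#'   episode_id = "e1", diagnosis_codes = "icd10:O24.4",
#'   procedure_codes = "", discharge_status = "routine"
#' )
#' derive_indicators(eps)$diabetes_any
#' @export
derive_indicators <- function(episodes, code_sets = default_code_sets()) {
  n <- nrow(episodes)
  codes <- episode_code_table(episodes)
  hits <- purrr::map(code_sets, match_code_set, codes = codes, n_rows = n)

  ga_band <- resolve_band(
    list(
      lt29 = hits$ga_lt29, `29to36` = hits$ga_29to36,
      `37to42` = hits$ga_37to42, gt42 = hits$ga_gt42
    ),
    priority = c("lt29", "29to36", "gt42", "37to42")
  )
  bw_band <- resolve_band(
    list(
      lt2500 = hits$bw_lt2500, ge4500 = hits$bw_ge4500,
      `2500to4499` = hits$bw_2500to4499
    ),
    priority = c("lt2500", "ge4500", "2500to4499")
  )
  plu_band <- resolve_band(
    list(
      multiple = hits$plurality_multiple, twin = hits$plurality_twin,
      singleton = hits$plurality_singleton
    ),
    priority = c("multiple", "twin", "singleton")
  )

  status <- episodes[["discharge_status"]] %||% rep("", n)
  out <- tibble(
    episode_id = episodes$episode_id,
    ga_band = ga_band,
    birthweight_band = bw_band,
    plurality_band = plu_band,
    cesarean = hits$cesarean,
    previous_cesarean = hits$previous_cesarean,
    sga_lga = hits$sga_lga,
    hypertension_preg = hits$hypertension_preg,
    diabetes_any = hits$diabetes_any,
    infant_died = !is.na(status) & status == "died"
  )
  extra <- setdiff(
    names(code_sets),
    c(
      "ga_lt29", "ga_29to36", "ga_37to42", "ga_gt42", "cesarean",
      "previous_cesarean", "bw_lt2500", "bw_2500to4499", "bw_ge4500",
      "sga_lga", "hypertension_preg", "diabetes_any",
      "plurality_singleton", "plurality_twin", "plurality_multiple"
    )
  )
  for (nm in extra) out[[nm]] <- hits[[nm]]
  out
}

#' Identify pregnancy- or birth-related hospital episodes
#'
#' The filter applied to hospital episodes before infant-side linkage: an
#' episode qualifies if its major diagnostic category is 14, any ICD-9
#' diagnosis is V23 or falls in 640-679, or any ICD-10 diagnosis starts with
#' O1, O2, O3, O4, O6, O7, O8 or O9. Newborn birth admissions also qualify
#' (ICD-10 Z38*, ICD-9 V30-V39 liveborn codes, or age at admission of
#' 0 years), since the maternity code ranges alone would exclude the infant
#' records this filter exists to keep.
#'
#' @param episodes Hospital-episode tibble.
#' @return Logical vector, one element per episode.
#' @export
is_pregnancy_or_birth_record <- function(episodes) {
  n <- nrow(episodes)
  codes <- episode_code_table(episodes)
  dx <- codes[codes$axis == "dx", ]

  icd9 <- dx[dx$system == "icd9", ]
  root9 <- suppressWarnings(as.integer(substr(icd9$code, 1, 3)))
  mat9 <- startsWith(icd9$code, "V23") |
    (!is.na(root9) & root9 >= 640 & root9 <= 679)
  v3 <- grepl("^V3[0-9]", icd9$code)

  icd10 <- dx[dx$system == "icd10", ]
  mat10 <- grepl("^O[1234679]", icd10$code)
  nb10 <- startsWith(icd10$code, "Z38")

  flag <- rep(FALSE, n)
  flag[unique(icd9$row[mat9 | v3])] <- TRUE
  flag[unique(icd10$row[mat10 | nb10])] <- TRUE
  mdc <- episodes[["mdc"]]
  if (!is.null(mdc)) flag <- flag | (!is.na(mdc) & mdc == 14L)
  age <- episodes[["age_at_admission_yrs"]]
  if (!is.null(age)) flag <- flag | (!is.na(age) & age == 0L)
  flag
}
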