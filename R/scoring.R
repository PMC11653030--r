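# Additive link-score comparators. Each scored variable contributes a fixed
# number of points when the vital record and the hospital episode agree at a
# given concordance level; the link score is the sum over variables. The sum
# of per-variable maxima is 148. Condition flags (cesarean, previous
# cesarean, hypertension, diabetes, SGA/LGA, infant death) score only on
# positive-positive concordance: the joint absence of a diagnosis carries no
# identifying information and scoring it would swamp the cutoffs.

#' Comparator point table
#'
#' The packaged point values for every scored variable and concordance
#' level. Override individual entries for sensitivity analyses; the
#' invariant that all values are nonnegative integers is enforced.
#'
#' @param ... Named overrides, e.g. `zip = 6`.
#' @return Named list of point values (class `natalink_comparator_spec`).
#' @examples
#' spec <- comparator_spec()
#' spec_max_total(spec) # 148
#' @export
comparator_spec <- function(...) {
  spec <- list(
    mother_dob_exact = 10L, mother_dob_transposed = 5L,
    hospital = 10L,
    infant_dob_exact = 10L, infant_dob_transposed = 5L,
    zip = 5L,
    ga_lt29 = 20L, ga_29to36 = 10L, ga_37to42 = 2L, ga_gt42 = 10L,
    sex = 2L,
    payer = 5L,
    race_any = 5L, race_minority_bonus = 5L, race_white_bonus = 2L,
    ethnicity = 2L,
    county = 2L,
    infant_death = 10L,
    cesarean = 5L,
    previous_cesarean = 10L,
    bw_lt2500 = 10L, bw_2500to4499 = 2L, bw_ge4500 = 10L,
    sga_lga = 7L,
    hypertension = 10L,
    diabetes = 10L,
    plurality_singleton = 2L, plurality_multi = 10L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(spec))
  if (length(unknown)) abort(paste0("unknown comparator entries: ", toString(unknown)))
  spec[names(overrides)] <- lapply(overrides, as.integer)
  if (any(unlist(spec) < 0)) abort("comparator points must be nonnegative")
  structure(spec, class = "natalink_comparator_spec")
}

# variables excluded from the "at least 1 other variable" requirement
REQUIRED_VARIABLES <- c("mother_dob", "infant_dob", "hospital")

SCORE_VARIABLES <- c(
  "mother_dob", "hospital", "infant_dob", "zip", "gestational_age", "sex",
  "payer", "race", "ethnicity", "county", "infant_death", "cesarean",
  "previous_cesarean", "birthweight", "sga_lga", "hypertension", "diabetes",
  "plurality"
)

#' Sum of per-variable maxima of a comparator spec
#'
#' The highest total a fully concordant pair can attain; 148 for the
#' packaged table.
#'
#' @param spec A [comparator_spec()].
#' @return Integer.
#' @export
spec_max_total <- function(spec = comparator_spec()) {
  as.integer(
    spec$mother_dob_exact + spec$hospital + spec$infant_dob_exact + spec$zip +
      max(spec$ga_lt29, spec$ga_29to36, spec$ga_37to42, spec$ga_gt42) +
      spec$sex + spec$payer +
      spec$race_any + max(spec$race_minority_bonus, spec$race_white_bonus) +
      spec$ethnicity + spec$county + spec$infant_death + spec$cesarean +
      spec$previous_cesarean +
      max(spec$bw_lt2500, spec$bw_2500to4499, spec$bw_ge4500) +
      spec$sga_lga + spec$hypertension + spec$diabetes +
      max(spec$plurality_singleton, spec$plurality_multi)
  )
}

#' Compare two dates for linkage concordance
#'
#' Levels: `exact` (equal); `transposed` (swapping month and day of one date
#' yields the other, with month and day distinct); `year_differs` (month and
#' day equal, year differs); `none` otherwise or when either date is
#' missing. Symmetric in its arguments; vectorized.
#'
#' @param a,b Date vectors.
#' @return Character vector of levels.
#' @examples
#' compare_date(as.Date("1990-03-07"), as.Date("1990-07-03")) # "transposed"
#' @export
compare_date <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.Date(a), n)
  b <- rep_len(as.Date(b), n)
  out <- rep("none", n)
  both <- !is.na(a) & !is.na(b)
  ya <- as.integer(format(a, "%Y")); ma <- as.integer(format(a, "%m"))
  da <- as.integer(format(a, "%d"))
  yb <- as.integer(format(b, "%Y")); mb <- as.integer(format(b, "%m"))
  db <- as.integer(format(b, "%d"))
  exact <- both & a == b
  transposed <- both & !exact & ya == yb & ma == db & da == mb & ma != da
  year_diff <- both & !exact & ma == mb & da == db & ya != yb
  out[year_diff] <- "year_differs"
  out[transposed] <- "transposed"
  out[exact] <- "exact"
  out
}

# vital-side gestational-age band from completed weeks
vital_ga_band <- function(wk) {
  case_when(
    is.na(wk) ~ "unknown",
    wk < 29 ~ "lt29",
    wk < 37 ~ "29to36",
    wk <= 42 ~ "37to42",
    TRUE ~ "gt42"
  )
}

# vital-side birthweight band in grams
vital_bw_band <- function(g) {
  case_when(
    is.na(g) ~ "unknown",
    g < 2500 ~ "lt2500",
    g < 4500 ~ "2500to4499",
    TRUE ~ "ge4500"
  )
}

MINORITY_RACE <- c(
  "amer_indian_alaska_native", "asian", "black", "hawaiian_pacific_islander",
  "hispanic", "other", "multiple"
)

eq_known <- function(a, b, unknown = "unknown") {
  out <- !is.na(a) & !is.na(b) & a == b
  out[is.na(out)] <- FALSE
  if (length(unknown) == 1L && !is.na(unknown)) {
    out <- out & a != unknown
    out[is.na(out)] <- FALSE
  }
  out
}

# Vectorized scoring core. `v`, `e`, `ind` are row-aligned tibbles (one row
# per candidate pair): vital record, hospital episode, derived indicators of
# that episode. Returns one row per pair with per-variable point columns
# (pts_*), the total, and the flags acceptance needs.
score_pair_table <- function(v, e, ind, spec = comparator_spec(),
                             side = c("mother", "infant")) {
  side <- match.arg(side)
  n <- nrow(v)
  zero <- rep(0L, n)

  if (side == "mother") {
    dob_level <- compare_date(v$mother_dob, e$patient_dob)
    pts_mother_dob <- ifelse(dob_level == "exact", spec$mother_dob_exact,
      ifelse(dob_level == "transposed", spec$mother_dob_transposed, 0L)
    )
    # the maternal abstract has no infant DOB field: the delivery admission
    # window stands in, so containment counts as an exact link
    in_window <- !is.na(v$infant_dob) & !is.na(e$admit_date) &
      !is.na(e$discharge_date) &
      v$infant_dob >= e$admit_date & v$infant_dob <= e$discharge_date
    infant_dob_level <- ifelse(in_window, "exact", "none")
    pts_infant_dob <- ifelse(in_window, spec$infant_dob_exact, 0L)
  } else {
    dob_level <- rep("none", n)
    pts_mother_dob <- zero
    infant_dob_level <- compare_date(v$infant_dob, e$patient_dob)
    pts_infant_dob <- ifelse(infant_dob_level == "exact", spec$infant_dob_exact,
      ifelse(infant_dob_level == "transposed", spec$infant_dob_transposed, 0L)
    )
  }

  hospital_linked <- eq_known(v$hospital_id, e$hospital_id, unknown = NA)
  pts_hospital <- ifelse(hospital_linked, spec$hospital, 0L)
  pts_zip <- ifelse(eq_known(v$zip, e$zip, unknown = NA), spec$zip, 0L)

  v_ga <- vital_ga_band(v$gestational_age_wk)
  ga_match <- eq_known(v_ga, ind$ga_band)
  pts_ga <- ifelse(!ga_match, 0L, unname(c(
    lt29 = spec$ga_lt29, `29to36` = spec$ga_29to36,
    `37to42` = spec$ga_37to42, gt42 = spec$ga_gt42, unknown = 0L
  )[v_ga]))

  sex_concordant <- eq_known(v$infant_sex, e$sex)
  pts_sex <- ifelse(sex_concordant, spec$sex, 0L)
  pts_payer <- ifelse(eq_known(v$payer, e$payer), spec$payer, 0L)

  race_match <- eq_known(v$race_eth, e$race_eth)
  pts_race <- ifelse(!race_match, 0L,
    spec$race_any +
      ifelse(v$race_eth %in% MINORITY_RACE, spec$race_minority_bonus,
        ifelse(v$race_eth == "white_nh", spec$race_white_bonus, 0L)
      )
  )
  v_hisp <- ifelse(is.na(v$race_eth) | v$race_eth == "unknown", NA,
    v$race_eth == "hispanic"
  )
  e_hisp <- ifelse(is.na(e$race_eth) | e$race_eth == "unknown", NA,
    e$race_eth == "hispanic"
  )
  pts_ethnicity <- ifelse(!is.na(v_hisp) & !is.na(e_hisp) & v_hisp == e_hisp,
    spec$ethnicity, 0L
  )
  pts_county <- ifelse(eq_known(v$county, e$county, unknown = NA), spec$county, 0L)

  flag <- function(vf, if_) !is.na(vf) & vf & if_
  pts_infant_death <- ifelse(flag(v$infant_death, ind$infant_died), spec$infant_death, 0L)
  pts_cesarean <- ifelse(flag(v$cesarean, ind$cesarean), spec$cesarean, 0L)
  pts_previous_cesarean <- ifelse(flag(v$previous_cesarean, ind$previous_cesarean),
    spec$previous_cesarean, 0L
  )

  v_bw <- vital_bw_band(v$birthweight_g)
  bw_match <- eq_known(v_bw, ind$birthweight_band)
  pts_birthweight <- ifelse(!bw_match, 0L, unname(c(
    lt2500 = spec$bw_lt2500, `2500to4499` = spec$bw_2500to4499,
    ge4500 = spec$bw_ge4500, unknown = 0L
  )[v_bw]))

  vcol <- function(nm) v[[nm]] %||% rep(NA, n)
  pts_sga_lga <- ifelse(flag(vcol("sga_lga"), ind$sga_lga), spec$sga_lga, 0L)
  v_htn <- vcol("prepregnancy_hypertension") | vcol("gestational_hypertension") |
    vcol("eclampsia")
  v_diab <- vcol("gestational_diabetes") | vcol("preexisting_diabetes")
  pts_hypertension <- ifelse(flag(v_htn, ind$hypertension_preg), spec$hypertension, 0L)
  pts_diabetes <- ifelse(flag(v_diab, ind$diabetes_any), spec$diabetes, 0L)

  plu_match <- eq_known(v$plurality, ind$plurality_band)
  pts_plurality <- ifelse(!plu_match, 0L,
    ifelse(v$plurality == "singleton", spec$plurality_singleton, spec$plurality_multi)
  )

  pts <- tibble(
    pts_mother_dob = as.integer(pts_mother_dob),
    pts_hospital = as.integer(pts_hospital),
    pts_infant_dob = as.integer(pts_infant_dob),
    pts_zip = as.integer(pts_zip),
    pts_gestational_age = as.integer(pts_ga),
    pts_sex = as.integer(pts_sex),
    pts_payer = as.integer(pts_payer),
    pts_race = as.integer(pts_race),
    pts_ethnicity = as.integer(pts_ethnicity),
    pts_county = as.integer(pts_county),
    pts_infant_death = as.integer(pts_infant_death),
    pts_cesarean = as.integer(pts_cesarean),
    pts_previous_cesarean = as.integer(pts_previous_cesarean),
    pts_birthweight = as.integer(pts_birthweight),
    pts_sga_lga = as.integer(pts_sga_lga),
    pts_hypertension = as.integer(pts_hypertension),
    pts_diabetes = as.integer(pts_diabetes),
    pts_plurality = as.integer(pts_plurality)
  )
  other_cols <- setdiff(names(pts), paste0("pts_", REQUIRED_VARIABLES))
  other_linked <- Reduce(`|`, lapply(pts[other_cols], function(x) x > 0L))

  mother_dob_linked <- dob_level %in% c("exact", "transposed", "year_differs")
  res <- pts
  res$total <- as.integer(rowSums(as.matrix(pts)))
  res$mother_dob_level <- dob_level
  res$infant_dob_level <- infant_dob_level
  res$mother_dob_linked <- mother_dob_linked
  res$infant_dob_linked <- infant_dob_level == "exact"
  res$hospital_linked <- hospital_linked
  res$other_variable_linked <- other_linked
  res$dob_relaxation_used <- mother_dob_linked & dob_level != "exact"
  res$sex_concordant <- sex_concordant
  res$plurality_multi_both <- !is.na(v$plurality) &
    v$plurality %in% c("twin", "multiple") &
    ind$plurality_band %in% c("twin", "multiple")
  res
}

breakdown_from_row <- function(row, side) {
  vars <- SCORE_VARIABLES
  if (side == "infant") vars <- setdiff(vars, "mother_dob")
  pts <- vapply(paste0("pts_", vars), function(cn) as.integer(row[[cn]]), 1L)
  level <- ifelse(pts > 0L, "concordant", "none")
  if ("mother_dob" %in% vars) level[vars == "mother_dob"] <- row$mother_dob_level
  level[vars == "infant_dob"] <- row$infant_dob_level
  breakdown <- tibble(variable = vars, level = unname(level), points = unname(pts))
  structure(
    list(
      breakdown = breakdown,
      total = as.integer(row$total),
      side = side,
      required_flags = list(
        mother_dob_linked = isTRUE(row$mother_dob_linked),
        infant_dob_linked = isTRUE(row$infant_dob_linked),
        hospital_linked = isTRUE(row$hospital_linked),
        other_variable_linked = isTRUE(row$other_variable_linked),
        dob_relaxation_used = isTRUE(row$dob_relaxation_used)
      ),
      sex_concordant = isTRUE(row$sex_concordant),
      plurality_multi_both = isTRUE(row$plurality_multi_both)
    ),
    class = "natalink_score"
  )
}

#' Score one vital record against one maternal hospital episode
#'
#' Computes the full per-variable breakdown and total link score for a
#' candidate pair on the birthing-person side. The birthing person's date of
#' birth is compared with transposition and year-relaxation levels; the
#' infant's date of birth is linked when it falls inside the episode's
#' admission window; condition indicators come from the episode's ICD codes.
#'
#' @param vital One-row vital-record tibble.
#' @param episode One-row hospital-episode tibble.
#' @param indicators Optional one-row output of [derive_indicators()] for
#'   `episode`; derived on the fly if omitted.
#' @param spec A [comparator_spec()].
#' @return A `natalink_score` object: `$breakdown` (variable, level,
#'   points), `$total`, `$required_flags`.
#' @export
score_mother_pair <- function(vital, episode, indicators = NULL,
                              spec = comparator_spec()) {
  if (is.null(indicators)) indicators <- derive_indicators(episode)
  row <- score_pair_table(vital, episode, indicators, spec, side = "mother")
  breakdown_from_row(row[1, ], "mother")
}

#' Score one vital record against one infant hospital episode
#'
#' As [score_mother_pair()] but on the infant side: the birthing person's
#' date of birth is unavailable on infant discharge records and is omitted;
#' the infant's date of birth is compared against the episode's patient date
#' of birth (with transposition); infant-sex concordance is recorded as a
#' hard flag because discordant-sex pairs are never accepted. Maternal-only
#' condition comparators contribute only if their codes appear on the infant
#' episode, which the packaged (maternal) code sets do not produce.
#'
#' @inheritParams score_mother_pair
#' @return A `natalink_score` object.
#' @export
score_infant_pair <- function(vital, episode, indicators = NULL,
                              spec = comparator_spec()) {
  if (is.null(indicators)) indicators <- derive_indicators(episode)
  row <- score_pair_table(vital, episode, indicators, spec, side = "infant")
  breakdown_from_row(row[1, ], "infant")
}

#' @export
print.natalink_score <- function(x, ...) {
  cat("<link score breakdown (", x$side, " side)>\n", sep = "")
  print(x$breakdown[x$breakdown$points > 0 | x$breakdown$level != "none", ])
  cat("total:", x$total, "\n")
  invisible(x)
}
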