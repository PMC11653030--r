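# Ground-truthed synthetic cohort generator. Emits vital records, maternal
# and infant birth-admission episodes, and a truth table mapping each vital
# record to its true episodes, under a configurable error and missingness
# model. Episode ICD codes are written consistently with the generated
# clinical truth, so indicator derivation inverts the generation on
# unperturbed data.

default_comorbidity_table <- function() {
  tibble(
    indicator = c(
      "gestational_diabetes", "preexisting_diabetes",
      "prepregnancy_hypertension", "gestational_hypertension", "eclampsia",
      "placental_abruption", "chorioamnionitis", "neural_tube_defect",
      "gastroschisis_omphalocele", "cleft_lip_palate", "major_heart_defect"
    ),
    prevalence = c(
      0.0934, 0.0179, 0.0172, 0.0709, 0.0016,
      0.0109, 0.0261, 0.0005, 0.0009, 0.0022, 0.0039
    ),
    sens_vs = c(
      0.484, 0.385, 0.378, 0.401, 0.50,
      0.321, 0.205, 0.213, 0.203, 0.194, 0.040
    ),
    sens_hospital = c(
      0.878, 0.775, 0.821, 0.898, 0.561,
      0.890, 0.965, 0.919, 0.950, 0.884, 0.979
    ),
    site = c(rep("mother", 7), rep("infant", 4))
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. Defaults reflect the observed
#' marginals of a large statewide birth cohort: a twin rate near 3%, fetal
#' deaths near 0.55% of deliveries, the gestational-age band distribution of
#' live births, comorbidity prevalences with per-source recording
#' sensitivities (certificate vs hospital), encrypted-SSN coverage of about
#' 80% for birthing people and under 10% for infants, and episode
#' withholding rates near the observed unlinked fractions.
#'
#' @param n_deliveries Number of deliveries (a delivery may produce several
#'   fetuses).
#' @param year_range Two integers, inclusive span of birth years.
#' @param twin_rate,higher_multiple_rate Probability a delivery is a twin /
#'   higher-order multiple gestation.
#' @param fetal_death_rate Probability a fetus is a fetal death.
#' @param ga_band_probs Named probabilities for completed-week bands
#'   `20-27`, `28-31`, `32-36`, `37-42`, `43-44` (normalized internally).
#' @param comorbidities Tibble with columns `indicator`, `prevalence`,
#'   `sens_vs`, `sens_hospital`, `site`; see `natalink:::default_comorbidity_table()`.
#' @param infant_death_probs Named per-band probabilities of infant death.
#' @param p_mother_unlinked,p_infant_unlinked Probability the true maternal /
#'   infant episode is withheld from the hospital file.
#' @param p_dob_transposed Probability an episode's patient date of birth
#'   has month and day swapped.
#' @param p_field_missing Probability each perturbable episode field
#'   (patient date of birth, zip, county, payer, race/ethnicity) is deleted.
#' @param p_zip_error Probability one digit of the episode zip is altered.
#' @param enc_ssn_mother,enc_ssn_infant Encrypted-SSN coverage per side.
#' @param n_hospitals,n_zips Size of the hospital and zip pools.
#' @param rng_seed Seed; identical config and seed reproduce identical
#'   output.
#' @return A validated `natalink_simulation_config`.
#' @export
simulation_config <- function(n_deliveries = 1000,
                              year_range = c(2005L, 2020L),
                              twin_rate = 0.0303,
                              higher_multiple_rate = 0.0011,
                              fetal_death_rate = 0.0055,
                              ga_band_probs = c(
                                "20-27" = 0.0054, "28-31" = 0.0082,
                                "32-36" = 0.0763, "37-42" = 0.8987,
                                "43-44" = 0.0114
                              ),
                              comorbidities = default_comorbidity_table(),
                              infant_death_probs = c(
                                "20-27" = 0.25, "28-31" = 0.06,
                                "32-36" = 0.01, "37-42" = 0.002,
                                "43-44" = 0.002
                              ),
                              p_mother_unlinked = 0.05,
                              p_infant_unlinked = 0.03,
                              p_dob_transposed = 0.01,
                              p_field_missing = 0.02,
                              p_zip_error = 0.02,
                              enc_ssn_mother = 0.80,
                              enc_ssn_infant = 0.05,
                              n_hospitals = 25L,
                              n_zips = 60L,
                              rng_seed = 1L) {
  cfg <- list(
    n_deliveries = as.integer(n_deliveries), year_range = as.integer(year_range),
    twin_rate = twin_rate, higher_multiple_rate = higher_multiple_rate,
    fetal_death_rate = fetal_death_rate,
    ga_band_probs = ga_band_probs / sum(ga_band_probs),
    comorbidities = comorbidities,
    infant_death_probs = infant_death_probs,
    p_mother_unlinked = p_mother_unlinked,
    p_infant_unlinked = p_infant_unlinked,
    p_dob_transposed = p_dob_transposed,
    p_field_missing = p_field_missing,
    p_zip_error = p_zip_error,
    enc_ssn_mother = enc_ssn_mother, enc_ssn_infant = enc_ssn_infant,
    n_hospitals = as.integer(n_hospitals), n_zips = as.integer(n_zips),
    rng_seed = as.integer(rng_seed)
  )
  problems <- character()
  probs <- c(
    twin_rate, higher_multiple_rate, fetal_death_rate, p_mother_unlinked,
    p_infant_unlinked, p_dob_transposed, p_field_missing, p_zip_error,
    enc_ssn_mother, enc_ssn_infant, cfg$ga_band_probs, infant_death_probs,
    comorbidities$prevalence, comorbidities$sens_vs, comorbidities$sens_hospital
  )
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    problems <- c(problems, "all probabilities must lie in [0, 1]")
  }
  if (twin_rate + higher_multiple_rate > 1) {
    problems <- c(problems, "twin_rate + higher_multiple_rate must not exceed 1")
  }
  if (cfg$n_deliveries < 1) problems <- c(problems, "n_deliveries must be >= 1")
  if (length(cfg$year_range) != 2L || cfg$year_range[1] > cfg$year_range[2]) {
    problems <- c(problems, "year_range must be two ordered integers")
  }
  if (length(problems)) {
    abort(paste0("invalid simulation config: ", paste(problems, collapse = "; ")))
  }
  structure(cfg, class = "natalink_simulation_config")
}

GA_BAND_LIMITS <- list(
  "20-27" = c(20L, 27L), "28-31" = c(28L, 31L), "32-36" = c(32L, 36L),
  "37-42" = c(37L, 42L), "43-44" = c(43L, 44L)
)

# pick, per row, a code from a code set appropriate to the row's era;
# falls back to the other revision when a band group has no code in the
# era's revision, keeping indicator derivation invertible
pick_code <- function(set, icd10_era, axis = "dx") {
  slot10 <- if (axis == "dx") set$icd10_dx else set$icd10_proc
  slot9 <- if (axis == "dx") set$icd9_dx else set$icd9_proc
  c10 <- if (length(slot10)) paste0("icd10:", slot10[1]) else NA_character_
  c9 <- if (length(slot9)) paste0("icd9:", slot9[1]) else NA_character_
  out <- ifelse(icd10_era, c10, c9)
  ifelse(is.na(out), ifelse(icd10_era, c9, c10), out)
}

join_codes <- function(...) {
  m <- cbind(...)
  out <- apply(m, 1L, function(r) paste(r[!is.na(r)], collapse = ";"))
  out[out == ""] <- NA_character_
  out
}

transpose_dob <- function(d) {
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m"))
  day <- as.integer(format(d, "%d"))
  can <- !is.na(d) & day <= 12L & day != m
  out <- d
  out[can] <- as.Date(sprintf("%04d-%02d-%02d", y[can], day[can], m[can]))
  attr(out, "applied") <- can
  out
}

#' Perturb hospital episodes under the configured error model
#'
#' Independently applies, per episode: month/day transposition of the
#' patient date of birth (skipped, and logged as inapplicable, when month
#' equals day or the day cannot be a month), deletion of each perturbable
#' field (patient date of birth, zip, county, payer, race/ethnicity), and a
#' single-digit zip error. Draws come from the current RNG stream.
#'
#' @param episodes Hospital-episode tibble.
#' @param cfg A [simulation_config()].
#' @return The perturbed tibble; a per-episode log of applied perturbations
#'   in `attr(, "perturbations")`.
#' @export
perturb_record <- function(episodes, cfg) {
  n <- nrow(episodes)
  log <- rep("", n)
  add_log <- function(log, idx, what) {
    ifelse(seq_len(n) %in% which(idx), paste0(log, ifelse(nzchar(log), ";", ""), what), log)
  }

  want_swap <- runif(n) < cfg$p_dob_transposed
  if (any(want_swap)) {
    swapped <- transpose_dob(episodes$patient_dob[want_swap])
    applied <- attr(swapped, "applied")
    episodes$patient_dob[want_swap] <- as.Date(swapped)
    idx <- rep(FALSE, n)
    idx[which(want_swap)[applied]] <- TRUE
    log <- add_log(log, idx, "dob_transposed")
    inap <- rep(FALSE, n)
    inap[which(want_swap)[!applied]] <- TRUE
    log <- add_log(log, inap, "dob_transpose_inapplicable")
  }

  for (fld in c("patient_dob", "zip", "county", "payer", "race_eth")) {
    hit <- runif(n) < cfg$p_field_missing
    if (any(hit)) {
      episodes[[fld]][hit] <- NA
      log <- add_log(log, hit, paste0("missing_", fld))
    }
  }

  hit <- runif(n) < cfg$p_zip_error & !is.na(episodes$zip)
  if (any(hit)) {
    z <- episodes$zip[hit]
    pos <- sample.int(5L, length(z), replace = TRUE)
    digit <- as.character(sample.int(10L, length(z), replace = TRUE) - 1L)
    substr(z, pos, pos) <- digit
    episodes$zip[hit] <- z
    log <- add_log(log, hit, "zip_digit_error")
  }

  attr(episodes, "perturbations") <- log
  episodes
}

#' Simulate a ground-truthed delivery cohort
#'
#' Each delivery yields one vital record per fetus (sharing a sibling-set
#' id), one maternal birth-admission episode unless withheld, and one infant
#' episode per live-born infant unless withheld; fetal deaths produce no
#' infant episode. Episode fields are copied from the truth and then
#' perturbed under the error model; ICD codes are written to match the
#' generated clinical indicators (era-appropriate revision). Deterministic
#' under `cfg$rng_seed`.
#'
#' @param cfg A [simulation_config()].
#' @return A `natalink_cohort` list: `vitals`, `mother_episodes`,
#'   `infant_episodes`, `truth` (record_id to true episode ids and applied
#'   perturbations), and `config`.
#' @examples
#' sim <- simulate_cohort(simulation_config(n_deliveries = 20, rng_seed = 7))
#' nrow(sim$vitals) >= 20
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "natalink_simulation_config"))
  with_rng(cfg$rng_seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  nd <- cfg$n_deliveries
  sets <- default_code_sets()

  hospitals <- sprintf("H%03d", seq_len(cfg$n_hospitals))
  zips <- sprintf("9%04d", sample.int(9999L, cfg$n_zips))
  counties <- sprintf("C%02d", (seq_len(cfg$n_zips) %% 12L) + 1L)

  # delivery-level draws
  year <- sample(seq(cfg$year_range[1], cfg$year_range[2]), nd, replace = TRUE)
  infant_dob <- as.Date(sprintf("%d-01-01", year)) +
    sample.int(365L, nd, replace = TRUE) - 1L
  mother_age <- pmin(pmax(round(rnorm(nd, 29, 6)), 15L), 49L)
  mother_dob <- infant_dob - round(mother_age * 365.25) -
    sample.int(300L, nd, replace = TRUE)
  hospital <- sample(hospitals, nd, replace = TRUE)
  zi <- sample.int(cfg$n_zips, nd, replace = TRUE)
  zip <- zips[zi]
  county <- counties[zi]
  payer <- sample(
    c("private", "public", "self_pay", "other", "unknown"), nd,
    replace = TRUE, prob = c(0.476, 0.448, 0.030, 0.044, 0.002)
  )
  race_eth <- sample(
    c(
      "hispanic", "white_nh", "asian", "black", "amer_indian_alaska_native",
      "hawaiian_pacific_islander", "other", "multiple", "unknown"
    ), nd,
    replace = TRUE,
    prob = c(0.4864, 0.2786, 0.1314, 0.0512, 0.0034, 0.0041, 0.0006, 0.0208, 0.0235)
  )
  education <- sample(
    c("lt12", "12", "gt12", "unknown"), nd,
    replace = TRUE, prob = c(0.1994, 0.2438, 0.5127, 0.0441)
  )
  u <- runif(nd)
  plurality <- ifelse(u < cfg$higher_multiple_rate, "multiple",
    ifelse(u < cfg$higher_multiple_rate + cfg$twin_rate, "twin", "singleton")
  )
  n_fetus <- c(singleton = 1L, twin = 2L, multiple = 3L)[plurality]
  ga_band <- sample(names(cfg$ga_band_probs), nd,
    replace = TRUE, prob = cfg$ga_band_probs
  )
  ga_wk <- vapply(ga_band, function(b) {
    lim <- GA_BAND_LIMITS[[b]]
    sample(seq(lim[1], lim[2]), 1L)
  }, 1L)
  cesarean <- runif(nd) < ifelse(plurality == "singleton", 0.30, 0.72)
  previous_cesarean <- runif(nd) < 0.14
  ssn <- sprintf("S%08d", sample.int(99999999L, nd))

  com <- cfg$comorbidities
  com_true <- com_vs <- com_hosp <- matrix(
    FALSE, nd, nrow(com),
    dimnames = list(NULL, com$indicator)
  )
  for (j in seq_len(nrow(com))) {
    com_true[, j] <- runif(nd) < com$prevalence[j]
    com_vs[, j] <- com_true[, j] & runif(nd) < com$sens_vs[j]
    com_hosp[, j] <- com_true[, j] & runif(nd) < com$sens_hospital[j]
  }

  # fetus-level records
  del <- rep(seq_len(nd), n_fetus)
  order_in_set <- sequence(n_fetus)
  nf <- length(del)
  record_id <- sprintf("r%06d", seq_len(nf))
  sibling_set <- sprintf("d%05d", del)
  fetal_death <- runif(nf) < cfg$fetal_death_rate
  sex <- sample(c("M", "F"), nf, replace = TRUE, prob = c(0.512, 0.488))
  bw_mean <- unname(c(
    "20-27" = 850, "28-31" = 1500, "32-36" = 2500,
    "37-42" = 3400, "43-44" = 3600
  )[ga_band[del]])
  bw_sd <- unname(c(
    "20-27" = 250, "28-31" = 350, "32-36" = 480,
    "37-42" = 440, "43-44" = 450
  )[ga_band[del]])
  birthweight <- as.integer(pmin(pmax(round(rnorm(nf, bw_mean, bw_sd)), 300L), 5800L))
  # small/large for gestational age: beyond ~10th/90th centile of the
  # band-specific weight distribution
  sga_fetus <- abs((birthweight - bw_mean) / bw_sd) > 1.28
  infant_death <- !fetal_death &
    runif(nf) < unname(cfg$infant_death_probs[ga_band[del]])

  vitals <- tibble(
    record_id = record_id,
    year = year[del],
    is_fetal_death = fetal_death,
    mother_dob = mother_dob[del],
    infant_dob = infant_dob[del],
    hospital_id = hospital[del],
    zip = zip[del],
    county = county[del],
    payer = payer[del],
    race_eth = race_eth[del],
    infant_sex = sex,
    gestational_age_wk = ga_wk[del],
    birthweight_g = birthweight,
    plurality = plurality[del],
    birth_order = order_in_set,
    cesarean = cesarean[del],
    previous_cesarean = previous_cesarean[del],
    sga_lga = sga_fetus,
    infant_death = ifelse(fetal_death, NA, infant_death),
    education_yrs = education[del],
    mother_age_yrs = mother_age[del],
    sibling_set_id = sibling_set
  )
  for (j in seq_len(nrow(com))) {
    vitals[[com$indicator[j]]] <- com_vs[del, j]
  }
  vitals <- vitals[, vital_dictionary()$name]

  icd10_era <- year >= 2016L

  # --- maternal birth-admission episodes (one per delivery) ---
  ga_band_set <- ifelse(ga_wk < 29, "ga_lt29",
    ifelse(ga_wk < 37, "ga_29to36", ifelse(ga_wk <= 42, "ga_37to42", "ga_gt42"))
  )
  plu_set <- c(
    singleton = "plurality_singleton", twin = "plurality_twin",
    multiple = "plurality_multiple"
  )[plurality]

  del_bw_band <- vital_bw_band(birthweight[match(seq_len(nd), del)])
  del_sga <- as.vector(tapply(sga_fetus, del, any))
  bw_set <- c(
    lt2500 = "bw_lt2500", `2500to4499` = "bw_2500to4499", ge4500 = "bw_ge4500"
  )[del_bw_band]

  # vectorized era-appropriate code per row given a per-row set name
  code_for <- function(set_names, era) {
    out <- rep(NA_character_, length(era))
    for (s in unique(set_names)) {
      sel <- set_names == s
      out[sel] <- pick_code(sets[[s]], era[sel])
    }
    out
  }
  m_dx <- join_codes(
    code_for(ga_band_set, icd10_era),
    code_for(plu_set, icd10_era),
    code_for(bw_set, icd10_era & bw_set != "bw_2500to4499"),
    ifelse(del_sga, pick_code(sets$sga_lga, icd10_era), NA_character_),
    ifelse(cesarean, ifelse(icd10_era, "icd10:O82", "icd9:669.7"), NA_character_),
    ifelse(previous_cesarean,
      pick_code(sets$previous_cesarean, icd10_era), NA_character_
    ),
    ifelse(com_hosp[, "gestational_diabetes"],
      ifelse(icd10_era, "icd10:O24.4", "icd9:648.8"), NA_character_
    ),
    ifelse(com_hosp[, "preexisting_diabetes"],
      ifelse(icd10_era, "icd10:O24.0", "icd9:648.0"), NA_character_
    ),
    ifelse(com_hosp[, "prepregnancy_hypertension"],
      ifelse(icd10_era, "icd10:O10", "icd9:642.0"), NA_character_
    ),
    ifelse(com_hosp[, "gestational_hypertension"],
      ifelse(icd10_era, "icd10:O13", "icd9:642.4"), NA_character_
    ),
    ifelse(com_hosp[, "eclampsia"],
      ifelse(icd10_era, "icd10:O15", "icd9:642.6"), NA_character_
    ),
    ifelse(com_hosp[, "placental_abruption"],
      ifelse(icd10_era, "icd10:O45", "icd9:641.2"), NA_character_
    ),
    ifelse(com_hosp[, "chorioamnionitis"],
      ifelse(icd10_era, "icd10:O41.12", "icd9:658.4"), NA_character_
    )
  )
  m_proc <- ifelse(cesarean, ifelse(icd10_era, "icd10:10D", "icd9:74"), NA_character_)

  admit <- infant_dob - (runif(nd) < 0.5)
  discharge <- infant_dob + ifelse(cesarean, 3L, 2L)
  # the delivery's infant-death status reaches the maternal abstract only
  # through the infant record; maternal discharge status stays routine
  mother_episodes <- tibble(
    episode_id = sprintf("m%06d", seq_len(nd)),
    person_role = "mother",
    record_type = "PDD",
    hospital_id = hospital,
    admit_date = admit,
    discharge_date = discharge,
    patient_dob = mother_dob,
    zip = zip,
    county = county,
    payer = payer,
    race_eth = race_eth,
    sex = "F",
    diagnosis_codes = m_dx,
    procedure_codes = m_proc,
    mdc = 14L,
    discharge_status = "routine",
    enc_ssn = ifelse(runif(nd) < cfg$enc_ssn_mother, ssn, NA_character_),
    age_at_admission_yrs = mother_age
  )

  # --- infant birth-admission episodes (one per live-born fetus) ---
  live <- which(!fetal_death)
  nl <- length(live)
  dli <- del[live]
  era_i <- icd10_era[dli]
  ga_set_i <- ga_band_set[dli]
  plu_set_i <- plu_set[dli]
  bw_band_i <- vital_bw_band(birthweight[live])
  bw_set_i <- c(
    lt2500 = "bw_lt2500", `2500to4499` = "bw_2500to4499", ge4500 = "bw_ge4500"
  )[bw_band_i]
  sga_i <- sga_fetus[live]

  i_dx <- join_codes(
    code_for(ga_set_i, era_i),
    code_for(plu_set_i, era_i),
    code_for(bw_set_i, era_i & bw_set_i != "bw_2500to4499"),
    ifelse(sga_i, ifelse(era_i, "icd10:P05", "icd9:764.0"), NA_character_),
    ifelse(cesarean[dli], ifelse(era_i, "icd10:P03.4", "icd9:763.4"), NA_character_),
    ifelse(com_hosp[dli, "neural_tube_defect"],
      ifelse(era_i, "icd10:Q00", "icd9:740"), NA_character_
    ),
    ifelse(com_hosp[dli, "gastroschisis_omphalocele"],
      ifelse(era_i, "icd10:Q79.3", "icd9:756.73"), NA_character_
    ),
    ifelse(com_hosp[dli, "cleft_lip_palate"],
      ifelse(era_i, "icd10:Q37", "icd9:749"), NA_character_
    ),
    ifelse(com_hosp[dli, "major_heart_defect"],
      ifelse(era_i, "icd10:Q21", "icd9:745"), NA_character_
    )
  )
  stay <- ifelse(ga_wk[dli] < 29, 21L, ifelse(ga_wk[dli] < 37, 7L, 2L))
  infant_episodes <- tibble(
    episode_id = sprintf("i%06d", seq_len(nl)),
    person_role = "infant",
    record_type = "PDD",
    hospital_id = hospital[dli],
    admit_date = infant_dob[dli],
    discharge_date = infant_dob[dli] + stay,
    patient_dob = infant_dob[dli],
    zip = zip[dli],
    county = county[dli],
    payer = payer[dli],
    race_eth = race_eth[dli],
    sex = sex[live],
    diagnosis_codes = i_dx,
    procedure_codes = NA_character_,
    mdc = NA_integer_,
    discharge_status = ifelse(infant_death[live], "died", "routine"),
    enc_ssn = ifelse(runif(nl) < cfg$enc_ssn_infant,
      sprintf("T%08d", sample.int(99999999L, nl)), NA_character_
    ),
    age_at_admission_yrs = 0L
  )

  # --- withholding and perturbation ---
  mother_kept <- runif(nd) >= cfg$p_mother_unlinked
  infant_kept <- runif(nl) >= cfg$p_infant_unlinked

  mother_out <- perturb_record(mother_episodes[mother_kept, , drop = FALSE], cfg)
  infant_out <- perturb_record(infant_episodes[infant_kept, , drop = FALSE], cfg)
  m_log <- setNames(attr(mother_out, "perturbations"), mother_out$episode_id)
  i_log <- setNames(attr(infant_out, "perturbations"), infant_out$episode_id)

  true_m <- ifelse(mother_kept[del], sprintf("m%06d", del), NA_character_)
  infant_ep_of <- rep(NA_character_, nf)
  infant_ep_of[live] <- ifelse(infant_kept, sprintf("i%06d", seq_len(nl)), NA_character_)

  pert <- function(ids, log) {
    out <- log[ids]
    out[is.na(ids) | !(ids %in% names(log))] <- ""
    unname(out)
  }
  truth <- tibble(
    record_id = record_id,
    mother_episode_id = true_m,
    infant_episode_id = infant_ep_of,
    mother_perturbations = pert(true_m, m_log),
    infant_perturbations = pert(infant_ep_of, i_log)
  )

  structure(
    list(
      vitals = vitals,
      mother_episodes = as_tibble(mother_out),
      infant_episodes = as_tibble(infant_out),
      truth = truth,
      config = cfg
    ),
    class = "natalink_cohort"
  )
}

#' @export
print.natalink_cohort <- function(x, ...) {
  cat(
    "<natalink synthetic cohort: ", nrow(x$vitals), " vital records, ",
    nrow(x$mother_episodes), " maternal / ", nrow(x$infant_episodes),
    " infant episodes>\n",
    sep = ""
  )
  invisible(x)
}
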