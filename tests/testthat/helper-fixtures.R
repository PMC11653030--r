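# Programmatic fixtures: single-record constructors with field overrides.

make_vital <- function(...) {
  base <- tibble::tibble(
    record_id = "r000001", year = 2018L, is_fetal_death = FALSE,
    mother_dob = as.Date("1990-03-07"), infant_dob = as.Date("2018-06-15"),
    hospital_id = "H001", zip = "90210", county = "C01",
    payer = "private", race_eth = "hispanic", infant_sex = "F",
    gestational_age_wk = 39L, birthweight_g = 3300L,
    plurality = "singleton", birth_order = 1L,
    cesarean = FALSE, previous_cesarean = FALSE, sga_lga = FALSE,
    infant_death = FALSE,
    gestational_diabetes = FALSE, preexisting_diabetes = FALSE,
    prepregnancy_hypertension = FALSE, gestational_hypertension = FALSE,
    eclampsia = FALSE, placental_abruption = FALSE, chorioamnionitis = FALSE,
    neural_tube_defect = FALSE, gastroschisis_omphalocele = FALSE,
    cleft_lip_palate = FALSE, major_heart_defect = FALSE,
    education_yrs = "gt12", mother_age_yrs = 28L, sibling_set_id = "d00001"
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

make_episode <- function(...) {
  base <- tibble::tibble(
    episode_id = "e000001", person_role = "mother", record_type = "PDD",
    hospital_id = "H001", admit_date = as.Date("2018-06-14"),
    discharge_date = as.Date("2018-06-17"), patient_dob = as.Date("1990-03-07"),
    zip = "90210", county = "C01", payer = "private", race_eth = "hispanic",
    sex = "F", diagnosis_codes = "", procedure_codes = "",
    mdc = 14L, discharge_status = "routine", enc_ssn = NA_character_,
    age_at_admission_yrs = 28L
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# a vital/episode pair concordant at the highest-scoring level of every
# variable: preterm <29 wk, birthweight <2500 g, minority race match, twin
# plurality, infant death, cesarean with previous cesarean, hypertension and
# diabetes coded on both sides
make_allmax_pair <- function() {
  vital <- make_vital(
    infant_sex = "F", gestational_age_wk = 27L, birthweight_g = 900L,
    plurality = "twin", cesarean = TRUE, previous_cesarean = TRUE,
    sga_lga = TRUE, infant_death = TRUE, gestational_diabetes = TRUE,
    gestational_hypertension = TRUE, race_eth = "black"
  )
  episode <- make_episode(
    race_eth = "black",
    diagnosis_codes = paste(
      "icd10:P07.2", "icd10:O30.0", "icd10:P05.01", "icd10:P05",
      "icd10:O82", "icd10:O34.2", "icd10:O24.4", "icd10:O13",
      sep = ";"
    ),
    procedure_codes = "icd10:10D",
    discharge_status = "died"
  )
  list(vital = vital, episode = episode)
}

# small noisy instances for engine-vs-oracle comparisons
make_instance <- function(seed, n_deliveries = 60) {
  cfg <- simulation_config(
    n_deliveries = n_deliveries, rng_seed = seed,
    p_mother_unlinked = 0.08, p_infant_unlinked = 0.05,
    p_dob_transposed = 0.05, p_field_missing = 0.05, p_zip_error = 0.05,
    n_hospitals = 6L, n_zips = 8L, year_range = c(2014L, 2016L)
  )
  simulate_cohort(cfg)
}

# drop reader/diagnostic attributes for content comparisons
strip_attrs <- function(x) {
  attr(x, "diagnostics") <- NULL
  attr(x, "perturbations") <- NULL
  as.data.frame(x)
}
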