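test_that("date comparison distinguishes exact, transposed and year-shift", {
  d <- function(x) as.Date(x)
  expect_equal(compare_date(d("1990-03-07"), d("1990-07-03")), "transposed")
  expect_equal(compare_date(d("1990-03-07"), d("1990-03-07")), "exact")
  expect_equal(compare_date(d("1990-03-07"), d("1991-03-07")), "year_differs")
  expect_equal(compare_date(d("1990-03-07"), d("1990-03-08")), "none")
  expect_equal(compare_date(d("1990-05-05"), d("1990-05-05")), "exact")
  # month == day can never be transposed-distinct
  expect_equal(compare_date(d("1990-05-05"), d("1991-05-05")), "year_differs")
  expect_equal(compare_date(as.Date(NA), d("1990-03-07")), "none")
})

test_that("date comparison is symmetric", {
  set.seed(9)
  a <- as.Date("1980-01-01") + sample.int(12000L, 300L)
  b <- as.Date("1980-01-01") + sample.int(12000L, 300L)
  swap <- sample(c(TRUE, FALSE), 300, replace = TRUE)
  b[swap] <- as.Date(sprintf(
    "%s-%02d-%02d",
    format(a[swap], "%Y"),
    as.integer(format(a[swap], "%d")) %% 12 + 1L,
    as.integer(format(a[swap], "%m"))
  ))
  expect_equal(compare_date(a, b), compare_date(b, a))
})

test_that("the sum of per-variable maxima is 148 and the all-max pair attains it", {
  expect_equal(spec_max_total(comparator_spec()), 148L)
  p <- make_allmax_pair()
  b <- score_mother_pair(p$vital, p$episode)
  expect_equal(b$total, 148L)
  expect_equal(sum(b$breakdown$points), 148L)
  expect_true(all(unlist(b$required_flags[c(
    "mother_dob_linked", "infant_dob_linked", "hospital_linked",
    "other_variable_linked"
  )])))
  expect_false(b$required_flags$dob_relaxation_used)
})

test_that("an all-missing or fully discordant pair scores zero", {
  v <- make_vital(
    mother_dob = as.Date(NA), infant_dob = as.Date("2018-06-15"),
    hospital_id = NA_character_, zip = NA_character_, county = NA_character_,
    payer = "unknown", race_eth = "unknown", infant_sex = "unknown",
    gestational_age_wk = NA_integer_, birthweight_g = NA_integer_,
    cesarean = FALSE, infant_death = FALSE
  )
  e <- make_episode(
    patient_dob = as.Date(NA), hospital_id = NA_character_,
    zip = NA_character_, county = NA_character_, payer = "unknown",
    race_eth = "unknown", sex = "unknown",
    admit_date = as.Date("2001-01-01"), discharge_date = as.Date("2001-01-02")
  )
  b <- score_mother_pair(v, e)
  expect_equal(b$total, 0L)
  bi <- score_infant_pair(v, e)
  expect_equal(bi$total, 0L)
})

test_that("a required-triple-only pair scores 30 with no other variable linked", {
  v <- make_vital(
    zip = NA_character_, county = NA_character_, payer = "unknown",
    race_eth = "unknown", infant_sex = "unknown",
    gestational_age_wk = NA_integer_, birthweight_g = NA_integer_,
    plurality = "twin" # discordant with unmarked episode
  )
  e <- make_episode(
    zip = NA_character_, county = NA_character_, payer = "unknown",
    race_eth = "unknown", sex = "unknown"
  )
  b <- score_mother_pair(v, e)
  expect_equal(b$total, 30L)
  expect_true(b$required_flags$mother_dob_linked)
  expect_true(b$required_flags$infant_dob_linked)
  expect_true(b$required_flags$hospital_linked)
  expect_false(b$required_flags$other_variable_linked)
})

test_that("transposed mother date of birth contributes exactly 5 points", {
  v <- make_vital(mother_dob = as.Date("1990-03-07"))
  e <- make_episode(
    patient_dob = as.Date("1990-07-03"), hospital_id = "H999",
    zip = NA_character_, county = NA_character_, payer = "unknown",
    race_eth = "unknown", sex = "unknown",
    admit_date = as.Date("2001-01-01"), discharge_date = as.Date("2001-01-02")
  )
  b <- score_mother_pair(v, e)
  row <- b$breakdown[b$breakdown$variable == "mother_dob", ]
  expect_equal(row$level, "transposed")
  expect_equal(row$points, 5L)
  expect_equal(b$total, 5L)
  expect_true(b$required_flags$dob_relaxation_used)
})

test_that("infant-side scoring omits the mother DOB and records the sex flag", {
  v <- make_vital(
    infant_sex = "M", gestational_age_wk = 26L, birthweight_g = 800L,
    infant_death = TRUE, zip = NA_character_, county = NA_character_,
    payer = "unknown", race_eth = "unknown", plurality = "twin"
  )
  e <- make_episode(
    person_role = "infant", patient_dob = as.Date("2018-06-15"), sex = "M",
    diagnosis_codes = "icd10:P07.2;icd10:P07.0", discharge_status = "died",
    zip = NA_character_, county = NA_character_, payer = "unknown",
    race_eth = "unknown"
  )
  b <- score_infant_pair(v, e)
  expect_false("mother_dob" %in% b$breakdown$variable)
  # infant dob 10 + hospital 10 + sex 2 + GA<29 20 + bw<2500 10 + death 10
  expect_equal(b$total, 62L)
  expect_gte(b$total, 52L)
  expect_true(b$sex_concordant)

  e2 <- e
  e2$sex <- "F"
  b2 <- score_infant_pair(v, e2)
  expect_false(b2$sex_concordant)
  expect_equal(b2$total, b$total - 2L)
})

test_that("race scoring is additive: minority match 10, white match 7", {
  v <- make_vital(race_eth = "black")
  e <- make_episode(race_eth = "black")
  b <- score_mother_pair(v, e)
  expect_equal(b$breakdown$points[b$breakdown$variable == "race"], 10L)
  v2 <- make_vital(race_eth = "white_nh")
  e2 <- make_episode(race_eth = "white_nh")
  b2 <- score_mother_pair(v2, e2)
  expect_equal(b2$breakdown$points[b2$breakdown$variable == "race"], 7L)
  # white/hispanic discordant on ethnicity as well as race
  b3 <- score_mother_pair(v2, make_episode(race_eth = "hispanic"))
  expect_equal(b3$breakdown$points[b3$breakdown$variable == "race"], 0L)
  expect_equal(b3$breakdown$points[b3$breakdown$variable == "ethnicity"], 0L)
})

test_that("breakdown totals equal the sum of contributions and match the oracle", {
  set.seed(77)
  sim <- make_instance(77, n_deliveries = 40)
  v <- sim$vitals
  eps <- sim$mother_episodes
  ind <- derive_indicators(eps)
  for (k in 1:200) {
    vi <- sample.int(nrow(v), 1)
    ei <- sample.int(nrow(eps), 1)
    b <- score_mother_pair(v[vi, ], eps[ei, ], ind[ei, ])
    expect_equal(b$total, sum(b$breakdown$points))
    expect_gte(b$total, 0L)
    expect_lte(b$total, 148L)
    o <- oracle_score1(v[vi, ], eps[ei, ], ind[ei, ], "mother")
    expect_equal(b$total, o$total, label = paste("pair", vi, ei))
  }
  ieps <- sim$infant_episodes
  iind <- derive_indicators(ieps)
  for (k in 1:200) {
    vi <- sample.int(nrow(v), 1)
    ei <- sample.int(nrow(ieps), 1)
    b <- score_infant_pair(v[vi, ], ieps[ei, ], iind[ei, ])
    o <- oracle_score1(v[vi, ], ieps[ei, ], iind[ei, ], "infant")
    expect_equal(b$total, sum(b$breakdown$points))
    expect_equal(b$total, o$total)
  }
})

test_that("making any concordant variable discordant never increases the score", {
  p <- make_allmax_pair()
  base <- score_mother_pair(p$vital, p$episode)$total
  degrade <- list(
    function(v, e) { e$patient_dob <- as.Date("1971-01-19"); list(v, e) },
    function(v, e) { e$hospital_id <- "H999"; list(v, e) },
    function(v, e) { v$infant_dob <- as.Date("2019-06-15"); list(v, e) },
    function(v, e) { e$zip <- "00000"; list(v, e) },
    function(v, e) { e$diagnosis_codes <- sub("icd10:P07.2;", "", e$diagnosis_codes); list(v, e) },
    function(v, e) { e$sex <- "M"; list(v, e) },
    function(v, e) { e$payer <- "self_pay"; list(v, e) },
    function(v, e) { e$race_eth <- "asian"; list(v, e) },
    function(v, e) { e$county <- "C99"; list(v, e) },
    function(v, e) { e$discharge_status <- "routine"; list(v, e) },
    function(v, e) { e$procedure_codes <- ""; e$diagnosis_codes <- sub("icd10:O82;", "", e$diagnosis_codes); list(v, e) },
    function(v, e) { v$plurality <- "singleton"; list(v, e) }
  )
  for (f in degrade) {
    pe <- f(p$vital, p$episode)
    expect_lt(score_mother_pair(pe[[1]], pe[[2]])$total, base)
  }
})
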