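test_that("percentages use half-up rounding to two decimals and NA for 0/0", {
  expect_equal(percent_of(7285345, 8040000), 90.61)
  expect_equal(percent_of(680757, 7285345), 9.34)
  expect_equal(percent_of(618325, 7285345), 8.49)
  expect_equal(percent_of(1, 800), 0.13) # 0.125 rounds up, not to even
  expect_equal(percent_of(0, 100), 0)
  expect_true(is.na(percent_of(0, 0)))
})

test_that("linkage rates recompute from counts and partition across strata", {
  sim <- make_instance(51, n_deliveries = 150)
  res <- link_cohort(
    sim$vitals, sim$mother_episodes, sim$infant_episodes,
    linkage_config(rng_seed = 51)
  )
  m <- linkage_rates(res, sim$vitals)
  o <- m$overall
  expect_equal(o$pct_both, percent_of(o$n_linked_both, o$n_total))
  expect_lte(o$n_linked_both, min(o$n_linked_mother, o$n_linked_infant))
  expect_true(all(m$strata$pct_both >= 0 & m$strata$pct_both <= 100, na.rm = TRUE))

  # per-stratum counts sum to the overall counts within every stratum variable
  sums <- m$strata %>%
    dplyr::group_by(stratum) %>%
    dplyr::summarise(
      n = sum(n_total), nm = sum(n_linked_mother), nb = sum(n_linked_both)
    )
  expect_true(all(sums$n == o$n_total))
  expect_true(all(sums$nm == o$n_linked_mother))
  expect_true(all(sums$nb == o$n_linked_both))

  # fetal deaths excluded from the live-birth denominators
  expect_equal(o$n_total + m$fetal_deaths$n_total, nrow(sim$vitals))
  expect_error(linkage_rates(res, sim$vitals, strata = "shoe_size"), "unknown strata")
})

test_that("zero links yield zero rates, not NA", {
  sim <- make_instance(52, n_deliveries = 20)
  res <- link_cohort(
    sim$vitals, sim$mother_episodes[0, ], sim$infant_episodes[0, ],
    linkage_config(rng_seed = 52)
  )
  m <- linkage_rates(res, sim$vitals)
  expect_equal(m$overall$pct_both, 0)
  expect_equal(m$overall$pct_mother, 0)
})

test_that("linked/unlinked distributions sum to 100 within each characteristic", {
  sim <- make_instance(53, n_deliveries = 200)
  res <- link_cohort(
    sim$vitals, sim$mother_episodes, sim$infant_episodes,
    linkage_config(rng_seed = 53)
  )
  tab <- compare_linked_unlinked(res, sim$vitals)
  chk <- tab %>%
    dplyr::group_by(side, characteristic) %>%
    dplyr::summarise(
      l = sum(pct_linked), u = sum(pct_unlinked), .groups = "drop"
    )
  expect_true(all(abs(chk$l - 100) < 0.15))
  expect_true(all(abs(chk$u - 100) < 0.15 | is.na(chk$u)))
})

test_that("differential withholding shows up in the unlinked distribution", {
  # self-pay maternal episodes withheld far more often than others
  cfg <- simulation_config(
    n_deliveries = 1500, rng_seed = 54, p_mother_unlinked = 0.02,
    p_infant_unlinked = 0.02, p_dob_transposed = 0, p_field_missing = 0,
    p_zip_error = 0
  )
  sim <- simulate_cohort(cfg)
  drop_sp <- sim$mother_episodes$payer == "self_pay" &
    natalink:::with_rng(54, runif(nrow(sim$mother_episodes))) < 0.7
  res <- link_cohort(
    sim$vitals, sim$mother_episodes[!drop_sp, ], sim$infant_episodes,
    linkage_config(rng_seed = 54)
  )
  tab <- compare_linked_unlinked(res, sim$vitals, characteristics = "payer")
  sp <- tab[tab$side == "mother" & tab$level == "self_pay", ]
  expect_gt(sp$pct_unlinked, sp$pct_linked)
})

test_that("ascertainment union bounds hold and all-linked edge cases are sane", {
  sim <- make_instance(55, n_deliveries = 300)
  res <- link_cohort(
    sim$vitals, sim$mother_episodes, sim$infant_episodes,
    linkage_config(rng_seed = 55)
  )
  tab <- ascertainment_union(res, sim$vitals, sim$mother_episodes, sim$infant_episodes)
  expect_true(all(tab$n_union <= tab$n_vs + tab$n_hospital))
  expect_true(all(tab$n_union >= pmax(tab$n_vs, tab$n_hospital)))
  expect_true(all(tab$n_linked == tab$n_linked[1]))
  expect_error(
    ascertainment_union(res, sim$vitals, sim$mother_episodes,
      sim$infant_episodes,
      indicators = "nope"
    ),
    "unknown indicators"
  )
})

test_that("prevalence contrast compares population and linked cohort per stratum", {
  sim <- make_instance(56, n_deliveries = 250)
  res <- link_cohort(
    sim$vitals, sim$mother_episodes, sim$infant_episodes,
    linkage_config(rng_seed = 56)
  )
  tab <- prevalence_contrast(res, sim$vitals)
  ov <- tab[tab$level == "overall", ]
  live <- !sim$vitals$is_fetal_death
  expect_equal(
    ov$n_outcome,
    sum(sim$vitals$gestational_age_wk[live] < 37, na.rm = TRUE)
  )
  expect_equal(sum(tab$n_population[-1]), ov$n_population)
  expect_equal(ov$pct_population, percent_of(ov$n_outcome, ov$n_population))
  # when every record is linked the two columns coincide
  cfg0 <- simulation_config(
    n_deliveries = 100, rng_seed = 57, p_mother_unlinked = 0,
    p_infant_unlinked = 0, p_dob_transposed = 0, p_field_missing = 0,
    p_zip_error = 0
  )
  sim0 <- simulate_cohort(cfg0)
  res0 <- link_cohort(
    sim0$vitals, sim0$mother_episodes, sim0$infant_episodes,
    linkage_config(rng_seed = 57)
  )
  tab0 <- prevalence_contrast(res0, sim0$vitals)
  expect_equal(tab0$pct_population, tab0$pct_linked)
})

test_that("GA-differential withholding depresses linked preterm prevalence", {
  cfg <- simulation_config(
    n_deliveries = 2000, rng_seed = 58, p_mother_unlinked = 0,
    p_infant_unlinked = 0, p_dob_transposed = 0, p_field_missing = 0,
    p_zip_error = 0
  )
  sim <- simulate_cohort(cfg)
  # withhold most preterm infant episodes
  ind <- derive_indicators(sim$infant_episodes)
  preterm_ep <- ind$ga_band %in% c("lt29", "29to36")
  drop <- preterm_ep & natalink:::with_rng(58, runif(nrow(ind))) < 0.6
  res <- link_cohort(
    sim$vitals, sim$mother_episodes, sim$infant_episodes[!drop, ],
    linkage_config(rng_seed = 58)
  )
  tab <- prevalence_contrast(res, sim$vitals)
  ov <- tab[tab$level == "overall", ]
  expect_lt(ov$pct_linked, ov$pct_population)
})

test_that("truth metrics match a direct set comparison and are idempotent", {
  sim <- make_instance(59, n_deliveries = 120)
  res <- link_cohort(
    sim$vitals, sim$mother_episodes, sim$infant_episodes,
    linkage_config(rng_seed = 59)
  )
  tm <- truth_metrics(res, sim$truth)
  # brute-force recomputation from raw assignment/truth sets
  a <- res$assignments
  t <- sim$truth
  made <- a$record_id[!is.na(a$mother_episode_id)]
  correct <- sum(vapply(made, function(r) {
    isTRUE(a$mother_episode_id[a$record_id == r] ==
      t$mother_episode_id[t$record_id == r])
  }, TRUE))
  expect_equal(tm$n_correct[tm$side == "mother"], correct)
  expect_equal(tm$n_made[tm$side == "mother"], length(made))
  expect_equal(tm$n_true[tm$side == "mother"], sum(!is.na(t$mother_episode_id)))
  expect_identical(tm, truth_metrics(res, sim$truth))

  # no links: recall 0, precision undefined (NA)
  res0 <- link_cohort(
    sim$vitals, sim$mother_episodes[0, ], sim$infant_episodes[0, ],
    linkage_config(rng_seed = 59)
  )
  tm0 <- truth_metrics(res0, sim$truth)
  expect_true(all(is.na(tm0$precision)))
  expect_equal(tm0$recall, c(0, 0, 0))
})

test_that("tidiers and autoplot methods produce the expected shapes", {
  sim <- make_instance(60, n_deliveries = 80)
  res <- link_cohort(
    sim$vitals, sim$mother_episodes, sim$infant_episodes,
    linkage_config(rng_seed = 60)
  )
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_vitals, nrow(sim$vitals))
  m <- linkage_rates(res, sim$vitals)
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(nrow(glance(m)), 1L)
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(res), "ggplot")
  p <- make_allmax_pair()
  expect_equal(nrow(tidy(score_mother_pair(p$vital, p$episode))), 18L)
})
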