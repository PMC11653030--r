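# Evaluation surfaces: linkage-rate tables, linked-vs-unlinked population
# comparison, dual-source ascertainment, prevalence contrasts, and
# truth-based precision/recall (available only for synthetic cohorts, where
# the true pairing is known). Percentages are reported to two decimals with
# half-up rounding; counts are never rounded; undefined ratios are NA.

GA_STRATA_BREAKS <- c(20, 28, 32, 37, 43, 45)
GA_STRATA_LABELS <- c("20-27", "28-31", "32-36", "37-42", "43-44")

# evaluation strata derived from vital fields
derive_strata <- function(vitals) {
  tibble(
    record_id = vitals$record_id,
    year = as.character(vitals$year),
    age_band = case_when(
      is.na(vitals$mother_age_yrs) ~ "missing",
      vitals$mother_age_yrs < 18 ~ "<18",
      vitals$mother_age_yrs <= 34 ~ "18-34",
      TRUE ~ ">34"
    ),
    payer = ifelse(is.na(vitals$payer), "unknown", vitals$payer),
    race_eth = ifelse(is.na(vitals$race_eth), "unknown", vitals$race_eth),
    education = ifelse(is.na(vitals$education_yrs), "unknown", vitals$education_yrs),
    ga_band = ifelse(
      is.na(vitals$gestational_age_wk), "missing",
      as.character(cut(vitals$gestational_age_wk,
        breaks = GA_STRATA_BREAKS, labels = GA_STRATA_LABELS, right = FALSE
      ))
    ),
    plurality = vitals$plurality,
    infant_death = case_when(
      vitals$is_fetal_death ~ "fetal_death",
      is.na(vitals$infant_death) ~ "missing",
      vitals$infant_death ~ "yes",
      TRUE ~ "no"
    )
  )
}

DEFAULT_STRATA <- c(
  "year", "age_band", "payer", "race_eth", "education", "ga_band",
  "plurality", "infant_death"
)

#' Linkage rates, overall and by stratum
#'
#' Counts and percentages of vital records linked to an episode of the
#' birthing person, of the infant, and of both, overall and within strata of
#' year, maternal age band, payer, race/ethnicity, education,
#' gestational-age band, plurality and infant death. Live births form the
#' denominators; fetal deaths are summarized separately with a
#' birthing-person rate only, since no infant record can exist for them.
#'
#' @param result A `natalink_linkage` from [link_cohort()].
#' @param vitals The vital-record tibble the linkage ran on.
#' @param strata Character vector of stratum variables (subset of the
#'   defaults); unknown names are an error.
#' @param truth Optional truth table; adds precision/recall via
#'   [truth_metrics()].
#' @return A `natalink_metrics` object with `$overall` (one row),
#'   `$strata` (tidy per-level rows), `$fetal_deaths`, and optionally
#'   `$truth`.
#' @export
linkage_rates <- function(result, vitals, strata = DEFAULT_STRATA, truth = NULL) {
  stopifnot(inherits(result, "natalink_linkage"))
  extra <- setdiff(result$assignments$record_id, vitals$record_id)
  if (length(extra)) abort("result refers to records absent from `vitals`")
  bad <- setdiff(strata, DEFAULT_STRATA)
  if (length(bad)) abort(paste0("unknown strata: ", toString(bad)))

  a <- result$assignments
  linked_m <- vitals$record_id %in% a$record_id[!is.na(a$mother_episode_id)]
  linked_i <- vitals$record_id %in% a$record_id[!is.na(a$infant_episode_id)]
  live <- !vitals$is_fetal_death

  overall <- tibble(
    n_total = sum(live),
    n_linked_mother = sum(linked_m & live),
    n_linked_infant = sum(linked_i & live),
    n_linked_both = sum(linked_m & linked_i & live),
    pct_mother = percent_of(sum(linked_m & live), sum(live)),
    pct_infant = percent_of(sum(linked_i & live), sum(live)),
    pct_both = percent_of(sum(linked_m & linked_i & live), sum(live))
  )
  fetal <- tibble(
    n_total = sum(!live),
    n_linked_mother = sum(linked_m & !live),
    pct_mother = percent_of(sum(linked_m & !live), sum(!live))
  )

  st <- derive_strata(vitals)
  per_stratum <- purrr::map(strata, function(sv) {
    d <- tibble(
      level = st[[sv]][live],
      m = linked_m[live], i = linked_i[live], b = (linked_m & linked_i)[live]
    )
    d %>%
      group_by(.data$level) %>%
      summarise(
        n_total = n(),
        n_linked_mother = sum(.data$m),
        n_linked_infant = sum(.data$i),
        n_linked_both = sum(.data$b),
        .groups = "drop"
      ) %>%
      mutate(
        stratum = sv,
        pct_mother = percent_of(.data$n_linked_mother, .data$n_total),
        pct_infant = percent_of(.data$n_linked_infant, .data$n_total),
        pct_both = percent_of(.data$n_linked_both, .data$n_total)
      ) %>%
      relocate("stratum")
  })

  out <- structure(
    list(
      overall = overall,
      strata = bind_rows(per_stratum),
      fetal_deaths = fetal
    ),
    class = "natalink_metrics"
  )
  if (!is.null(truth)) out$truth <- truth_metrics(result, truth, vitals)
  out
}

#' @export
print.natalink_metrics <- function(x, ...) {
  cat("<natalink linkage metrics>\n")
  print(x$overall)
  invisible(x)
}

#' Characteristics of linked versus unlinked records
#'
#' For each side (birthing person, infant), the percentage distribution of
#' each characteristic within the linked and the unlinked subsets of live
#' births — the table used to judge whether unlinked records are unequally
#' distributed (selection bias). All-linked strata keep explicit zero
#' denominators rather than dropping the unlinked column.
#'
#' @inheritParams linkage_rates
#' @param characteristics Stratum variables to tabulate.
#' @return Tidy tibble: `side`, `characteristic`, `level`, counts and
#'   percentages for linked and unlinked subsets.
#' @export
compare_linked_unlinked <- function(result, vitals,
                                    characteristics = DEFAULT_STRATA) {
  stopifnot(inherits(result, "natalink_linkage"))
  a <- result$assignments
  live <- !vitals$is_fetal_death
  st <- derive_strata(vitals)
  sides <- list(
    mother = vitals$record_id %in% a$record_id[!is.na(a$mother_episode_id)],
    infant = vitals$record_id %in% a$record_id[!is.na(a$infant_episode_id)]
  )
  rows <- list()
  for (side in names(sides)) {
    linked <- sides[[side]]
    n_l <- sum(linked & live)
    n_u <- sum(!linked & live)
    for (ch in characteristics) {
      lev <- sort(unique(st[[ch]][live]))
      for (lv in lev) {
        sel <- live & st[[ch]] == lv
        rows[[length(rows) + 1L]] <- tibble(
          side = side, characteristic = ch, level = lv,
          n_linked = sum(sel & linked), pct_linked = percent_of(sum(sel & linked), n_l),
          n_unlinked = sum(sel & !linked), pct_unlinked = percent_of(sum(sel & !linked), n_u)
        )
      }
    }
  }
  bind_rows(rows)
}

ASCERTAINMENT_INDICATORS <- c(
  "gestational_diabetes", "preexisting_diabetes", "prepregnancy_hypertension",
  "gestational_hypertension", "eclampsia", "placental_abruption",
  "chorioamnionitis", "neural_tube_defect", "gastroschisis_omphalocele",
  "cleft_lip_palate", "major_heart_defect", "infant_death"
)

#' Dual-source variable ascertainment
#'
#' Among records linked to both the birthing person's and the infant's
#' episodes, counts each indicator as ascertained from the certificate
#' alone, from the hospital codes alone, and from either source (the
#' union), with percentages over the linked denominator. The union is
#' always at least each single source; querying both sources recovers
#' under-reporting on either one.
#'
#' @inheritParams linkage_rates
#' @param mother_episodes,infant_episodes Episode tibbles the result linked
#'   against (source of the ICD codes).
#' @param indicators Indicator names (default: all packaged ascertainment
#'   indicators).
#' @param code_sets Code sets used to derive hospital-side indicators.
#' @return Tibble: `indicator`, `n_linked`, `n_vs`, `pct_vs`, `n_hospital`,
#'   `pct_hospital`, `n_union`, `pct_union`.
#' @export
ascertainment_union <- function(result, vitals, mother_episodes, infant_episodes,
                                indicators = ASCERTAINMENT_INDICATORS,
                                code_sets = default_code_sets()) {
  stopifnot(inherits(result, "natalink_linkage"))
  bad <- setdiff(indicators, ASCERTAINMENT_INDICATORS)
  if (length(bad)) abort(paste0("unknown indicators: ", toString(bad)))

  a <- result$assignments
  both <- a[!is.na(a$mother_episode_id) & !is.na(a$infant_episode_id), , drop = FALSE]
  vi <- match(both$record_id, vitals$record_id)
  ind_m <- derive_indicators(
    mother_episodes[match(both$mother_episode_id, mother_episodes$episode_id), , drop = FALSE],
    code_sets
  )
  ind_i <- derive_indicators(
    infant_episodes[match(both$infant_episode_id, infant_episodes$episode_id), , drop = FALSE],
    code_sets
  )
  n_linked <- nrow(both)

  rows <- purrr::map(indicators, function(nm) {
    if (nm == "infant_death") {
      vs <- !is.na(vitals$infant_death[vi]) & vitals$infant_death[vi]
      hc <- ind_i$infant_died
    } else {
      v_col <- vitals[[nm]][vi]
      vs <- !is.na(v_col) & v_col
      hc <- (ind_m[[nm]] %||% rep(FALSE, n_linked)) |
        (ind_i[[nm]] %||% rep(FALSE, n_linked))
    }
    tibble(
      indicator = nm, n_linked = n_linked,
      n_vs = sum(vs), pct_vs = percent_of(sum(vs), n_linked),
      n_hospital = sum(hc), pct_hospital = percent_of(sum(hc), n_linked),
      n_union = sum(vs | hc), pct_union = percent_of(sum(vs | hc), n_linked)
    )
  })
  bind_rows(rows)
}

#' Outcome prevalence in the full population versus the linked cohort
#'
#' Contrasts the prevalence of an outcome (default: preterm live birth, 20
#' to <37 completed weeks) between all live-birth vital records and the
#' subset linked to both episode types, overall and within strata — the
#' check for linkage selection bias on the outcome.
#'
#' @inheritParams linkage_rates
#' @param outcome `"preterm"` (the packaged outcome) or a logical vector
#'   aligned with `vitals`.
#' @param strata Stratum variable (default `"race_eth"`).
#' @return Tibble with population and linked counts and percentages per
#'   level, preceded by an overall row.
#' @export
prevalence_contrast <- function(result, vitals, outcome = "preterm",
                                strata = "race_eth") {
  stopifnot(inherits(result, "natalink_linkage"))
  if (identical(outcome, "preterm")) {
    y <- !is.na(vitals$gestational_age_wk) &
      vitals$gestational_age_wk >= 20 & vitals$gestational_age_wk < 37
  } else {
    stopifnot(is.logical(outcome), length(outcome) == nrow(vitals))
    y <- outcome
  }
  a <- result$assignments
  linked <- vitals$record_id %in%
    a$record_id[!is.na(a$mother_episode_id) & !is.na(a$infant_episode_id)]
  live <- !vitals$is_fetal_death
  st <- derive_strata(vitals)[[strata]]
  if (is.null(st)) abort(paste0("unknown stratum variable: ", strata))

  one_row <- function(label, sel) {
    tibble(
      level = label,
      n_population = sum(sel), n_outcome = sum(sel & y),
      pct_population = percent_of(sum(sel & y), sum(sel)),
      n_linked = sum(sel & linked), n_outcome_linked = sum(sel & linked & y),
      pct_linked = percent_of(sum(sel & linked & y), sum(sel & linked))
    )
  }
  bind_rows(
    one_row("overall", live),
    purrr::map(sort(unique(st[live])), function(lv) one_row(lv, live & st == lv))
  )
}

#' Truth-based linkage accuracy
#'
#' Precision (correct links over made links), recall (correct links over
#' truly linkable records) and F1, per side and pooled — the missed-link /
#' false-link error rates that can only be measured when the true pairing is
#' known, i.e. on synthetic cohorts. Undefined ratios (zero denominators)
#' are NA.
#'
#' When `vitals` is supplied, infant links inside an indistinguishable
#' sibling set (same sibling set, sex, birthweight band, delivery mode and
#' survival) count as correct if they land on the true episode of any class
#' member: the truth labeling within such a set is arbitrary — the records
#' are exchangeable and no method can tell them apart — so any within-class
#' permutation is a correct linkage.
#'
#' @param result A `natalink_linkage`.
#' @param truth Truth tibble from [simulate_cohort()].
#' @param vitals Optional vital-record tibble enabling the
#'   exchangeable-twin correction.
#' @return Tibble: `side`, `n_true`, `n_made`, `n_correct`, `precision`,
#'   `recall`, `f1`.
#' @export
truth_metrics <- function(result, truth, vitals = NULL) {
  stopifnot(inherits(result, "natalink_linkage"))
  a <- result$assignments
  extra <- setdiff(a$record_id, truth$record_id)
  if (length(extra)) abort("result refers to records absent from `truth`")

  infant_truth_ok <- function(made_ids, made_eps) {
    t_ep <- truth$infant_episode_id[match(made_ids, truth$record_id)]
    ok <- !is.na(made_eps) & !is.na(t_ep) & made_eps == t_ep
    if (is.null(vitals)) {
      return(ok)
    }
    vi <- match(made_ids, vitals$record_id)
    cls <- paste(
      vitals$sibling_set_id[vi], vitals$infant_sex[vi],
      vital_bw_band(vitals$birthweight_g[vi]),
      ifelse(is.na(vitals$cesarean[vi]), "na", vitals$cesarean[vi]),
      ifelse(is.na(vitals$infant_death[vi]), "na", vitals$infant_death[vi])
    )
    vcls <- paste(
      vitals$sibling_set_id, vitals$infant_sex,
      vital_bw_band(vitals$birthweight_g),
      ifelse(is.na(vitals$cesarean), "na", vitals$cesarean),
      ifelse(is.na(vitals$infant_death), "na", vitals$infant_death)
    )
    class_eps <- split(
      truth$infant_episode_id[match(vitals$record_id, truth$record_id)], vcls
    )
    swap_ok <- purrr::map2_lgl(cls, made_eps, function(cl, ep) {
      !is.na(ep) && ep %in% class_eps[[cl]]
    })
    ok | swap_ok
  }

  side_row <- function(side, made_ids, made_eps, truth_eps) {
    made <- !is.na(made_eps)
    t_ep <- truth_eps[match(made_ids, truth$record_id)]
    correct <- made & !is.na(t_ep) & made_eps == t_ep
    if (side == "infant") correct <- infant_truth_ok(made_ids, made_eps)
    n_true <- sum(!is.na(truth_eps))
    n_made <- sum(made)
    n_correct <- sum(correct)
    precision <- if (n_made > 0) n_correct / n_made else NA_real_
    recall <- if (n_true > 0) n_correct / n_true else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else {
      NA_real_
    }
    tibble(
      side = side, n_true = n_true, n_made = n_made, n_correct = n_correct,
      precision = precision, recall = recall, f1 = f1
    )
  }
  m <- side_row("mother", a$record_id, a$mother_episode_id, truth$mother_episode_id)
  i <- side_row("infant", a$record_id, a$infant_episode_id, truth$infant_episode_id)
  pooled <- tibble(
    side = "overall",
    n_true = m$n_true + i$n_true,
    n_made = m$n_made + i$n_made,
    n_correct = m$n_correct + i$n_correct
  )
  pooled$precision <- ifelse(pooled$n_made > 0, pooled$n_correct / pooled$n_made, NA_real_)
  pooled$recall <- ifelse(pooled$n_true > 0, pooled$n_correct / pooled$n_true, NA_real_)
  pooled$f1 <- ifelse(
    !is.na(pooled$precision) & !is.na(pooled$recall) & pooled$precision + pooled$recall > 0,
    2 * pooled$precision * pooled$recall / (pooled$precision + pooled$recall), NA_real_
  )
  bind_rows(m, i, pooled)
}
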