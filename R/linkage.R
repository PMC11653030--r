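# Multi-pass blocking linkage engine. Each pass restricts comparisons to
# pairs agreeing exactly on a small key set, scores the pairs, filters them
# through the acceptance rules, and assigns episodes greedily in descending
# score order with seeded random tie-breaking. Previously linked vital
# records and consumed episodes are removed before each pass.

#' Define a blocking pass
#'
#' @param label Single-letter pass label, unique within a schedule.
#' @param keys Blocking variables: subset of `mother_dob`, `infant_dob`,
#'   `zip`, `hospital`, `sex`, `payer`, `preterm`.
#' @param dedup_repeat Marks a pass that repeats an earlier key set so that
#'   remaining twin/multiple records can pick up duplicate episodes.
#' @return A `natalink_pass` object.
#' @export
blocking_pass <- function(label, keys, dedup_repeat = FALSE) {
  allowed <- c("mother_dob", "infant_dob", "zip", "hospital", "sex", "payer", "preterm")
  bad <- setdiff(keys, allowed)
  if (length(keys) == 0L || length(bad)) {
    abort(paste0("invalid blocking keys: ", toString(bad)))
  }
  structure(
    list(label = label, keys = keys, dedup_repeat = dedup_repeat),
    class = "natalink_pass"
  )
}

#' Packaged pass schedules
#'
#' The maternal schedule blocks first on the birthing person's date of birth
#' and delivery hospital, then falls back to key sets that tolerate an
#' erroneous birth date or hospital: infant date of birth with zip, infant
#' date of birth with hospital, birthing person's date of birth with zip,
#' zip with hospital, and finally preterm status with infant date of birth.
#' The infant schedule starts from hospital and infant date of birth, with
#' repeat passes so twin and multiple deliveries can pick up their duplicate
#' episodes, then widens to zip-based keys.
#'
#' @return List of [blocking_pass()] objects.
#' @export
maternal_pass_schedule <- function() {
  list(
    blocking_pass("A", c("mother_dob", "hospital")),
    blocking_pass("B", c("infant_dob", "zip")),
    blocking_pass("C", c("infant_dob", "hospital")),
    blocking_pass("D", c("mother_dob", "zip")),
    blocking_pass("E", c("zip", "hospital")),
    blocking_pass("F", c("preterm", "infant_dob"))
  )
}

#' @rdname maternal_pass_schedule
#' @export
infant_pass_schedule <- function() {
  list(
    blocking_pass("A", c("hospital", "infant_dob")),
    blocking_pass("B", c("hospital", "infant_dob"), dedup_repeat = TRUE),
    blocking_pass("C", c("hospital", "infant_dob"), dedup_repeat = TRUE),
    blocking_pass("D", c("hospital", "infant_dob"), dedup_repeat = TRUE),
    blocking_pass("E", c("infant_dob", "zip")),
    blocking_pass("F", c("infant_dob", "zip"), dedup_repeat = TRUE),
    blocking_pass("G", c("zip", "sex")),
    blocking_pass("H", c("zip", "payer")),
    blocking_pass("I", c("zip", "hospital"))
  )
}

#' Linkage configuration
#'
#' @param mother_cutoff Minimum accepted maternal link score (default 40).
#' @param infant_cutoff Minimum accepted infant link score (default 31).
#' @param rng_seed Seed for tie-breaking and twin assignment.
#' @param maternal_passes,infant_passes Pass schedules.
#' @param require_plurality_concordance Drop maternal links for twin or
#'   multiple vital records unless the episode is also coded twin/multiple.
#' @param ssn_requires_extra_variable In longitudinal linkage, a matching
#'   encrypted SSN alone is never sufficient; at least one other variable
#'   must also match (default `TRUE`).
#' @param spec Comparator point table ([comparator_spec()]).
#' @param code_sets Indicator code sets ([default_code_sets()]).
#' @return A validated `natalink_linkage_config`.
#' @export
linkage_config <- function(mother_cutoff = 40L, infant_cutoff = 31L,
                           rng_seed = 1L,
                           maternal_passes = maternal_pass_schedule(),
                           infant_passes = infant_pass_schedule(),
                           require_plurality_concordance = TRUE,
                           ssn_requires_extra_variable = TRUE,
                           spec = comparator_spec(),
                           code_sets = default_code_sets()) {
  problems <- character()
  if (!is.numeric(mother_cutoff) || mother_cutoff <= 0) {
    problems <- c(problems, "mother_cutoff must be a positive integer")
  }
  if (!is.numeric(infant_cutoff) || infant_cutoff <= 0) {
    problems <- c(problems, "infant_cutoff must be a positive integer")
  }
  for (sched in list(maternal_passes, infant_passes)) {
    labels <- vapply(sched, `[[`, "", "label")
    if (anyDuplicated(labels)) {
      problems <- c(problems, paste0("duplicate pass labels: ", toString(labels[duplicated(labels)])))
    }
  }
  if (length(problems)) abort(paste0("invalid linkage config: ", paste(problems, collapse = "; ")))
  structure(
    list(
      mother_cutoff = as.integer(mother_cutoff),
      infant_cutoff = as.integer(infant_cutoff),
      rng_seed = as.integer(rng_seed),
      maternal_passes = maternal_passes,
      infant_passes = infant_passes,
      require_plurality_concordance = isTRUE(require_plurality_concordance),
      ssn_requires_extra_variable = isTRUE(ssn_requires_extra_variable),
      spec = spec,
      code_sets = code_sets
    ),
    class = "natalink_linkage_config"
  )
}

# run code under a locally seeded RNG, restoring the caller's stream
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# one row per calendar day of each episode's stay (stays capped at 30 days),
# used to key the infant date of birth against maternal admission windows
expand_stay_dates <- function(episodes) {
  ok <- !is.na(episodes$admit_date) & !is.na(episodes$discharge_date)
  adm <- episodes$admit_date[ok]
  len <- pmin(as.integer(episodes$discharge_date[ok] - adm), 30L) + 1L
  tibble(
    episode_id = rep(episodes$episode_id[ok], len),
    stay_date = adm[rep(seq_along(adm), len)] + (sequence(len) - 1L)
  )
}

#' Generate candidate pairs for one blocking pass
#'
#' Returns all and only the (vital record, episode) pairs agreeing exactly
#' on every blocking key of the pass. Missing key values never match. On the
#' maternal side the `infant_dob` key matches any day of the episode's
#' admission stay; the `preterm` key restricts both sides to preterm
#' (certificate gestation <37 weeks; episode gestational-age band below 37
#' weeks) rather than partitioning on it.
#'
#' @param vitals Vital-record tibble.
#' @param episodes Hospital-episode tibble.
#' @param pass A [blocking_pass()].
#' @param side `"mother"` or `"infant"`.
#' @param indicators Output of [derive_indicators()] for `episodes`
#'   (required when the pass blocks on `preterm`).
#' @return Tibble with columns `record_id`, `episode_id`.
#' @export
generate_candidates <- function(vitals, episodes, pass, side = c("mother", "infant"),
                                indicators = NULL) {
  side <- match.arg(side)
  v <- tibble(record_id = vitals$record_id)
  e <- tibble(episode_id = episodes$episode_id)
  keys <- pass$keys

  if ("preterm" %in% keys) {
    if (is.null(indicators)) indicators <- derive_indicators(episodes)
    v_pre <- !is.na(vitals$gestational_age_wk) & vitals$gestational_age_wk < 37
    e_pre <- indicators$ga_band %in% c("lt29", "29to36")
    v <- v[v_pre, , drop = FALSE]
    e <- e[e_pre, , drop = FALSE]
    vitals <- vitals[v_pre, , drop = FALSE]
    episodes <- episodes[e_pre, , drop = FALSE]
    keys <- setdiff(keys, "preterm")
  }

  needs_stay <- side == "mother" && "infant_dob" %in% keys
  if (needs_stay) {
    stays <- expand_stay_dates(episodes)
    e <- inner_join(e, stays, by = "episode_id")
    epos <- match(e$episode_id, episodes$episode_id)
  } else {
    epos <- seq_len(nrow(e))
  }

  for (k in keys) {
    v[[paste0("k_", k)]] <- switch(k,
      mother_dob = vitals$mother_dob,
      infant_dob = vitals$infant_dob,
      zip = vitals$zip,
      hospital = vitals$hospital_id,
      sex = vitals$infant_sex,
      payer = vitals$payer
    )
    e[[paste0("k_", k)]] <- switch(k,
      mother_dob = episodes$patient_dob[epos],
      infant_dob = if (needs_stay) e$stay_date else episodes$patient_dob[epos],
      zip = episodes$zip[epos],
      hospital = episodes$hospital_id[epos],
      sex = episodes$sex[epos],
      payer = episodes$payer[epos]
    )
  }
  kcols <- paste0("k_", keys)
  v <- v[stats::complete.cases(v[kcols]), , drop = FALSE]
  e <- e[stats::complete.cases(e[kcols]), , drop = FALSE]
  out <- inner_join(v, e, by = kcols, relationship = "many-to-many")
  distinct(out[, c("record_id", "episode_id")])
}

#' Acceptance rules
#'
#' A maternal candidate is accepted when the required triple is linked (the
#' birthing person's date of birth — exactly, or month/day transposed, or
#' with a differing year —, the infant's date of birth, and the hospital),
#' at least one other variable is linked, and the total score reaches the
#' maternal cutoff. An infant candidate is accepted when infant sex is
#' concordant and the total reaches the infant cutoff; discordant sex is
#' never accepted regardless of score.
#'
#' @param b A `natalink_score` from [score_mother_pair()] /
#'   [score_infant_pair()].
#' @param cfg A [linkage_config()].
#' @return Logical flag.
#' @export
accept_mother <- function(b, cfg = linkage_config()) {
  stopifnot(inherits(b, "natalink_score"))
  f <- b$required_flags
  f$mother_dob_linked && f$infant_dob_linked && f$hospital_linked &&
    f$other_variable_linked && b$total >= cfg$mother_cutoff
}

#' @rdname accept_mother
#' @export
accept_infant <- function(b, cfg = linkage_config()) {
  stopifnot(inherits(b, "natalink_score"))
  b$sex_concordant && b$total >= cfg$infant_cutoff
}

# vectorized acceptance over a scored candidate table
accept_rows <- function(scored, side, cfg, v_plurality = NULL) {
  if (side == "mother") {
    ok <- scored$mother_dob_linked & scored$infant_dob_linked &
      scored$hospital_linked & scored$other_variable_linked &
      scored$total >= cfg$mother_cutoff
    if (cfg$require_plurality_concordance && !is.null(v_plurality)) {
      multi <- !is.na(v_plurality) & v_plurality %in% c("twin", "multiple")
      ok <- ok & (!multi | scored$plurality_multi_both)
    }
    ok
  } else {
    scored$sex_concordant & scored$total >= cfg$infant_cutoff
  }
}

#' Assign episodes to vital records from scored, accepted candidates
#'
#' Greedy selection in descending score order: the highest-scoring pair is
#' assigned first, so a contested episode goes to its higher-scoring
#' claimant; equal-score claimants are taken in record-id order. When one
#' record holds several equally maximal candidates, one is chosen uniformly
#' at random from the seeded generator and flagged `tiebreak`. Each episode
#' is consumed at most once, except that a maternal episode may be shared by
#' records of one sibling set.
#'
#' @param cands Tibble of accepted candidates: `record_id`, `episode_id`,
#'   `total`.
#' @param share_by Optional named character vector mapping `record_id` to a
#'   sibling-set id; enables maternal episode sharing within a set.
#' @param consumed_owners Named character vector of episodes consumed in
#'   earlier passes (value: owning sibling-set id, or `""`).
#' @return Tibble `record_id`, `episode_id`, `score`, `tiebreak` plus the
#'   updated consumption map in attribute `consumed_owners`.
#' @export
select_best <- function(cands, share_by = NULL, consumed_owners = character()) {
  if (nrow(cands) == 0L) {
    out <- tibble(
      record_id = character(), episode_id = character(),
      score = integer(), tiebreak = logical()
    )
    attr(out, "consumed_owners") <- consumed_owners
    return(out)
  }
  ord <- order(-cands$total, cands$record_id, cands$episode_id)
  cands <- cands[ord, , drop = FALSE]
  u <- runif(nrow(cands)) # tie-break keys, drawn in canonical order
  ord2 <- order(-cands$total, cands$record_id, u)
  cands <- cands[ord2, , drop = FALSE]

  rid <- cands$record_id
  eid <- cands$episode_id
  tot <- cands$total
  set_of <- function(r) if (is.null(share_by)) "" else share_by[[r]] %||% ""

  assigned <- new.env(parent = emptyenv())
  consumed <- new.env(parent = emptyenv())
  for (nm in names(consumed_owners)) assign(nm, consumed_owners[[nm]], envir = consumed)

  available <- function(i, r_set) {
    owner <- if (exists(eid[i], envir = consumed, inherits = FALSE)) {
      get(eid[i], envir = consumed)
    } else {
      NULL
    }
    is.null(owner) || (!is.null(share_by) && nzchar(r_set) && identical(owner, r_set))
  }

  res_r <- character(); res_e <- character(); res_s <- integer(); res_t <- logical()
  i <- 1L
  n <- length(rid)
  while (i <= n) {
    r <- rid[i]
    if (exists(r, envir = assigned, inherits = FALSE)) {
      i <- i + 1L
      next
    }
    r_set <- set_of(r)
    if (!available(i, r_set)) {
      i <- i + 1L
      next
    }
    # group = this record's candidates at this score; count availability for
    # the tiebreak flag
    j <- i
    n_avail <- 0L
    while (j <= n && rid[j] == r && tot[j] == tot[i]) {
      if (available(j, r_set)) n_avail <- n_avail + 1L
      j <- j + 1L
    }
    res_r <- c(res_r, r)
    res_e <- c(res_e, eid[i])
    res_s <- c(res_s, tot[i])
    res_t <- c(res_t, n_avail > 1L)
    assign(r, TRUE, envir = assigned)
    assign(eid[i], r_set, envir = consumed)
    i <- i + 1L
  }
  out <- tibble(record_id = res_r, episode_id = res_e, score = res_s, tiebreak = res_t)
  owners <- as.list(consumed)
  attr(out, "consumed_owners") <- setNames(
    vapply(owners, identity, ""),
    names(owners)
  )
  out
}

# score candidate id pairs against full tables; returns scored table with ids
score_candidates <- function(cand_ids, vitals, episodes, indicators, spec, side) {
  vi <- match(cand_ids$record_id, vitals$record_id)
  ei <- match(cand_ids$episode_id, episodes$episode_id)
  scored <- score_pair_table(
    vitals[vi, , drop = FALSE], episodes[ei, , drop = FALSE],
    indicators[ei, , drop = FALSE], spec, side
  )
  scored$record_id <- cand_ids$record_id
  scored$episode_id <- cand_ids$episode_id
  scored$v_plurality <- vitals$plurality[vi]
  scored
}

run_passes <- function(vitals, episodes, cfg, side) {
  passes <- if (side == "mother") cfg$maternal_passes else cfg$infant_passes
  indicators <- derive_indicators(episodes, cfg$code_sets)
  share_by <- NULL
  if (side == "mother") {
    share_by <- setNames(vitals$sibling_set_id, vitals$record_id)
  }
  consumed <- character()
  assignments <- list()
  pass_counts <- list()
  linked_ids <- character()

  for (pass in passes) {
    remaining <- vitals[!(vitals$record_id %in% linked_ids), , drop = FALSE]
    if (nrow(remaining) == 0L) {
      pass_counts[[pass$label]] <- tibble(
        pass = pass$label, candidates = 0L, accepted = 0L, assigned = 0L
      )
      next
    }
    cand_ids <- generate_candidates(remaining, episodes, pass, side, indicators)
    # availability: unconsumed, or a maternal episode owned by this record's set
    if (nrow(cand_ids) > 0L && length(consumed)) {
      owner <- consumed[cand_ids$episode_id]
      free <- is.na(owner)
      if (side == "mother") {
        free <- free | owner == share_by[cand_ids$record_id]
      }
      cand_ids <- cand_ids[free, , drop = FALSE]
    }
    n_cand <- nrow(cand_ids)
    if (n_cand == 0L) {
      pass_counts[[pass$label]] <- tibble(
        pass = pass$label, candidates = 0L, accepted = 0L, assigned = 0L
      )
      next
    }
    scored <- score_candidates(cand_ids, vitals, episodes, indicators, cfg$spec, side)
    ok <- accept_rows(scored, side, cfg, scored$v_plurality)
    acc <- scored[ok, c("record_id", "episode_id", "total"), drop = FALSE]
    sel <- select_best(acc, share_by = share_by, consumed_owners = consumed)
    consumed <- attr(sel, "consumed_owners")
    if (nrow(sel)) {
      sel$pass <- pass$label
      assignments[[length(assignments) + 1L]] <- sel
      linked_ids <- c(linked_ids, sel$record_id)
    }
    pass_counts[[pass$label]] <- tibble(
      pass = pass$label, candidates = n_cand, accepted = sum(ok),
      assigned = nrow(sel)
    )
  }
  list(
    assignments = if (length(assignments)) bind_rows(assignments) else {
      tibble(
        record_id = character(), episode_id = character(),
        score = integer(), tiebreak = logical(), pass = character()
      )
    },
    pass_counts = bind_rows(pass_counts)
  )
}

#' Link vital records to the birthing person's delivery episodes
#'
#' Runs the maternal pass schedule A..F: blocking, scoring, acceptance
#' (required triple, one other variable, score cutoff, plurality concordance
#' for multiples) and greedy selection, removing linked records and consumed
#' episodes between passes. Records without a link after the final pass
#' remain unlinked.
#'
#' @param vitals Vital-record tibble.
#' @param episodes Maternal hospital-episode tibble (delivery admissions).
#' @param cfg A [linkage_config()].
#' @return List with `assignments` (record_id, episode_id, score, tiebreak,
#'   pass) and `pass_counts`.
#' @export
link_mothers <- function(vitals, episodes, cfg = linkage_config()) {
  with_rng(cfg$rng_seed, run_passes(vitals, episodes, cfg, "mother"))
}

#' Link birth records to the infant's birth-admission episode
#'
#' Episodes are first restricted to pregnancy/birth records
#' ([is_pregnancy_or_birth_record()]); fetal deaths are excluded from the
#' vital side since no infant record exists for them. The infant schedule
#' A..I includes repeat passes so twin and multiple deliveries can link
#' their duplicate episodes. Discordant infant sex is never accepted.
#'
#' @inheritParams link_mothers
#' @param episodes Infant hospital-episode tibble.
#' @export
link_infants <- function(vitals, episodes, cfg = linkage_config()) {
  episodes <- episodes[is_pregnancy_or_birth_record(episodes), , drop = FALSE]
  vitals <- vitals[!vitals$is_fetal_death, , drop = FALSE]
  with_rng(cfg$rng_seed + 1L, run_passes(vitals, episodes, cfg, "infant"))
}

#' Resolve twin and multiple-birth assignments
#'
#' Drops maternal links for twin/multiple vital records whose episode is not
#' also coded as a multiple gestation, and randomly reassigns infant
#' episodes among indistinguishable same-sex siblings (same sex, birthweight
#' band, delivery mode and survival), flagging them `twin_ambiguous`: for
#' such sets the data cannot say which record belongs to which infant.
#'
#' @param vitals Vital-record tibble.
#' @param mother_assign,infant_assign Assignment tibbles from
#'   [link_mothers()] / [link_infants()].
#' @param mother_episodes Maternal episode tibble (for plurality codes).
#' @param cfg A [linkage_config()].
#' @return List of the two adjusted assignment tibbles; infant assignments
#'   gain a `twin_ambiguous` column.
#' @export
resolve_multiples <- function(vitals, mother_assign, infant_assign,
                              mother_episodes, cfg = linkage_config()) {
  if (nrow(mother_assign) > 0L && cfg$require_plurality_concordance) {
    ind <- derive_indicators(mother_episodes, cfg$code_sets)
    vi <- match(mother_assign$record_id, vitals$record_id)
    ei <- match(mother_assign$episode_id, mother_episodes$episode_id)
    multi <- vitals$plurality[vi] %in% c("twin", "multiple")
    conc <- ind$plurality_band[ei] %in% c("twin", "multiple")
    mother_assign <- mother_assign[!multi | conc, , drop = FALSE]
  }

  infant_assign$twin_ambiguous <- rep(FALSE, nrow(infant_assign))
  if (nrow(infant_assign) > 0L) {
    vi <- match(infant_assign$record_id, vitals$record_id)
    key <- paste(
      vitals$sibling_set_id[vi], vitals$infant_sex[vi],
      vital_bw_band(vitals$birthweight_g[vi]),
      ifelse(is.na(vitals$cesarean[vi]), "na", vitals$cesarean[vi]),
      ifelse(is.na(vitals$infant_death[vi]), "na", vitals$infant_death[vi])
    )
    multi <- vitals$plurality[vi] %in% c("twin", "multiple")
    groups <- split(seq_len(nrow(infant_assign)), key)
    for (g in groups) {
      if (length(g) < 2L || !all(multi[g])) next
      perm <- sample.int(length(g))
      infant_assign$episode_id[g] <- infant_assign$episode_id[g][perm]
      infant_assign$score[g] <- infant_assign$score[g][perm]
      infant_assign$twin_ambiguous[g] <- TRUE
    }
  }
  list(mother = mother_assign, infant = infant_assign)
}

#' Run the full principal linkage
#'
#' Links the vital records to maternal and infant hospital episodes, applies
#' the multiple-birth resolution, and returns a `natalink_linkage` object
#' holding one assignment row per vital record (with pass label, score and
#' tie-break provenance per side), the per-pass counts, and the
#' configuration used. Deterministic given `cfg$rng_seed`.
#'
#' @param vitals Vital-record tibble.
#' @param mother_episodes,infant_episodes Hospital-episode tibbles.
#' @param cfg A [linkage_config()].
#' @return A `natalink_linkage` object.
#' @examples
#' sim <- simulate_cohort(simulation_config(n_deliveries = 50, rng_seed = 1))
#' res <- link_cohort(sim$vitals, sim$mother_episodes, sim$infant_episodes)
#' glance(res)
#' @export
link_cohort <- function(vitals, mother_episodes, infant_episodes,
                        cfg = linkage_config()) {
  m <- link_mothers(vitals, mother_episodes, cfg)
  i <- link_infants(vitals, infant_episodes, cfg)
  fixed <- with_rng(
    cfg$rng_seed + 2L,
    resolve_multiples(vitals, m$assignments, i$assignments, mother_episodes, cfg)
  )
  ma <- rename(
    fixed$mother,
    mother_episode_id = "episode_id", mother_score = "score",
    mother_tiebreak = "tiebreak", mother_pass = "pass"
  )
  ia <- rename(
    fixed$infant,
    infant_episode_id = "episode_id", infant_score = "score",
    infant_tiebreak = "tiebreak", infant_pass = "pass"
  )
  assignments <- full_join(ma, ia, by = "record_id")
  assignments <- assignments[, c(
    "record_id", "mother_episode_id", "mother_pass", "mother_score",
    "mother_tiebreak", "infant_episode_id", "infant_pass", "infant_score",
    "infant_tiebreak", "twin_ambiguous"
  )]
  assignments <- assignments[order(assignments$record_id), , drop = FALSE]
  structure(
    list(
      assignments = assignments,
      unlinked = list(
        mother = setdiff(vitals$record_id, ma$record_id),
        infant = setdiff(
          vitals$record_id[!vitals$is_fetal_death],
          ia$record_id
        )
      ),
      pass_counts = bind_rows(
        mutate(m$pass_counts, side = "mother"),
        mutate(i$pass_counts, side = "infant")
      ),
      n_vitals = nrow(vitals),
      config = cfg
    ),
    class = "natalink_linkage"
  )
}

#' @export
print.natalink_linkage <- function(x, ...) {
  cat("<natalink linkage: ", x$n_vitals, " vital records>\n", sep = "")
  cat(
    " mother links:", sum(!is.na(x$assignments$mother_episode_id)),
    "| infant links:", sum(!is.na(x$assignments$infant_episode_id)), "\n"
  )
  invisible(x)
}

#' Longitudinal linkage of additional episodes
#'
#' Attaches further hospital episodes (discharge, emergency department,
#' ambulatory surgery) to each linked person over time. Within the follow-up
#' window (birthing person: one year before through one year after
#' delivery; infant: birth through one year), an episode attaches when its
#' encrypted SSN matches the person's SSN from the birth admission *and* at
#' least one other variable (date of birth, zip, county, payer,
#' race/ethnicity) also matches — a matching SSN alone is never a match.
#' Episodes without an SSN attach on the variable evidence alone: exact date
#' of birth plus at least two of zip, county, payer and race/ethnicity.
#'
#' @param result A `natalink_linkage` from [link_cohort()].
#' @param vitals Vital-record tibble.
#' @param mother_episodes,infant_episodes Birth-admission episode tibbles
#'   (source of the anchor SSNs).
#' @param episodes Additional episode tibble to attach.
#' @param cfg A [linkage_config()].
#' @return Tibble: `person_id`, `record_id`, `role`, `episode_id`,
#'   `admit_date`, `basis` (`"ssn"` or `"variables"`), ordered by person and
#'   admission date.
#' @export
link_longitudinal <- function(result, vitals, mother_episodes, infant_episodes,
                              episodes, cfg = linkage_config()) {
  a <- result$assignments
  anchor <- function(ids, eps) eps[match(ids, eps$episode_id), , drop = FALSE]

  persons <- list()
  am <- a[!is.na(a$mother_episode_id), , drop = FALSE]
  if (nrow(am)) {
    vi <- match(am$record_id, vitals$record_id)
    ae <- anchor(am$mother_episode_id, mother_episodes)
    persons$mother <- tibble(
      person_id = paste0(am$record_id, ":mother"),
      record_id = am$record_id, role = "mother",
      dob = vitals$mother_dob[vi], zip = vitals$zip[vi],
      county = vitals$county[vi], payer = vitals$payer[vi],
      race_eth = vitals$race_eth[vi], enc_ssn = ae$enc_ssn,
      win_lo = vitals$infant_dob[vi] - 365L,
      win_hi = vitals$infant_dob[vi] + 365L
    )
  }
  ai <- a[!is.na(a$infant_episode_id), , drop = FALSE]
  if (nrow(ai)) {
    vi <- match(ai$record_id, vitals$record_id)
    ae <- anchor(ai$infant_episode_id, infant_episodes)
    persons$infant <- tibble(
      person_id = paste0(ai$record_id, ":infant"),
      record_id = ai$record_id, role = "infant",
      dob = vitals$infant_dob[vi], zip = vitals$zip[vi],
      county = vitals$county[vi], payer = vitals$payer[vi],
      race_eth = vitals$race_eth[vi], enc_ssn = ae$enc_ssn,
      win_lo = vitals$infant_dob[vi],
      win_hi = vitals$infant_dob[vi] + 365L
    )
  }
  persons <- bind_rows(persons)
  empty <- tibble(
    person_id = character(), record_id = character(), role = character(),
    episode_id = character(), admit_date = as.Date(character()),
    basis = character()
  )
  if (nrow(persons) == 0L || nrow(episodes) == 0L) {
    return(empty)
  }

  # candidate pairs: SSN equality, else DOB equality
  by_ssn <- inner_join(
    persons[!is.na(persons$enc_ssn), , drop = FALSE],
    tibble(episode_id = episodes$episode_id, enc_ssn = episodes$enc_ssn),
    by = "enc_ssn"
  )
  no_ssn_eps <- episodes[is.na(episodes$enc_ssn), , drop = FALSE]
  by_dob <- inner_join(
    persons,
    tibble(episode_id = no_ssn_eps$episode_id, dob = no_ssn_eps$patient_dob),
    by = "dob"
  )
  by_dob$basis <- "variables"
  by_ssn$basis <- "ssn"
  cand <- bind_rows(by_ssn, by_dob)
  if (nrow(cand) == 0L) {
    return(empty)
  }
  ei <- match(cand$episode_id, episodes$episode_id)
  in_window <- !is.na(episodes$admit_date[ei]) &
    episodes$admit_date[ei] >= cand$win_lo &
    episodes$admit_date[ei] <= cand$win_hi
  cand <- cand[in_window, , drop = FALSE]
  ei <- ei[in_window]
  if (nrow(cand) == 0L) {
    return(empty)
  }

  pi <- match(cand$person_id, persons$person_id)
  m_dob <- eq_known(persons$dob[pi], episodes$patient_dob[ei], unknown = NA)
  m_zip <- eq_known(persons$zip[pi], episodes$zip[ei], unknown = NA)
  m_cty <- eq_known(persons$county[pi], episodes$county[ei], unknown = NA)
  m_pay <- eq_known(persons$payer[pi], episodes$payer[ei])
  m_race <- eq_known(persons$race_eth[pi], episodes$race_eth[ei])
  n_extra <- m_dob + m_zip + m_cty + m_pay + m_race

  keep <- ifelse(cand$basis == "ssn",
    if (cfg$ssn_requires_extra_variable) n_extra >= 1L else TRUE,
    m_dob & (m_zip + m_cty + m_pay + m_race) >= 2L
  )
  cand <- cand[keep, , drop = FALSE]
  ei <- ei[keep]
  out <- tibble(
    person_id = cand$person_id, record_id = cand$record_id, role = cand$role,
    episode_id = cand$episode_id, admit_date = episodes$admit_date[ei],
    basis = cand$basis
  )
  out <- distinct(out)
  out[order(out$person_id, out$admit_date, out$episode_id), , drop = FALSE]
}
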