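# Independent oracle: a from-scratch reimplementation of the scoring
# arithmetic, brute-force all-pairs candidate filtering, and the selection
# loop, written in plain base R against the published point values. Used to
# cross-check the engine; shares no code with the package's scoring or
# blocking path (indicator derivation from ICD codes is exercised by its own
# exhaustive tests and reused here as an input).

oracle_date_level <- function(a, b) {
  if (is.na(a) || is.na(b)) return("none")
  if (a == b) return("exact")
  ya <- as.integer(format(a, "%Y")); ma <- as.integer(format(a, "%m"))
  da <- as.integer(format(a, "%d"))
  yb <- as.integer(format(b, "%Y")); mb <- as.integer(format(b, "%m"))
  db <- as.integer(format(b, "%d"))
  if (ya == yb && ma == db && da == mb && ma != da) return("transposed")
  if (ma == mb && da == db && ya != yb) return("year_differs")
  "none"
}

oracle_minority <- c(
  "amer_indian_alaska_native", "asian", "black", "hawaiian_pacific_islander",
  "hispanic", "other", "multiple"
)

oracle_ga_band <- function(wk) {
  if (is.na(wk)) "unknown"
  else if (wk < 29) "lt29"
  else if (wk < 37) "29to36"
  else if (wk <= 42) "37to42"
  else "gt42"
}

oracle_bw_band <- function(g) {
  if (is.na(g)) "unknown"
  else if (g < 2500) "lt2500"
  else if (g < 4500) "2500to4499"
  else "ge4500"
}

# score one pair by direct hand-written sums of the published point values
oracle_score1 <- function(v, e, ind, side) {
  pts <- 0L
  other <- FALSE
  eq <- function(a, b, no_unknown = FALSE) {
    if (is.na(a) || is.na(b)) return(FALSE)
    if (no_unknown && (a == "unknown" || b == "unknown")) return(FALSE)
    a == b
  }

  mdl <- "none"
  if (side == "mother") {
    mdl <- oracle_date_level(v$mother_dob, e$patient_dob)
    if (mdl == "exact") pts <- pts + 10L
    if (mdl == "transposed") pts <- pts + 5L
    idl_ok <- !is.na(v$infant_dob) && !is.na(e$admit_date) &&
      !is.na(e$discharge_date) &&
      v$infant_dob >= e$admit_date && v$infant_dob <= e$discharge_date
    if (idl_ok) pts <- pts + 10L
  } else {
    il <- oracle_date_level(v$infant_dob, e$patient_dob)
    idl_ok <- il == "exact"
    if (il == "exact") pts <- pts + 10L
    if (il == "transposed") pts <- pts + 5L
  }
  hosp <- eq(v$hospital_id, e$hospital_id)
  if (hosp) pts <- pts + 10L

  if (eq(v$zip, e$zip)) { pts <- pts + 5L; other <- TRUE }
  vga <- oracle_ga_band(v$gestational_age_wk)
  if (vga != "unknown" && vga == ind$ga_band) {
    p <- c(lt29 = 20L, "29to36" = 10L, "37to42" = 2L, gt42 = 10L)[[vga]]
    pts <- pts + p; other <- TRUE
  }
  sex_ok <- eq(v$infant_sex, e$sex, no_unknown = TRUE)
  if (sex_ok) { pts <- pts + 2L; other <- TRUE }
  if (eq(v$payer, e$payer, no_unknown = TRUE)) { pts <- pts + 5L; other <- TRUE }
  if (eq(v$race_eth, e$race_eth, no_unknown = TRUE)) {
    pts <- pts + 5L
    if (v$race_eth %in% oracle_minority) pts <- pts + 5L
    if (v$race_eth == "white_nh") pts <- pts + 2L
    other <- TRUE
  }
  if (!is.na(v$race_eth) && !is.na(e$race_eth) &&
    v$race_eth != "unknown" && e$race_eth != "unknown" &&
    (v$race_eth == "hispanic") == (e$race_eth == "hispanic")) {
    pts <- pts + 2L; other <- TRUE
  }
  if (eq(v$county, e$county)) { pts <- pts + 2L; other <- TRUE }
  if (isTRUE(v$infant_death) && ind$infant_died) { pts <- pts + 10L; other <- TRUE }
  if (isTRUE(v$cesarean) && ind$cesarean) { pts <- pts + 5L; other <- TRUE }
  if (isTRUE(v$previous_cesarean) && ind$previous_cesarean) {
    pts <- pts + 10L; other <- TRUE
  }
  vbw <- oracle_bw_band(v$birthweight_g)
  if (vbw != "unknown" && vbw == ind$birthweight_band) {
    p <- c(lt2500 = 10L, "2500to4499" = 2L, ge4500 = 10L)[[vbw]]
    pts <- pts + p; other <- TRUE
  }
  if (isTRUE(v$sga_lga) && ind$sga_lga) { pts <- pts + 7L; other <- TRUE }
  v_htn <- isTRUE(v$prepregnancy_hypertension) ||
    isTRUE(v$gestational_hypertension) || isTRUE(v$eclampsia)
  if (v_htn && ind$hypertension_preg) { pts <- pts + 10L; other <- TRUE }
  v_dia <- isTRUE(v$gestational_diabetes) || isTRUE(v$preexisting_diabetes)
  if (v_dia && ind$diabetes_any) { pts <- pts + 10L; other <- TRUE }
  if (!is.na(v$plurality) && v$plurality == ind$plurality_band) {
    pts <- pts + if (v$plurality == "singleton") 2L else 10L
    other <- TRUE
  }

  list(
    total = pts,
    eligible = side == "infant" ||
      (mdl %in% c("exact", "transposed", "year_differs") && idl_ok && hosp && other),
    sex_ok = sex_ok,
    plu_both = !is.na(v$plurality) && v$plurality %in% c("twin", "multiple") &&
      ind$plurality_band %in% c("twin", "multiple")
  )
}

# brute-force candidate filter: every pair, tested against the pass keys
oracle_candidates <- function(vitals, episodes, keys, side, ind) {
  nv <- nrow(vitals)
  ne <- nrow(episodes)
  if (nv == 0 || ne == 0) {
    return(data.frame(vi = integer(), ei = integer()))
  }
  ok <- matrix(TRUE, nv, ne)
  agree <- function(va, eb) {
    m <- outer(va, eb, "==")
    m[is.na(m)] <- FALSE
    m
  }
  for (k in keys) {
    ok <- ok & switch(k,
      mother_dob = agree(vitals$mother_dob, episodes$patient_dob),
      infant_dob = if (side == "mother") {
        m1 <- outer(as.integer(vitals$infant_dob), as.integer(episodes$admit_date), ">=")
        m2 <- outer(as.integer(vitals$infant_dob), as.integer(episodes$discharge_date), "<=")
        m1[is.na(m1)] <- FALSE; m2[is.na(m2)] <- FALSE
        m1 & m2
      } else {
        agree(vitals$infant_dob, episodes$patient_dob)
      },
      zip = agree(vitals$zip, episodes$zip),
      hospital = agree(vitals$hospital_id, episodes$hospital_id),
      sex = agree(vitals$infant_sex, episodes$sex),
      payer = agree(vitals$payer, episodes$payer),
      preterm = {
        vp <- !is.na(vitals$gestational_age_wk) & vitals$gestational_age_wk < 37
        ep <- ind$ga_band %in% c("lt29", "29to36")
        outer(vp, ep, "&")
      }
    )
  }
  idx <- which(ok, arr.ind = TRUE)
  data.frame(vi = idx[, 1], ei = idx[, 2])
}

# selection: canonical sort, one tie-break key per row, re-sort, scan
oracle_select <- function(acc, share_by = NULL, consumed = list()) {
  taken <- data.frame(
    record_id = character(), episode_id = character(),
    score = integer(), tiebreak = logical()
  )
  if (nrow(acc) == 0) {
    return(list(assign = taken, consumed = consumed))
  }
  acc <- acc[order(-acc$total, acc$record_id, acc$episode_id), , drop = FALSE]
  acc$u <- runif(nrow(acc))
  acc <- acc[order(-acc$total, acc$record_id, acc$u), , drop = FALSE]
  assigned <- character()
  avail <- function(i, rset) {
    own <- consumed[[acc$episode_id[i]]]
    is.null(own) || (!is.null(share_by) && nzchar(rset) && identical(own, rset))
  }
  i <- 1
  while (i <= nrow(acc)) {
    r <- acc$record_id[i]
    rset <- if (is.null(share_by)) "" else share_by[[r]]
    if (r %in% assigned || !avail(i, rset)) {
      i <- i + 1
      next
    }
    grp <- which(acc$record_id == r & acc$total == acc$total[i])
    n_avail <- sum(vapply(grp, avail, TRUE, rset = rset))
    taken <- rbind(taken, data.frame(
      record_id = r, episode_id = acc$episode_id[i],
      score = acc$total[i], tiebreak = n_avail > 1
    ))
    assigned <- c(assigned, r)
    consumed[[acc$episode_id[i]]] <- rset
    i <- i + 1
  }
  list(assign = taken, consumed = consumed)
}

oracle_passes_def <- function(side) {
  if (side == "mother") {
    list(
      list(keys = c("mother_dob", "hospital")),
      list(keys = c("infant_dob", "zip")),
      list(keys = c("infant_dob", "hospital")),
      list(keys = c("mother_dob", "zip")),
      list(keys = c("zip", "hospital")),
      list(keys = c("preterm", "infant_dob"))
    )
  } else {
    list(
      list(keys = c("hospital", "infant_dob")),
      list(keys = c("hospital", "infant_dob")),
      list(keys = c("hospital", "infant_dob")),
      list(keys = c("hospital", "infant_dob")),
      list(keys = c("infant_dob", "zip")),
      list(keys = c("infant_dob", "zip")),
      list(keys = c("zip", "sex")),
      list(keys = c("zip", "payer")),
      list(keys = c("zip", "hospital"))
    )
  }
}

# full multi-pass oracle for one side (RNG state must match the engine's:
# callers wrap in the same seed the engine uses for that side)
oracle_side <- function(vitals, episodes, side, mother_cutoff = 40L,
                        infant_cutoff = 31L) {
  if (side == "infant") {
    episodes <- episodes[is_pregnancy_or_birth_record(episodes), , drop = FALSE]
    vitals <- vitals[!vitals$is_fetal_death, , drop = FALSE]
  }
  ind <- derive_indicators(episodes)
  share_by <- NULL
  if (side == "mother") {
    share_by <- as.list(setNames(vitals$sibling_set_id, vitals$record_id))
  }
  consumed <- list()
  linked <- character()
  out <- NULL
  for (p in oracle_passes_def(side)) {
    rem <- vitals[!(vitals$record_id %in% linked), , drop = FALSE]
    if (nrow(rem) == 0) next
    cand <- oracle_candidates(rem, episodes, p$keys, side, ind)
    if (nrow(cand) > 0) {
      keep <- vapply(seq_len(nrow(cand)), function(j) {
        own <- consumed[[episodes$episode_id[cand$ei[j]]]]
        is.null(own) ||
          (side == "mother" && identical(own, share_by[[rem$record_id[cand$vi[j]]]]))
      }, TRUE)
      cand <- cand[keep, , drop = FALSE]
    }
    if (nrow(cand) == 0) next
    acc_rows <- lapply(seq_len(nrow(cand)), function(j) {
      v <- rem[cand$vi[j], ]
      e <- episodes[cand$ei[j], ]
      s <- oracle_score1(v, e, ind[cand$ei[j], ], side)
      accept <- if (side == "mother") {
        multi <- v$plurality %in% c("twin", "multiple")
        s$eligible && s$total >= mother_cutoff && (!multi || s$plu_both)
      } else {
        s$sex_ok && s$total >= infant_cutoff
      }
      if (accept) {
        data.frame(
          record_id = v$record_id, episode_id = e$episode_id, total = s$total
        )
      } else {
        NULL
      }
    })
    acc <- do.call(rbind, acc_rows)
    if (is.null(acc) || nrow(acc) == 0) next
    sel <- oracle_select(acc, share_by, consumed)
    consumed <- sel$consumed
    if (nrow(sel$assign) > 0) {
      out <- rbind(out, sel$assign)
      linked <- c(linked, sel$assign$record_id)
    }
  }
  if (is.null(out)) {
    out <- data.frame(
      record_id = character(), episode_id = character(),
      score = integer(), tiebreak = logical()
    )
  }
  out[order(out$record_id), , drop = FALSE]
}
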