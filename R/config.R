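# Structured configuration files, the end-to-end pipeline, and run
# manifests tying seeds and configs to output digests.

LINKAGE_KEYS <- c(
  "kind", "mother_cutoff", "infant_cutoff", "rng_seed",
  "require_plurality_concordance", "ssn_requires_extra_variable",
  "maternal_passes", "infant_passes", "spec"
)
SIMULATION_KEYS <- c(
  "kind", "n_deliveries", "year_range", "twin_rate", "higher_multiple_rate",
  "fetal_death_rate", "ga_band_probs", "infant_death_probs",
  "p_mother_unlinked", "p_infant_unlinked", "p_dob_transposed",
  "p_field_missing", "p_zip_error", "enc_ssn_mother", "enc_ssn_infant",
  "n_hospitals", "n_zips", "rng_seed"
)

parse_passes <- function(blocks) {
  purrr::map(blocks, function(b) {
    blocking_pass(b$label, unlist(b$keys), isTRUE(b$dedup_repeat))
  })
}

#' Load and validate a configuration file
#'
#' Reads a YAML config and returns a validated [linkage_config()] or
#' [simulation_config()]. The kind is taken from the `kind:` key
#' (`"linkage"` or `"simulation"`) or inferred from the presence of
#' `n_deliveries`. Omitted keys take the packaged defaults (cutoffs 40/31,
#' packaged pass schedules and point table). Unknown keys and out-of-range
#' values are reported together in one error.
#'
#' @param path YAML file path.
#' @param kind Optional explicit kind, overriding detection.
#' @return A validated config object.
#' @export
load_config <- function(path, kind = NULL) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  kind <- kind %||% raw$kind %||%
    if (any(names(raw) %in% setdiff(SIMULATION_KEYS, c("kind", "rng_seed")))) {
      "simulation"
    } else {
      "linkage"
    }
  keys <- if (kind == "simulation") SIMULATION_KEYS else LINKAGE_KEYS
  unknown <- setdiff(names(raw), keys)
  if (length(unknown)) {
    abort(paste0(
      "unknown config keys for kind '", kind, "': ", toString(unknown)
    ))
  }
  raw$kind <- NULL
  if (kind == "simulation") {
    if (!is.null(raw$ga_band_probs)) raw$ga_band_probs <- unlist(raw$ga_band_probs)
    if (!is.null(raw$infant_death_probs)) {
      raw$infant_death_probs <- unlist(raw$infant_death_probs)
    }
    if (!is.null(raw$year_range)) raw$year_range <- unlist(raw$year_range)
    do.call(simulation_config, raw)
  } else {
    if (!is.null(raw$maternal_passes)) raw$maternal_passes <- parse_passes(raw$maternal_passes)
    if (!is.null(raw$infant_passes)) raw$infant_passes <- parse_passes(raw$infant_passes)
    if (!is.null(raw$spec)) raw$spec <- do.call(comparator_spec, raw$spec)
    do.call(linkage_config, raw)
  }
}

#' Write a configuration back to YAML
#'
#' Round-trips through [load_config()]: `load_config(dump_config(cfg, p))`
#' reproduces `cfg`.
#'
#' @param cfg A linkage or simulation config.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  if (inherits(cfg, "natalink_simulation_config")) {
    out <- unclass(cfg)
    out$comorbidities <- NULL
    out$ga_band_probs <- as.list(out$ga_band_probs)
    out$infant_death_probs <- as.list(out$infant_death_probs)
    out$kind <- "simulation"
  } else {
    out <- list(
      kind = "linkage",
      mother_cutoff = cfg$mother_cutoff,
      infant_cutoff = cfg$infant_cutoff,
      rng_seed = cfg$rng_seed,
      require_plurality_concordance = cfg$require_plurality_concordance,
      ssn_requires_extra_variable = cfg$ssn_requires_extra_variable,
      maternal_passes = purrr::map(cfg$maternal_passes, unclass),
      infant_passes = purrr::map(cfg$infant_passes, unclass)
    )
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the simulate-link-evaluate pipeline
#'
#' Simulates a cohort, writes its files, runs the principal linkage, writes
#' the linked cohort with a per-pass report, computes the evaluation
#' metrics, and writes a run manifest with md5 digests of every output.
#' End-to-end deterministic under `seed` (the manifest timestamp aside).
#' Stage failures abort with the failing stage named.
#'
#' @param sim_cfg A [simulation_config()].
#' @param link_cfg A [linkage_config()].
#' @param outdir Output directory (created if needed).
#' @param seed Optional integer overriding both configs' seeds.
#' @return Invisibly, a list with `manifest`, `cohort`, `result`, `metrics`.
#' @export
run_pipeline <- function(sim_cfg = simulation_config(),
                         link_cfg = linkage_config(),
                         outdir, seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  if (!is.null(seed)) {
    sim_cfg$rng_seed <- as.integer(seed)
    link_cfg$rng_seed <- as.integer(seed)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)

  sim <- stage("simulate", {
    s <- simulate_cohort(sim_cfg)
    write_vital_file(s$vitals, p("vitals.csv"))
    write_hospital_file(s$mother_episodes, p("mother_episodes.csv"))
    write_hospital_file(s$infant_episodes, p("infant_episodes.csv"))
    readr::write_csv(s$truth, p("truth.csv"), na = "")
    s
  })
  result <- stage("link", {
    r <- link_cohort(sim$vitals, sim$mother_episodes, sim$infant_episodes, link_cfg)
    write_linked_cohort(r, sim$vitals, p("linked.csv"))
    jsonlite::write_json(
      list(pass_counts = r$pass_counts, n_vitals = r$n_vitals),
      p("report.json"),
      dataframe = "rows", auto_unbox = TRUE, pretty = TRUE
    )
    r
  })
  metrics <- stage("evaluate", {
    m <- linkage_rates(result, sim$vitals, truth = sim$truth)
    asc <- ascertainment_union(result, sim$vitals, sim$mother_episodes, sim$infant_episodes)
    prev <- prevalence_contrast(result, sim$vitals)
    jsonlite::write_json(
      list(
        overall = m$overall, fetal_deaths = m$fetal_deaths,
        strata = m$strata, truth = m$truth,
        ascertainment = asc, prevalence_contrast = prev
      ),
      p("metrics.json"),
      dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
    )
    m
  })

  cfg_path_sim <- dump_config(sim_cfg, p("sim_config.yaml"))
  cfg_path_link <- dump_config(link_cfg, p("link_config.yaml"))
  outputs <- c(
    "vitals.csv", "mother_episodes.csv", "infant_episodes.csv", "truth.csv",
    "linked.csv", "report.json", "metrics.json"
  )
  manifest <- list(
    command = "run",
    tool = "natalink",
    tool_version = as.character(utils::packageVersion("natalink")),
    seed = link_cfg$rng_seed,
    config_digests = as.list(tools::md5sum(c(
      sim_config = p("sim_config.yaml"), link_config = p("link_config.yaml")
    ))),
    output_digests = as.list(tools::md5sum(setNames(
      file.path(outdir, outputs), outputs
    ))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  names(manifest$config_digests) <- c("sim_config.yaml", "link_config.yaml")
  names(manifest$output_digests) <- outputs
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, cohort = sim, result = result, metrics = metrics))
}

#' Format a tibble as a Markdown table
#'
#' Small helper behind the report command; numeric cells are printed as-is,
#' NAs as em-dashes.
#'
#' @param df A data frame.
#' @return A single Markdown string.
#' @export
format_table_md <- function(df) {
  cells <- purrr::map(df, function(col) {
    out <- as.character(col)
    out[is.na(col)] <- "—"
    out
  })
  m <- do.call(cbind, cells)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(m, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}
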