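trial_log_schema <- c(
  participant_id = "c", level = "i", block = "i", trial = "i",
  stim1 = "c", stim2 = "c", stim3 = "c", rule_dim = "c", rule_feature = "c",
  shift = "l", shift_type = "c", choice = "i", outcome = "i",
  confidence = "i", rt = "d"
)

#' Write / read trial logs
#'
#' Trial logs are stored as delimited text (comma by default, tab for
#' `.tsv` paths) with an explicit header; columns may appear in any order in
#' a file, they are matched by name. `read_trials()` validates the schema
#' and reports offending rows: every required column must be present,
#' `outcome` must be 0/1, `choice` at least 1, and confidence (where
#' recorded) inside 1-100.
#'
#' @param trials Trial-log tibble (see [run_level()]).
#' @param path File path (`.csv` or `.tsv`).
#' @return `write_trials()` returns `path` invisibly; `read_trials()` a
#'   typed trial-log tibble.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(names(trial_log_schema), names(trials))
  if (length(missing)) {
    abort(paste0("Trial log is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(trials[names(trial_log_schema)], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           show_col_types = FALSE)
  missing <- setdiff(names(trial_log_schema), names(raw))
  if (length(missing)) {
    abort(paste0("Trial log is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- raw[names(trial_log_schema)]
  out$participant_id <- as.character(out$participant_id)
  for (col in c("level", "block", "trial", "choice", "outcome", "confidence")) {
    out[[col]] <- as.integer(out[[col]])
  }
  out$shift <- as.logical(out$shift)
  out$rt <- as.numeric(out$rt)

  bad_conf <- which(!is.na(out$confidence) &
                      (out$confidence < 1L | out$confidence > 100L))
  if (length(bad_conf)) {
    abort(sprintf("Confidence outside [1, 100] at row(s): %s",
                  paste(head(bad_conf, 5L), collapse = ", ")))
  }
  bad_out <- which(!out$outcome %in% c(0L, 1L))
  if (length(bad_out)) {
    abort(sprintf("Outcome not 0/1 at row(s): %s",
                  paste(head(bad_out, 5L), collapse = ", ")))
  }
  bad_choice <- which(is.na(out$choice) | out$choice < 1L)
  if (length(bad_choice)) {
    abort(sprintf("Invalid stimulus choice at row(s): %s",
                  paste(head(bad_choice, 5L), collapse = ", ")))
  }
  as_tibble(out)
}

#' Write / read a demographics table
#'
#' Columns: `participant_id`, `group` ("OCD"/"control"), `age`, `gender`
#' (numeric code: 1 = female, 2 = male, 0 = non-binary/other; modelled as an
#' unordered factor, the numeric code is an I/O convention only), `iq`.
#'
#' @param demographics Demographics tibble.
#' @param path File path.
#' @export
write_demographics <- function(demographics, path) {
  readr::write_csv(demographics, path)
  invisible(path)
}

#' @rdname write_demographics
#' @export
read_demographics <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols())
  needed <- c("participant_id", "group", "age", "gender", "iq")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    abort(paste0("Demographics table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  d$participant_id <- as.character(d$participant_id)
  d$gender <- as.integer(d$gender)
  as_tibble(d[union(needed, names(d))])
}

#' Write / read a full cohort as delimited text
#'
#' Writes `trials.csv`, `demographics.csv` and (if present)
#' `agent_params.csv` into `dir`.
#'
#' @param cohort An `rs_cohort`.
#' @param dir Directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(cohort$trials, file.path(dir, "trials.csv"))
  write_demographics(cohort$demographics, file.path(dir, "demographics.csv"))
  if (!is.null(cohort$agent_params)) {
    readr::write_csv(cohort$agent_params, file.path(dir, "agent_params.csv"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pp <- file.path(dir, "agent_params.csv")
  as_cohort(
    trials = read_trials(file.path(dir, "trials.csv")),
    demographics = read_demographics(file.path(dir, "demographics.csv")),
    agent_params = if (file.exists(pp)) {
      readr::read_csv(pp, show_col_types = FALSE)
    }
  )
}

#' Write fitted model results and a run manifest
#'
#' Serialises each [`rs_model`][print.rs_model] (formula, family,
#' coefficient table, BIC, convergence/singularity flags, VIF table) into a
#' single structured JSON file, together with a manifest recording the seed
#' and a hash of the configuration. Identical inputs produce identical
#' files.
#'
#' @param results Named list of `rs_model` objects (may be empty).
#' @param path Output file path (JSON).
#' @param seed Seed to record in the manifest.
#' @param config Configuration object to hash into the manifest.
#' @return The manifest, invisibly.
#' @export
write_results <- function(results, path, seed = NULL, config = NULL) {
  records <- purrr::map(results, function(m) {
    list(
      formula = m$formula, family = m$family,
      coefficients = m$coefficients, bic = m$bic,
      converged = m$converged, singular = m$singular,
      simplified = m$simplified, vif = m$vif, n_obs = m$n_obs
    )
  })
  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(config),
    n_models = length(results),
    models = names(results) %||% character(0)
  )
  jsonlite::write_json(list(manifest = manifest, results = records), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Run configuration: round-trip to YAML
#'
#' The configuration bundles the task design (levels with their dimensions
#' and shift-gap bounds), the cohort presets, and the pipeline toggles into
#' a single human-readable file.
#'
#' @param config A run-configuration list (see [default_run_config()]).
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  cfg <- config
  cfg$levels <- lapply(cfg$levels, function(l) {
    list(level_id = l$level_id, n_stimuli = l$n_stimuli,
         dimensions = l$dimensions, n_blocks = l$n_blocks,
         trials_per_block = l$trials_per_block,
         shift_gap_min = l$shift_gap_min, shift_gap_max = l$shift_gap_max)
  })
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$levels <- lapply(cfg$levels, function(l) {
    level_spec(l$level_id, l$n_stimuli, l$dimensions, l$n_blocks,
               l$trials_per_block, l$shift_gap_min, l$shift_gap_max)
  })
  cfg
}

#' @rdname write_run_config
#' @export
default_run_config <- function() {
  list(
    levels = make_default_levels(),
    seed = 1L,
    cohort = list(delta_b = -12, delta_w = 3, n_per_group = 29L),
    exclusion_mode = "weighted",
    model_spec = "joint",
    gc_variant = "proportion"
  )
}
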