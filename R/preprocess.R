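#' Chance accuracy of a level and the cohort-level exclusion threshold
#'
#' @param levels List of [level_spec()]s.
#' @return Trial-weighted chance accuracy across levels (a random policy's
#'   expected accuracy): with the default design,
#'   (60 x 1/2 + 70 x 1/2 + 70 x 1/3) / 200.
#' @export
chance_accuracy <- function(levels = make_default_levels()) {
  nt <- vapply(levels, n_trials, 0L)
  sum(nt / vapply(levels, function(l) l$n_stimuli, 0L)) / sum(nt)
}

#' Apply participant-level exclusion criteria
#'
#' Excludes participants whose overall accuracy is at or below chance
#' (`mode = "weighted"`: the trial-weighted chance level across levels;
#' `mode = "per_level"`: at or below chance at every level) and participants
#' whose modal confidence rating accounts for more than `conf_identical_max`
#' of trials (insufficient use of the confidence scale).
#'
#' @param cohort An `rs_cohort` (or list with `trials` and `demographics`).
#' @param mode Chance-threshold mode, `"weighted"` or `"per_level"`.
#' @param conf_identical_max Maximal tolerated fraction of identical
#'   confidence ratings (default 0.9).
#' @return A list with `cohort` (filtered) and `report` (one row per
#'   participant: accuracy, chance threshold, flags and exclusion reason).
#' @export
apply_exclusions <- function(cohort, mode = c("weighted", "per_level"),
                             conf_identical_max = 0.9) {
  mode <- match.arg(mode)
  trials <- cohort$trials
  if (is.null(trials) || nrow(trials) == 0L) abort("Empty cohort.")

  chance_by_level <- trials |>
    dplyr::distinct(.data$level, .data$stim1, .data$stim2, .data$stim3) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      n_stimuli = max(2L + !is.na(.data$stim3)), .groups = "drop"
    )

  per_level <- trials |>
    dplyr::left_join(chance_by_level, by = "level") |>
    dplyr::group_by(.data$participant_id, .data$level) |>
    dplyr::summarise(
      acc = mean(.data$outcome), n = dplyr::n(),
      chance = 1 / .data$n_stimuli[1L], .groups = "drop"
    )

  acc_tab <- per_level |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      accuracy = sum(.data$acc * .data$n) / sum(.data$n),
      chance_threshold = sum(.data$chance * .data$n) / sum(.data$n),
      at_chance_all_levels = all(.data$acc <= .data$chance),
      .groups = "drop"
    )

  conf_tab <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      modal_conf_frac = max(table(.data$confidence)) / dplyr::n(),
      .groups = "drop"
    )

  report <- acc_tab |>
    dplyr::left_join(conf_tab, by = "participant_id") |>
    dplyr::mutate(
      chance_excluded = if (mode == "weighted") {
        .data$accuracy <= .data$chance_threshold
      } else {
        .data$at_chance_all_levels
      },
      confidence_excluded = .data$modal_conf_frac > conf_identical_max,
      excluded = .data$chance_excluded | .data$confidence_excluded,
      reason = dplyr::case_when(
        chance_excluded ~ "chance performance",
        confidence_excluded ~ "constant confidence",
        .default = NA_character_
      )
    )

  keep <- report$participant_id[!report$excluded]
  out <- as_cohort(
    trials = dplyr::filter(trials, .data$participant_id %in% keep),
    demographics = dplyr::filter(cohort$demographics,
                                 .data$participant_id %in% keep),
    agent_params = if (!is.null(cohort$agent_params)) {
      dplyr::filter(cohort$agent_params, .data$participant_id %in% keep)
    }
  )
  list(cohort = out, report = report)
}

#' Remove slow-outlier trials by log-RT
#'
#' Per participant and level, reaction times are log-transformed and trials
#' whose log-RT deviates from the mean by more than `n_sd` standard
#' deviations are removed. The first trial of each block is excluded both
#' from the threshold computation and from removal (it is never filtered).
#' A within-cell SD of 0 removes nothing.
#'
#' @param trials Trial-log tibble with a positive `rt` column.
#' @param n_sd Threshold in SD units (default 3).
#' @return List with `trials` (kept rows, flag column `rt_outlier` all
#'   `FALSE`), `removed` (dropped rows) and `fraction_removed`.
#' @export
rt_outlier_filter <- function(trials, n_sd = 3) {
  if (!"rt" %in% names(trials) || all(is.na(trials$rt))) {
    abort("`trials` must contain a non-missing `rt` column.")
  }
  if (any(trials$rt <= 0, na.rm = TRUE)) abort("Reaction times must be positive.")
  flagged <- trials |>
    dplyr::group_by(.data$participant_id, .data$level) |>
    dplyr::mutate(
      first_of_block = !duplicated(.data$block),
      log_rt = log(.data$rt),
      m = mean(.data$log_rt[!.data$first_of_block]),
      s = sd(.data$log_rt[!.data$first_of_block]),
      rt_outlier = !.data$first_of_block & !is.na(.data$s) & .data$s > 0 &
        abs(.data$log_rt - .data$m) > n_sd * .data$s
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"log_rt", -"m", -"s", -"first_of_block")
  kept <- dplyr::filter(flagged, !.data$rt_outlier)
  removed <- dplyr::filter(flagged, .data$rt_outlier)
  list(trials = kept, removed = removed,
       fraction_removed = nrow(removed) / nrow(trials))
}

#' Annotate trials with their distance from the covert rule shifts
#'
#' Distance is counted relative to the first trial governed by a new rule:
#' that trial has distance +1 ("trial 1"), its successors +2, +3, ...;
#' trials before a shift count backwards from it (-1 = last trial under the
#' old rule). There is no distance 0. `post_distance`/`post_shift_type`
#' describe the most recent shift within the level (NA before the first
#' shift); `pre_distance` the upcoming one (NA after the last). Windows never
#' cross level boundaries.
#'
#' @param trials Trial-log tibble with `shift`/`shift_type` columns.
#' @return The tibble with `post_distance`, `post_shift_type` and
#'   `pre_distance` columns appended.
#' @export
annotate_shift_distance <- function(trials) {
  # distances use the recorded trial indices, so the annotation stays valid
  # on logs with filtered-out trials
  out <- trials |>
    dplyr::arrange(.data$participant_id, .data$level, .data$trial) |>
    dplyr::group_by(.data$participant_id, .data$level) |>
    dplyr::mutate(.shift_ord = cumsum(.data$shift)) |>
    dplyr::ungroup()
  shifts <- out |>
    dplyr::filter(.data$shift) |>
    dplyr::group_by(.data$participant_id, .data$level) |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "level", ".ord",
                  .s_trial = "trial", .s_type = "shift_type")
  nxt <- dplyr::mutate(shifts, .ord = .data$.ord - 1L, .s_type = NULL,
                       .n_trial = .data$.s_trial, .s_trial = NULL)
  out |>
    dplyr::left_join(shifts,
                     by = c("participant_id", "level", ".shift_ord" = ".ord")) |>
    dplyr::left_join(nxt,
                     by = c("participant_id", "level", ".shift_ord" = ".ord")) |>
    dplyr::mutate(
      post_distance = .data$trial - .data$.s_trial + 1L,
      post_shift_type = .data$.s_type,
      pre_distance = .data$trial - .data$.n_trial
    ) |>
    dplyr::select(-".shift_ord", -".s_trial", -".s_type", -".n_trial")
}

#' Shift-aligned group summary of a behavioural metric
#'
#' For every shift event, trials from `window` before to `window` after the
#' shift (distances -window..-1, +1..+window; the shift trial itself is +1)
#' are collected, averaged within participant per shift type and distance,
#' then summarised as group mean and standard error.
#'
#' @param cohort An `rs_cohort`.
#' @param metric `"accuracy"` or `"confidence"`.
#' @param window Half-width of the window in trials (default 5).
#' @return A tibble of class `rs_shift_aligned`: `group`, `shift_type`,
#'   `distance`, `mean`, `se`, `n`.
#' @export
shift_aligned_summary <- function(cohort, metric = c("accuracy", "confidence"),
                                  window = 5L) {
  metric <- match.arg(metric)
  trials <- cohort$trials
  value <- if (metric == "accuracy") trials$outcome else trials$confidence
  trials$.value <- as.numeric(value)

  events <- trials |>
    dplyr::filter(.data$shift) |>
    dplyr::select("participant_id", "level", shift_trial = "trial",
                  ev_type = "shift_type")

  aligned <- events |>
    dplyr::cross_join(tibble(distance = c(-(window:1), 1:window))) |>
    dplyr::mutate(trial = .data$shift_trial + .data$distance -
                    (.data$distance > 0)) |>
    dplyr::inner_join(
      dplyr::select(trials, "participant_id", "level", "trial", ".value"),
      by = c("participant_id", "level", "trial")
    )

  per_participant <- aligned |>
    dplyr::group_by(.data$participant_id, .data$ev_type, .data$distance) |>
    dplyr::summarise(value = mean(.data$.value), .groups = "drop")

  per_participant |>
    dplyr::left_join(
      dplyr::select(cohort$demographics, "participant_id", "group"),
      by = "participant_id"
    ) |>
    dplyr::group_by(.data$group, shift_type = .data$ev_type, .data$distance) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$group, .data$shift_type, .data$distance) |>
    structure(class = c("rs_shift_aligned", "tbl_df", "tbl", "data.frame"),
              metric = metric)
}
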