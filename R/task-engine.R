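#' Sample a covert rule-shift schedule for one level
#'
#' Gaps between consecutive shifts are i.i.d. uniform on
#' `shift_gap_min:shift_gap_max` (default 6-11 trials), independent of
#' performance. The first shift is placed one full gap after the level start,
#' so trial 0 never carries a shift; block boundaries do not reset the gap
#' counter. Each shift is intra-dimensional (ID, same dimension, new rewarded
#' feature) or extra-dimensional (ED, new dimension) with probability 1/2,
#' re-drawn until every block containing at least two shifts contains both
#' types.
#'
#' A shift's `trial` is the first (0-based) trial governed by the new rule.
#'
#' @param level An [level_spec()] object.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A tibble with one row per shift: `trial`, `shift_type` ("ID"/"ED"),
#'   `old_dim`, `old_feature`, `new_dim`, `new_feature`. The rule in force
#'   from trial 0 is attached as attribute `"initial_rule"`
#'   (list of `dimension`, `feature`).
#' @export
sample_shift_schedule <- function(level, seed = NULL) {
  validate_level(level)
  with_seed_if(seed, {
    nt <- n_trials(level)
    gaps <- integer(0)
    pos <- integer(0)
    cum <- 0L
    repeat {
      g <- sample(level$shift_gap_min:level$shift_gap_max, 1L)
      cum <- cum + g
      if (cum >= nt) break
      pos <- c(pos, cum)
    }
    n_shift <- length(pos)
    types <- sample_shift_types(pos, n_shift, level)

    dims <- names(level$dimensions)
    rule_dim <- sample(dims, 1L)
    rule_feat <- sample(level$dimensions[[rule_dim]], 1L)
    initial <- list(dimension = rule_dim, feature = rule_feat)

    old_dims <- old_feats <- new_dims <- new_feats <- character(n_shift)
    for (i in seq_len(n_shift)) {
      old_dims[i] <- rule_dim
      old_feats[i] <- rule_feat
      if (identical(types[i], "ID")) {
        rule_feat <- resample(setdiff(level$dimensions[[rule_dim]], rule_feat), 1L)
      } else {
        rule_dim <- resample(setdiff(dims, rule_dim), 1L)
        rule_feat <- resample(level$dimensions[[rule_dim]], 1L)
      }
      new_dims[i] <- rule_dim
      new_feats[i] <- rule_feat
    }
    sched <- tibble::new_tibble(
      list(trial = pos, shift_type = types, old_dim = old_dims,
           old_feature = old_feats, new_dim = new_dims,
           new_feature = new_feats),
      nrow = n_shift
    )
    attr(sched, "initial_rule") <- initial
    sched
  })
}

# sample(x, 1) without the length-1 numeric trap
resample <- function(x, n) x[sample.int(length(x), n)]

sample_shift_types <- function(pos, n_shift, level) {
  if (n_shift == 0L) return(character(0))
  blocks <- pos %/% level$trials_per_block
  for (attempt in seq_len(10000L)) {
    types <- sample(c("ID", "ED"), n_shift, replace = TRUE)
    ok <- TRUE
    for (b in unique(blocks)) {
      tb <- types[blocks == b]
      if (length(tb) >= 2L && length(unique(tb)) < 2L) { ok <- FALSE; break }
    }
    if (ok && n_shift >= 2L && length(unique(types)) < 2L) ok <- FALSE
    if (ok) return(types)
  }
  abort("Could not sample a shift-type sequence satisfying the block constraint.")
}

# rule (dim, feature) in force at every trial of a level
rule_sequence <- function(schedule, nt) {
  init <- attr(schedule, "initial_rule")
  dim_seq <- rep(init$dimension, nt)
  feat_seq <- rep(init$feature, nt)
  if (nrow(schedule)) {
    for (i in seq_len(nrow(schedule))) {
      idx <- (schedule$trial[i] + 1L):nt
      dim_seq[idx] <- schedule$new_dim[i]
      feat_seq[idx] <- schedule$new_feature[i]
    }
  }
  list(dim = dim_seq, feature = feat_seq)
}

#' Sample the stimulus layout for one trial
#'
#' Every feature of every dimension is displayed exactly once per trial: for
#' each dimension the features are randomly permuted across the stimuli, so
#' within each dimension the displayed stimuli carry pairwise distinct
#' features and exactly one stimulus carries the currently rewarded feature.
#'
#' @inheritParams sample_shift_schedule
#' @return A character matrix (dimensions x stimuli); column `j` is the
#'   feature set of stimulus `j`.
#' @export
sample_trial_layout <- function(level, seed = NULL) {
  validate_level(level)
  with_seed_if(seed, layout_once(level))
}

layout_once <- function(level) {
  k <- level$n_stimuli
  m <- matrix("", nrow = length(level$dimensions), ncol = k,
              dimnames = list(names(level$dimensions), NULL))
  for (d in seq_along(level$dimensions)) {
    m[d, ] <- resample(level$dimensions[[d]], k)
  }
  m
}

#' Evaluate a choice against the current rule
#'
#' @param display A dimensions-x-stimuli character matrix as returned by
#'   [sample_trial_layout()].
#' @param choice 1-based index of the chosen stimulus.
#' @param rule A list with `dimension` and `feature` (the rewarded feature).
#' @return `1L` if the chosen stimulus carries the rewarded feature, else `0L`.
#' @export
evaluate_choice <- function(display, choice, rule) {
  k <- ncol(display)
  if (length(choice) != 1L || is.na(choice) || choice < 1L || choice > k) {
    abort(sprintf("`choice` must be a stimulus index in 1..%d.", k))
  }
  as.integer(rule$feature %in% display[, choice])
}

#' Simulate one level of the task under a choice policy
#'
#' The policy is a function `policy(display, history)` returning the 1-based
#' index of the chosen stimulus. `history` is a list with elements `displays`
#' (list of past display matrices), `choices` and `outcomes` (integer
#' vectors), all covering trials before the current one.
#'
#' @inheritParams sample_shift_schedule
#' @param policy Choice policy callback.
#' @param participant_id Identifier written into the log.
#' @param schedule Optional pre-sampled shift schedule (else sampled from
#'   `seed`).
#' @return A trial-log tibble, one row per trial, with columns
#'   `participant_id`, `level`, `block`, `trial` (0-based within level),
#'   `stim1..stim3` (semicolon-joined feature labels; `stim3` is `NA` for
#'   two-stimulus levels), `rule_dim`, `rule_feature`, `shift` (logical,
#'   first trial governed by a new rule), `shift_type`, `choice` (1-based),
#'   `outcome` (0/1), `confidence` (`NA`; filled by agents or humans), `rt`.
#' @export
run_level <- function(level, policy, seed = NULL, participant_id = "p1",
                      schedule = NULL) {
  validate_level(level)
  with_seed_if(seed, {
    if (is.null(schedule)) schedule <- sample_shift_schedule(level)
    nt <- n_trials(level)
    rules <- rule_sequence(schedule, nt)
    shift_flag <- logical(nt)
    shift_type <- rep("none", nt)
    if (nrow(schedule)) {
      shift_flag[schedule$trial + 1L] <- TRUE
      shift_type[schedule$trial + 1L] <- schedule$shift_type
    }

    displays <- vector("list", nt)
    choices <- integer(nt)
    outcomes <- integer(nt)
    stim_str <- matrix(NA_character_, nrow = nt, ncol = 3L)

    for (t in seq_len(nt)) {
      disp <- layout_once(level)
      displays[[t]] <- disp
      hist <- list(
        displays = displays[seq_len(t - 1L)],
        choices = choices[seq_len(t - 1L)],
        outcomes = outcomes[seq_len(t - 1L)]
      )
      ch <- policy(disp, hist)
      if (length(ch) != 1L || is.na(ch) || ch < 1L || ch > level$n_stimuli) {
        abort(sprintf("Policy returned an invalid stimulus index at trial %d.", t - 1L))
      }
      ch <- as.integer(ch)
      choices[t] <- ch
      outcomes[t] <- evaluate_choice(
        disp, ch, list(dimension = rules$dim[t], feature = rules$feature[t])
      )
      stim_str[t, seq_len(level$n_stimuli)] <-
        apply(disp, 2L, paste, collapse = ";")
    }

    block_idx <- (seq_len(nt) - 1L) %/% level$trials_per_block
    tibble(
      participant_id = participant_id,
      level = level$level_id,
      block = block_idx,
      trial = seq_len(nt) - 1L,
      stim1 = stim_str[, 1L], stim2 = stim_str[, 2L], stim3 = stim_str[, 3L],
      rule_dim = rules$dim, rule_feature = rules$feature,
      shift = shift_flag, shift_type = shift_type,
      choice = choices, outcome = outcomes,
      confidence = NA_integer_, rt = NA_real_
    )
  })
}

#' Simulate the full multi-level task for one participant
#'
#' @param levels List of [level_spec()] objects (default: the three-level
#'   200-trial design).
#' @inheritParams run_level
#' @return A trial-log tibble covering all levels (see [run_level()]).
#' @export
run_task <- function(levels = make_default_levels(), policy, seed = NULL,
                     participant_id = "p1") {
  logs <- purrr::imap(levels, function(lev, i) {
    run_level(lev, policy,
              seed = if (is.null(seed)) NULL else child_seed(seed, i),
              participant_id = participant_id)
  })
  dplyr::bind_rows(logs)
}

#' Uniformly random choice policy
#'
#' @return A policy function for [run_level()] choosing uniformly among the
#'   displayed stimuli.
#' @export
policy_random <- function() {
  function(display, history) sample.int(ncol(display), 1L)
}
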