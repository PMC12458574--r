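#' Initialise a uniform belief state over features
#'
#' The observer's belief is a probability distribution over the N unique
#' feature labels displayed at a level; it starts flat (1/N each) at the
#' beginning of every level.
#'
#' @param features Character vector of (unique) feature labels.
#' @return A named numeric probability vector of class `rs_belief`.
#' @export
init_beliefs <- function(features) {
  features <- as.character(features)
  if (length(features) < 2L) abort("Need at least 2 features.")
  if (anyDuplicated(features)) abort("Feature labels must be unique.")
  structure(setNames(rep(1 / length(features), length(features)), features),
            class = "rs_belief")
}

validate_belief <- function(belief) {
  p <- unclass(belief)
  if (is.null(names(p)) || !is.numeric(p)) {
    abort("`belief` must be a named numeric vector (see init_beliefs()).")
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-10) {
    abort("`belief` must be a probability vector (nonnegative, summing to 1).")
  }
  invisible(belief)
}

# features on the chosen stimulus / pooled over all unchosen stimuli.
# Errors if some dimension repeats a feature across stimuli (the engine's
# displays never do; the likelihood is only defined for differing dimensions).
display_feature_sets <- function(display, choice) {
  k <- ncol(display)
  if (length(choice) != 1L || is.na(choice) || choice < 1L || choice > k) {
    abort(sprintf("`choice` must be a stimulus index in 1..%d.", k))
  }
  if (any(apply(display, 1L, anyDuplicated) > 0L)) {
    abort("Display invariant violated: a dimension repeats a feature across stimuli.")
  }
  chosen <- display[, choice]
  unchosen <- unique(as.vector(display[, -choice, drop = FALSE]))
  list(chosen = chosen, unchosen = unchosen)
}

#' Feedback likelihood of an outcome given a candidate rewarded feature
#'
#' The likelihood spreads the evidence of a rewarded outcome uniformly over
#' the unique features of the chosen stimulus, and of an unrewarded outcome
#' uniformly over the unique features pooled across all unchosen stimuli;
#' features on the "wrong side" of the feedback get likelihood 0.
#'
#' @param feature Candidate rewarded feature label.
#' @param outcome Observed reward (1) or non-reward (0).
#' @param display Dimensions-x-stimuli character matrix.
#' @param choice 1-based chosen stimulus index.
#' @return The likelihood P(outcome | feature is the rewarded one).
#' @export
outcome_likelihood <- function(feature, outcome, display, choice) {
  sets <- display_feature_sets(display, choice)
  if (!feature %in% c(sets$chosen, sets$unchosen)) {
    abort(sprintf("Feature '%s' is not on the display.", feature))
  }
  on_chosen <- feature %in% sets$chosen
  if (outcome == 1) {
    if (on_chosen) 1 / length(sets$chosen) else 0
  } else {
    if (on_chosen) 0 else 1 / length(sets$unchosen)
  }
}

#' Bayesian belief update from one trial's feedback
#'
#' Multiplies the prior by the feedback likelihood and renormalises. If the
#' feedback invalidates every currently supported hypothesis (normalising
#' constant 0), the belief is reset to uniform, reflecting the observer's
#' knowledge that covert rule shifts occur. Probabilities below `1e-15` are
#' truncated to 0 before the zero-denominator test so resets are robust to
#' floating-point residue.
#'
#' @param belief Prior belief (see [init_beliefs()]).
#' @inheritParams outcome_likelihood
#' @return A list with `belief` (posterior, class `rs_belief`) and `reset`
#'   (logical).
#' @export
update_beliefs <- function(belief, display, choice, outcome) {
  validate_belief(belief)
  feats <- names(belief)
  sets <- display_feature_sets(display, choice)
  if (!setequal(feats, c(sets$chosen, sets$unchosen))) {
    abort("Belief feature set does not match the display's feature set.")
  }
  lik <- numeric(length(feats))
  names(lik) <- feats
  if (outcome == 1) {
    lik[sets$chosen] <- 1 / length(sets$chosen)
  } else {
    lik[sets$unchosen] <- 1 / length(sets$unchosen)
  }
  unnorm <- lik * unclass(belief)
  unnorm[unnorm < 1e-15] <- 0
  z <- sum(unnorm)
  if (z <= 1e-12) {
    list(belief = init_beliefs(feats), reset = TRUE)
  } else {
    list(belief = structure(unnorm / z, class = "rs_belief"), reset = FALSE)
  }
}

#' Shannon entropy of a belief state, in bits
#'
#' Uses the convention 0 * log2(0) = 0.
#'
#' @param belief A belief state.
#' @return Entropy in bits.
#' @export
posterior_entropy <- function(belief) {
  p <- unclass(belief)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' General Certainty: scaled inverse entropy of the belief
#'
#' The proportion of the maximum possible uncertainty (log2 N bits) that has
#' been eliminated, on the participants' 0-100 confidence scale:
#' `GC = 100 * (log2 N - S) / log2 N`. It is 0 for a uniform belief and 100
#' for a point mass. `variant = "printed"` computes
#' `100 * (log2 N - log2 S) / log2 N` instead, a dimensionally inconsistent
#' alternative retained only for sensitivity analysis (it diverges as S -> 0
#' and is nonzero at uniform).
#'
#' @param belief A belief state over N >= 2 features.
#' @param variant `"proportion"` (default) or `"printed"`.
#' @return Certainty on the 0-100 scale.
#' @export
general_certainty <- function(belief, variant = c("proportion", "printed")) {
  variant <- match.arg(variant)
  n <- length(unclass(belief))
  if (n < 2L) abort("General certainty requires at least 2 features.")
  s <- posterior_entropy(belief)
  if (variant == "proportion") {
    100 * (log2(n) - s) / log2(n)
  } else {
    100 * (log2(n) - log2(s)) / log2(n)
  }
}

#' Choice Certainty: posterior mass on the chosen stimulus
#'
#' The summed belief over the unique features carried by the chosen
#' stimulus, scaled to 0-100. Because each feature is displayed on exactly
#' one stimulus, choice certainties sum to 100 across the displayed stimuli.
#'
#' @inheritParams update_beliefs
#' @return Certainty on the 0-100 scale.
#' @export
choice_certainty <- function(belief, display, choice) {
  validate_belief(belief)
  sets <- display_feature_sets(display, choice)
  100 * sum(unclass(belief)[sets$chosen])
}

# ---- trace computation over trial logs --------------------------------------

# split "a;b;c" stimulus strings of one participant-level chunk into integer
# feature indices; returns list(features = chr, chosen = list of int vectors,
# n_stimuli, stim_sets = list over stimuli of n x ndim index matrices)
parse_displays <- function(chunk) {
  stim_cols <- c("stim1", "stim2", "stim3")
  present <- stim_cols[vapply(stim_cols, function(cc)
    cc %in% names(chunk) && !all(is.na(chunk[[cc]])), TRUE)]
  sets <- lapply(present, function(cc) strsplit(chunk[[cc]], ";", fixed = TRUE))
  features <- sort(unique(unlist(sets[[1]][1])))
  for (s in sets) features <- sort(unique(c(features, unlist(s[1]))))
  idx_sets <- lapply(sets, function(s) {
    lapply(s, function(f) {
      i <- match(f, features)
      if (anyNA(i)) abort("Display contains a feature label not seen on trial 0; feature set must be constant within a level.")
      i
    })
  })
  list(features = features, stim_sets = idx_sets, n_stimuli = length(present))
}

observer_trace_chunk <- function(chunk, gc_variant) {
  chunk <- dplyr::arrange(chunk, .data$trial)
  pd <- parse_displays(chunk)
  nfeat <- length(pd$features)
  nt <- nrow(chunk)
  if (!identical(sort(chunk$trial), 0:(nt - 1L))) {
    abort("Trial indices within a participant x level must be contiguous from 0.")
  }
  max_s <- log2(nfeat)
  gc_of <- function(s) {
    if (gc_variant == "proportion") 100 * (max_s - s) / max_s
    else 100 * (max_s - log2(s)) / max_s
  }
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

  prior <- rep(1 / nfeat, nfeat)
  gc_pre <- cc_pre <- gc_post <- cc_post <- entropy_bits <- numeric(nt)
  reset <- logical(nt)

  for (t in seq_len(nt)) {
    ch <- chunk$choice[t]
    chosen <- pd$stim_sets[[ch]][[t]]
    # every feature appears exactly once per trial -> unchosen = complement
    gc_pre[t] <- gc_of(ent(prior))
    cc_pre[t] <- 100 * sum(prior[chosen])
    lik <- numeric(nfeat)
    if (chunk$outcome[t] == 1) {
      lik[chosen] <- 1 / length(chosen)
    } else {
      lik[-chosen] <- 1 / (nfeat - length(chosen))
    }
    unnorm <- lik * prior
    unnorm[unnorm < 1e-15] <- 0
    z <- sum(unnorm)
    if (z <= 1e-12) {
      prior <- rep(1 / nfeat, nfeat)
      reset[t] <- TRUE
    } else {
      prior <- unnorm / z
    }
    entropy_bits[t] <- ent(prior)
    gc_post[t] <- gc_of(entropy_bits[t])
    cc_post[t] <- 100 * sum(prior[chosen])
  }

  chunk$gc_pre <- gc_pre
  chunk$cc_pre <- cc_pre
  chunk$gc_post <- gc_post
  chunk$cc_post <- cc_post
  chunk$entropy_bits <- entropy_bits
  chunk$reset <- reset
  chunk
}

#' Run the Bayes-optimal observer over a trial log
#'
#' Replays each participant's choices and feedback through the normative
#' observer, re-initialising the belief to uniform at the start of every
#' level. Two certainty traces are emitted per trial: `gc_pre`/`cc_pre` use
#' the belief updated through trial t-1 plus the trial-t choice -- the values
#' aligned with the participant's confidence report, which precedes feedback
#' -- and `gc_post`/`cc_post` use the post-feedback posterior (useful for
#' time-course plots). `entropy_bits` is the posterior entropy and `reset`
#' flags trials whose feedback invalidated every supported hypothesis.
#'
#' @param trials A trial-log tibble (see [run_level()]), any number of
#'   participants and levels.
#' @param gc_variant General-certainty variant, see [general_certainty()].
#' @return The input tibble with the six trace columns appended.
#' @export
run_observer <- function(trials, gc_variant = c("proportion", "printed")) {
  gc_variant <- match.arg(gc_variant)
  needed <- c("participant_id", "level", "trial", "stim1", "stim2", "choice", "outcome")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    abort(paste0("Trial log is missing column(s): ", paste(missing, collapse = ", ")))
  }
  trials |>
    dplyr::group_by(.data$participant_id, .data$level) |>
    dplyr::group_modify(~ observer_trace_chunk(.x, gc_variant)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$participant_id, .data$level, .data$trial)
}
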