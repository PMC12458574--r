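# Build a display matrix from one character vector per stimulus
# (each vector = that stimulus's features, one per dimension).
mk_display <- function(...) {
  stims <- list(...)
  matrix(unlist(stims), nrow = length(stims[[1]]),
         dimnames = list(paste0("dim", seq_along(stims[[1]])), NULL))
}

# parse the stim1..stim3 string columns of a trial log back into matrices
parse_log_displays <- function(log) {
  stim_cols <- c("stim1", "stim2", "stim3")
  stim_cols <- stim_cols[!vapply(stim_cols, function(cc) all(is.na(log[[cc]])), TRUE)]
  lapply(seq_len(nrow(log)), function(t) {
    cols <- lapply(stim_cols, function(cc) strsplit(log[[cc]][t], ";")[[1]])
    matrix(unlist(cols), nrow = length(cols[[1]]))
  })
}

# Likelihood of the observed feedback under candidate feature f, recomputed
# from first principles (counting, not the package's code path).
oracle_lik <- function(f, display, choice, outcome) {
  chosen <- display[, choice]
  unchosen <- setdiff(as.vector(display), chosen)
  if (outcome == 1) {
    if (f %in% chosen) 1 / length(chosen) else 0
  } else {
    if (f %in% chosen) 0 else 1 / length(unchosen)
  }
}

# Brute-force reference posterior trajectory. Reset segmentation comes from
# consistent-hypothesis set logic; posterior values are fresh normalised
# products of likelihoods over the trials since the last reset (recomputed
# from scratch at every trial, independent of any incremental update).
oracle_trajectory <- function(displays, choices, outcomes, features) {
  nt <- length(displays)
  consistent_set <- function(display, choice, outcome) {
    chosen <- display[, choice]
    if (outcome == 1) chosen else setdiff(as.vector(display), chosen)
  }
  seg_start <- 1L
  supports <- vector("list", nt)
  posteriors <- vector("list", nt)
  resets <- logical(nt)
  current <- features
  for (t in seq_len(nt)) {
    keep <- intersect(current, consistent_set(displays[[t]], choices[t], outcomes[t]))
    if (length(keep) == 0L) {
      resets[t] <- TRUE
      current <- features
      seg_start <- t + 1L
      posteriors[[t]] <- setNames(rep(1 / length(features), length(features)),
                                  features)
    } else {
      current <- keep
      prod_w <- setNames(rep(1, length(features)), features)
      for (s in seg_start:t) {
        for (f in features) {
          prod_w[f] <- prod_w[f] *
            oracle_lik(f, displays[[s]], choices[s], outcomes[s])
        }
      }
      posteriors[[t]] <- prod_w / sum(prod_w)
    }
    supports[[t]] <- if (resets[t]) features else current
  }
  list(posteriors = posteriors, supports = supports, resets = resets)
}

oracle_entropy <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
oracle_gc <- function(p) {
  n <- length(p)
  100 * (log2(n) - oracle_entropy(p)) / log2(n)
}

# a short level for randomised observer tests
mini_level <- function(n_stimuli = 2L, nt = 20L) {
  if (n_stimuli == 2L) {
    level_spec(1L, 2L,
               dimensions = list(colour = c("orange", "blue"),
                                 shape = c("round", "star")),
               n_blocks = 1L, trials_per_block = nt)
  } else {
    level_spec(3L, 3L,
               dimensions = list(colour = c("orange", "blue", "green"),
                                 shape = c("round", "star", "hexagon"),
                                 hair = c("hair", "no-hair", "curly-hair")),
               n_blocks = 1L, trials_per_block = nt)
  }
}
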