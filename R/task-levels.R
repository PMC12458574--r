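#' Define a task difficulty level
#'
#' A level fixes the number of displayed stimuli, the stimulus dimensions and
#' their feature labels, the block structure, and the bounds of the covert
#' rule-shift gap. Every dimension must carry exactly `n_stimuli` features so
#' that each trial can display each feature exactly once (one per stimulus),
#' which guarantees that exactly one displayed stimulus carries the rewarded
#' feature.
#'
#' @param level_id Integer level identifier (1, 2, 3 in the default design).
#' @param n_stimuli Number of stimuli displayed per trial.
#' @param dimensions Named list of character vectors: dimension name ->
#'   feature labels. Feature labels must be unique across dimensions.
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block.
#' @param shift_gap_min,shift_gap_max Inclusive bounds (in trials) of the
#'   uniform gap between consecutive covert rule shifts.
#' @return A `rs_level` object (a validated list).
#' @seealso [make_default_levels()]
#' @export
level_spec <- function(level_id, n_stimuli, dimensions, n_blocks,
                       trials_per_block, shift_gap_min = 6L,
                       shift_gap_max = 11L) {
  lev <- structure(
    list(
      level_id = as.integer(level_id),
      n_stimuli = as.integer(n_stimuli),
      dimensions = lapply(dimensions, as.character),
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      shift_gap_min = as.integer(shift_gap_min),
      shift_gap_max = as.integer(shift_gap_max)
    ),
    class = "rs_level"
  )
  validate_level(lev)
}

validate_level <- function(level) {
  if (!inherits(level, "rs_level")) abort("`level` must be an `rs_level` object.")
  dims <- level$dimensions
  if (is.null(names(dims)) || any(names(dims) == "")) {
    abort("All dimensions must be named.")
  }
  nf <- lengths(dims)
  if (any(nf < 2L)) abort("Each dimension needs at least 2 features.")
  if (any(nf != level$n_stimuli)) {
    abort(sprintf(
      "Every dimension must have exactly %d features (one per displayed stimulus); got counts: %s.",
      level$n_stimuli, paste(nf, collapse = ", ")
    ))
  }
  feats <- unlist(dims, use.names = FALSE)
  if (anyDuplicated(feats)) abort("Feature labels must be unique across dimensions.")
  if (level$shift_gap_min < 1L || level$shift_gap_max < level$shift_gap_min) {
    abort("Invalid shift gap bounds.")
  }
  level
}

n_trials <- function(level) level$n_blocks * level$trials_per_block
level_features <- function(level) unlist(level$dimensions, use.names = FALSE)

#' @export
print.rs_level <- function(x, ...) {
  cat(sprintf(
    "<rs_level %d> %d stimuli, %d x %d trials, dims: %s\n",
    x$level_id, x$n_stimuli, x$n_blocks, x$trials_per_block,
    paste(sprintf("%s(%s)", names(x$dimensions),
                  vapply(x$dimensions, paste, "", collapse = "/")),
          collapse = ", ")
  ))
  invisible(x)
}

#' Default three-level rule-shifting task design
#'
#' Level 1: 2 stimuli differing on 2 dimensions, 60 trials (2 blocks of 30).
#' Level 2: 2 stimuli, 3 dimensions, 70 trials (2 blocks of 35).
#' Level 3: 3 stimuli, 3 dimensions (3 features each), 70 trials
#' (2 blocks of 35). Total: 200 trials. Covert rule shifts occur every 6-11
#' trials at every level.
#'
#' @return A list of three [level_spec()] objects.
#' @examples
#' levels <- make_default_levels()
#' sum(vapply(levels, function(l) l$n_blocks * l$trials_per_block, 0L))
#' @export
make_default_levels <- function() {
  list(
    level_spec(
      1L, 2L,
      dimensions = list(
        colour = c("orange", "blue"),
        shape  = c("round", "star")
      ),
      n_blocks = 2L, trials_per_block = 30L
    ),
    level_spec(
      2L, 2L,
      dimensions = list(
        colour = c("orange", "blue"),
        shape  = c("round", "star"),
        hair   = c("hair", "no-hair")
      ),
      n_blocks = 2L, trials_per_block = 35L
    ),
    level_spec(
      3L, 3L,
      dimensions = list(
        colour = c("orange", "blue", "green"),
        shape  = c("round", "star", "hexagon"),
        hair   = c("hair", "no-hair", "curly-hair")
      ),
      n_blocks = 2L, trials_per_block = 35L
    )
  )
}
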