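# shared simulated cohorts, built once per test run
.cohort_cache <- new.env(parent = emptyenv())

# default-preset cohort at full size (29 + 29)
default_cohort <- function() {
  if (is.null(.cohort_cache$default)) {
    .cohort_cache$default <- suppressWarnings(simulate_cohort(seed = 101L))
  }
  .cohort_cache$default
}

# small preset cohort for quick model fits
small_cohort <- function() {
  if (is.null(.cohort_cache$small)) {
    sp <- default_group_specs(n = 8L)
    .cohort_cache$small <-
      suppressWarnings(simulate_cohort(sp$ocd, sp$control, seed = 202L))
  }
  .cohort_cache$small
}

# observer traces for the default cohort
default_traces <- function() {
  if (is.null(.cohort_cache$traces)) {
    .cohort_cache$traces <- run_observer(default_cohort()$trials)
  }
  .cohort_cache$traces
}
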