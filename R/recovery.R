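#' Parameter-recovery experiment for the group confidence effects
#'
#' Repeatedly simulates two-group cohorts with a known confidence-intercept
#' difference (`delta_b`, OCD minus control, slider units) and
#' Choice-Certainty coupling difference (`delta_w`), runs the full analysis
#' pipeline on each replicate (participant exclusions, RT outlier filter,
#' Bayes-observer traces, joint normative mixed model) and records the
#' estimated group main effect and CC x group interaction.
#'
#' @param delta_b True OCD-minus-control confidence intercept difference
#'   (default -12).
#' @param delta_w True OCD-minus-control CC weight difference (default +3).
#' @param n_per_group Participants per group (default 29).
#' @param n_replicates Number of replicate cohorts (>= 1).
#' @param seed Integer master seed; replicate seeds are derived from it.
#' @param alpha Significance threshold used for the sign-recovery rate.
#' @return An `rs_recovery` object: list with `replicates` (one row per
#'   replicate: estimates, SEs, p-values, exclusion count) and `truth`.
#'   `summary()` reports bias, RMSE and sign-recovery rates.
#' @export
recovery_experiment <- function(delta_b = -12, delta_w = 3, n_per_group = 29L,
                                n_replicates = 1L, seed = NULL, alpha = 0.05) {
  if (n_replicates < 1L) abort("`n_replicates` must be at least 1.")
  specs <- default_group_specs(delta_b = delta_b, delta_w = delta_w,
                               n = n_per_group)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_seed <- if (is.null(seed)) NULL else child_seed(seed, r)
    cohort <- simulate_cohort(specs$ocd, specs$control, seed = rep_seed)
    res <- analyze_cohort_normative(cohort)
    est <- res$model$coefficients
    pick <- function(term, col) est[[col]][est$term == term]
    rows[[r]] <- tibble(
      replicate = r,
      n_excluded = res$n_excluded,
      b_estimate = pick("groupOCD", "estimate"),
      b_se = pick("groupOCD", "se"),
      b_p = pick("groupOCD", "p_value"),
      w_estimate = pick("z_cc:groupOCD", "estimate"),
      w_se = pick("z_cc:groupOCD", "se"),
      w_p = pick("z_cc:groupOCD", "p_value"),
      singular = res$model$singular
    )
  }
  structure(
    list(
      replicates = dplyr::bind_rows(rows),
      truth = list(delta_b = delta_b, delta_w = delta_w),
      n_per_group = n_per_group, alpha = alpha
    ),
    class = "rs_recovery"
  )
}

# exclusions -> observer traces (on complete logs; the observer must see
# every trial) -> RT filter on the modelled rows -> joint normative model
analyze_cohort_normative <- function(cohort) {
  excl <- apply_exclusions(cohort)
  traces <- run_observer(excl$cohort$trials)
  filt <- rt_outlier_filter(traces)
  model <- fit_normative_model(excl$cohort, traces = filt$trials,
                               spec = "joint", vif = FALSE)
  list(model = model, n_excluded = sum(excl$report$excluded),
       rt_fraction_removed = filt$fraction_removed)
}

#' @export
print.rs_recovery <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<rs_recovery> %d replicates, n = %d/group, truth: delta_b = %g, delta_w = %g\n",
              nrow(x$replicates), x$n_per_group, x$truth$delta_b,
              x$truth$delta_w))
  print(as.data.frame(s), digits = 3)
  invisible(x)
}

#' @export
summary.rs_recovery <- function(object, ...) {
  reps <- object$replicates
  tb <- object$truth$delta_b
  tw <- object$truth$delta_w
  a <- object$alpha
  sign_ok <- function(est, p, true) {
    if (true == 0) return(NA_real_)
    mean(sign(est) == sign(true) & p < a)
  }
  tibble(
    effect = c("group intercept (delta_b)", "CC x group (delta_w)"),
    truth = c(tb, tw),
    mean_estimate = c(mean(reps$b_estimate), mean(reps$w_estimate)),
    bias = c(mean(reps$b_estimate) - tb, mean(reps$w_estimate) - tw),
    rmse = c(sqrt(mean((reps$b_estimate - tb)^2)),
             sqrt(mean((reps$w_estimate - tw)^2))),
    sign_recovery = c(sign_ok(reps$b_estimate, reps$b_p, tb),
                      sign_ok(reps$w_estimate, reps$w_p, tw)),
    rejection_rate = c(mean(reps$b_p < a), mean(reps$w_p < a))
  )
}
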