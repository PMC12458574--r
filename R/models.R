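# ---- analysis frame ---------------------------------------------------------

# merge trials + demographics into a model-ready frame: group as factor with
# control reference, z-scored continuous covariates (categoricals untouched),
# within-level lagged outcome, shift distances
build_analysis_frame <- function(cohort, traces = NULL) {
  trials <- traces %||% cohort$trials
  demo <- cohort$demographics |>
    dplyr::mutate(
      group = factor(.data$group, levels = c("control", "OCD")),
      gender = factor(.data$gender, levels = c(1, 2, 0)),
      z_age = zscore(.data$age),
      z_iq = zscore(.data$iq)
    )
  trials |>
    annotate_shift_distance() |>
    dplyr::group_by(.data$participant_id, .data$level) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(prev_outcome = dplyr::lag(.data$outcome)) |>
    dplyr::ungroup() |>
    dplyr::left_join(demo, by = "participant_id") |>
    dplyr::mutate(level_f = factor(.data$level))
}

# ---- model result container -------------------------------------------------

new_rs_model <- function(fit, formula, family, simplified = NULL, vif = NULL) {
  is_lmm <- inherits(fit, "lmerModLmerTest") || inherits(fit, "lmerMod")
  sm <- coef(summary(fit))
  coefs <- tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    statistic = sm[, if (is_lmm) "t value" else "z value"],
    df = if ("df" %in% colnames(sm)) sm[, "df"] else NA_real_,
    p_value = sm[, grep("^Pr", colnames(sm))]
  )
  msgs <- fit@optinfo$conv$lme4$messages
  conv <- length(setdiff(msgs, msgs[grepl("boundary \\(singular\\)", msgs)])) == 0L
  structure(
    list(
      formula = formula, family = family, coefficients = coefs,
      bic = BIC(fit), converged = conv, singular = lme4::isSingular(fit),
      simplified = simplified, vif = vif, n_obs = stats::nobs(fit),
      fit = fit
    ),
    class = "rs_model"
  )
}

#' @export
print.rs_model <- function(x, ...) {
  cat(sprintf("<rs_model> %s family: %s\n", x$family, x$formula))
  cat(sprintf("  BIC %.1f | converged: %s | singular: %s%s\n",
              x$bic, x$converged, x$singular,
              if (!is.null(x$simplified)) paste0(" | random effects simplified: ",
                                                 x$simplified) else ""))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

# is the participant-level random part degenerate (zero slope variance or
# |correlation| at 1)? A zero variance of the few-level task-level intercept
# also makes lme4 report a singular fit, but that is harmless and no reason
# to drop the participant slope.
participant_re_degenerate <- function(fit) {
  vc <- lme4::VarCorr(fit)
  vc <- vc[grep("^participant_id", names(vc))]
  resid_sd <- if (inherits(fit, "glmerMod")) 1 else attr(lme4::VarCorr(fit), "sc")
  for (m in vc) {
    sds <- attr(m, "stddev")
    if (any(sds < 1e-4 * max(resid_sd, max(sds)))) return(TRUE)
    cr <- attr(m, "correlation")
    if (!is.null(cr) && nrow(cr) > 1L &&
        any(abs(cr[lower.tri(cr)]) > 0.999)) return(TRUE)
  }
  FALSE
}

# fit a mixed model, walking the random-effects simplification ladder when
# the participant-level random part degenerates or the fit does not
# converge: full -> uncorrelated slope -> intercept only
fit_mixed <- function(fixed, random_ladder, data, family = "gaussian") {
  notes <- c(NA_character_, "uncorrelated random slope", "random intercepts only")
  last_err <- NULL
  for (i in seq_along(random_ladder)) {
    f <- as.formula(paste(fixed, "+", random_ladder[[i]]))
    fit <- tryCatch(
      suppressMessages(
        if (family == "binomial") {
          lme4::glmer(f, data = data, family = stats::binomial(),
                      control = lme4::glmerControl(
                        optimizer = "bobyqa", optCtrl = list(maxfun = 2e5)))
        } else {
          lmerTest::lmer(f, data = data, REML = TRUE,
                         control = lme4::lmerControl(
                           optimizer = "bobyqa", optCtrl = list(maxfun = 2e5)))
        }
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) { last_err <- fit; next }
    msgs <- fit@optinfo$conv$lme4$messages
    conv_ok <- length(msgs[!grepl("boundary \\(singular\\)", msgs)]) == 0L
    ok <- conv_ok && !participant_re_degenerate(fit)
    if (ok || i == length(random_ladder)) {
      return(new_rs_model(fit, deparse1(f), family,
                          simplified = notes[min(i, 3L)]))
    }
  }
  abort(paste("All candidate fits failed:", conditionMessage(last_err)))
}

# ---- functional-form selection ----------------------------------------------

form_terms <- function(form) {
  switch(form,
    linear = "z_dist",
    log = "log_dist",
    quadratic = "poly1 + poly2",
    abort(sprintf("Unknown functional form '%s'.", form))
  )
}

# distance regressors for post-shift trials: z-scored linear distance,
# log distance, and centred orthogonal polynomials of the observed distances
add_distance_terms <- function(df) {
  pp <- poly(df$post_distance, 2)
  df$z_dist <- zscore(df$post_distance)
  df$log_dist <- log(df$post_distance)
  df$poly1 <- pp[, 1L]
  df$poly2 <- pp[, 2L]
  df
}

post_shift_frame <- function(cohort, shift_type = NULL, window = 5L,
                             traces = NULL) {
  df <- build_analysis_frame(cohort, traces) |>
    dplyr::filter(!is.na(.data$post_distance), .data$post_distance <= window)
  if (!is.null(shift_type)) {
    df <- dplyr::filter(df, .data$post_shift_type == .env$shift_type)
  }
  add_distance_terms(df)
}

#' Select the functional form of post-shift recovery by BIC
#'
#' Fits one mixed model per candidate functional form of the trial distance
#' from the shift (linear: z-scored distance; log: log distance; quadratic:
#' centred orthogonal polynomials) and returns the form with the lowest BIC.
#' Accuracy models are logistic, confidence models linear; all candidates are
#' fitted with maximum likelihood (REML off) and a random intercept per
#' participant. Ties are broken toward the form with fewer parameters, then
#' candidate order.
#'
#' @param cohort An `rs_cohort` (exclusions already applied by the caller).
#' @param outcome `"accuracy"` or `"confidence"`.
#' @param shift_type Restrict to `"ID"` or `"ED"` shifts (`NULL` = both).
#' @param forms Candidate forms, a subset of `c("linear","quadratic","log")`.
#' @param window Post-shift window in trials (default 5).
#' @return A list with `choice` (the selected form) and `bic` (tibble of
#'   form, df, BIC).
#' @export
select_functional_form <- function(cohort, outcome = c("accuracy", "confidence"),
                                   shift_type = NULL,
                                   forms = c("linear", "quadratic", "log"),
                                   window = 5L) {
  outcome <- match.arg(outcome)
  if (length(forms) < 2L) abort("Need at least 2 candidate forms.")
  df <- post_shift_frame(cohort, shift_type, window)
  lhs <- if (outcome == "accuracy") "outcome" else "confidence"

  rows <- purrr::map(forms, function(fm) {
    f <- as.formula(paste(lhs, "~", form_terms(fm), "+ (1 | participant_id)"))
    fit <- tryCatch(
      if (outcome == "accuracy") {
        lme4::glmer(f, data = df, family = stats::binomial())
      } else {
        lme4::lmer(f, data = df, REML = FALSE)
      },
      error = function(e) NULL
    )
    if (is.null(fit)) return(tibble(form = fm, df = NA_real_, bic = NA_real_))
    tibble(form = fm, df = attr(logLik(fit), "df"), bic = BIC(fit))
  }) |> dplyr::bind_rows()

  if (all(is.na(rows$bic))) abort("No candidate functional form converged.")
  ranked <- rows |>
    dplyr::mutate(.ord = seq_len(dplyr::n())) |>
    dplyr::filter(!is.na(.data$bic)) |>
    dplyr::arrange(.data$bic, .data$df, .data$.ord)
  list(choice = ranked$form[1L], bic = dplyr::select(rows, -dplyr::any_of(".ord")))
}

#' Post-shift recovery mixed model
#'
#' Models accuracy (logistic) or confidence (linear) over the first `window`
#' trials after a rule shift as a function of trial distance (in the chosen
#' functional form), with demographic covariates and, optionally, group and
#' group x distance interactions. Random effects start from a per-participant
#' intercept plus a random slope of the first distance term and are
#' simplified on singular fits (flagged in the result).
#'
#' @inheritParams select_functional_form
#' @param metric `"accuracy"` or `"confidence"`.
#' @param shift_type `"ID"` or `"ED"`.
#' @param form `"linear"`, `"quadratic"`, `"log"`, or `"auto"` (BIC
#'   selection via [select_functional_form()]).
#' @param with_group Include group main effect and group x distance terms.
#' @return An [`rs_model`][print.rs_model] object; `tidy()` and `glance()`
#'   methods are available.
#' @export
fit_recovery_model <- function(cohort, metric = c("accuracy", "confidence"),
                               shift_type = c("ID", "ED"), form = "auto",
                               with_group = FALSE, window = 5L) {
  metric <- match.arg(metric)
  shift_type <- match.arg(shift_type)
  if (identical(form, "auto")) {
    form <- select_functional_form(cohort, metric, shift_type,
                                   window = window)$choice
  }
  df <- post_shift_frame(cohort, shift_type, window)
  lhs <- if (metric == "accuracy") "outcome" else "confidence"
  dterms <- form_terms(form)
  first_term <- strsplit(dterms, " \\+ ")[[1]][1]

  fixed <- paste(lhs, "~", dterms, "+ z_age + gender + z_iq")
  if (with_group) {
    inter <- paste(paste0("group:", strsplit(dterms, " \\+ ")[[1]]),
                   collapse = " + ")
    fixed <- paste(fixed, "+ group +", inter)
  }
  ladder <- list(
    sprintf("(1 + %s | participant_id)", first_term),
    sprintf("(1 + %s || participant_id)", first_term),
    "(1 | participant_id)"
  )
  fit_mixed(fixed, ladder, df,
            family = if (metric == "accuracy") "binomial" else "gaussian")
}

#' Feedback-sensitivity model of confidence
#'
#' Linear mixed model predicting confidence at trial t from accuracy at
#' trial t-1 (lag computed within level; the first trial of each level has a
#' missing lag and is dropped), group and their interaction, with
#' demographic covariates, a random slope of lagged accuracy per participant
#' and a random intercept per task level.
#'
#' @param cohort An `rs_cohort`.
#' @param with_group Include group main effect and group x lagged-accuracy
#'   interaction (default `TRUE`).
#' @return An `rs_model`.
#' @export
fit_feedback_model <- function(cohort, with_group = TRUE) {
  df <- build_analysis_frame(cohort) |>
    dplyr::filter(!is.na(.data$prev_outcome))
  fixed <- if (with_group) {
    "confidence ~ prev_outcome * group + gender + z_age + z_iq"
  } else {
    "confidence ~ prev_outcome + gender + z_age + z_iq"
  }
  ladder <- list(
    "(1 + prev_outcome | participant_id) + (1 | level_f)",
    "(1 + prev_outcome || participant_id) + (1 | level_f)",
    "(1 | participant_id) + (1 | level_f)"
  )
  fit_mixed(fixed, ladder, df)
}

#' Normative confidence model: tracking of Bayes-optimal certainty
#'
#' Linear mixed model of confidence on the observer's General Certainty (GC)
#' and Choice Certainty (CC), both z-scored, with group, the GC x group and
#' CC x group interactions and demographic covariates (`spec = "joint"`), or
#' with the CC terms dropped (`spec = "gc_only"`). The pre-feedback traces
#' (`gc_pre`, `cc_pre`) are the default regressors, matching the timing of
#' the confidence report. Random effects: intercept and slope of the focal
#' certainty regressor per participant plus a level intercept, simplified on
#' singularity. Variance inflation factors are computed on the main-effects
#' fixed design (interaction columns of z-scored predictors are structurally
#' collinear and uninformative) and attached to the result.
#'
#' @param cohort An `rs_cohort`.
#' @param traces Trial log with observer trace columns, as returned by
#'   [run_observer()]; computed from `cohort$trials` if missing.
#' @param spec `"joint"` or `"gc_only"`.
#' @param timing `"pre"` (default; certainty aligned with the confidence
#'   report) or `"post"` (post-feedback traces).
#' @param vif Compute variance inflation factors (default `TRUE`).
#' @return An `rs_model` with a `vif` tibble.
#' @export
fit_normative_model <- function(cohort, traces = NULL,
                                spec = c("joint", "gc_only"),
                                timing = c("pre", "post"), vif = TRUE) {
  spec <- match.arg(spec)
  timing <- match.arg(timing)
  if (is.null(traces)) traces <- run_observer(cohort$trials)
  df <- build_analysis_frame(cohort, traces) |>
    dplyr::mutate(
      z_gc = zscore(.data[[paste0("gc_", timing)]]),
      z_cc = zscore(.data[[paste0("cc_", timing)]])
    )

  fixed <- if (spec == "joint") {
    "confidence ~ z_gc + z_cc + group + z_gc:group + z_cc:group + gender + z_age + z_iq"
  } else {
    "confidence ~ z_gc + group + z_gc:group + gender + z_age + z_iq"
  }
  slope <- if (spec == "joint") "z_cc" else "z_gc"
  ladder <- list(
    sprintf("(1 + %s | participant_id) + (1 | level_f)", slope),
    sprintf("(1 + %s || participant_id) + (1 | level_f)", slope),
    "(1 | participant_id) + (1 | level_f)"
  )
  res <- fit_mixed(fixed, ladder, df)
  if (vif) {
    main <- if (spec == "joint") {
      "confidence ~ z_gc + z_cc + group + gender + z_age + z_iq"
    } else {
      "confidence ~ z_gc + group + gender + z_age + z_iq"
    }
    res$vif <- compute_vif(as.formula(main), df)
    if (any(res$vif$vif >= 10)) {
      warn("A variance inflation factor is >= 10; fixed effects are strongly collinear.")
    }
  }
  res
}

# generalized VIF of each fixed-effect term, via car on an auxiliary lm
compute_vif <- function(formula, data) {
  aux <- lm(formula, data = data)
  v <- car::vif(aux)
  if (is.matrix(v)) {
    tibble(term = rownames(v), vif = v[, 1L],
           gvif_scaled = v[, "GVIF^(1/(2*Df))"])
  } else {
    tibble(term = names(v), vif = unname(v), gvif_scaled = sqrt(unname(v)))
  }
}
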