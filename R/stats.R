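iqr_keep <- function(x) {
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr
}

# Shapiro-Wilk normality gate at alpha = 0.05 (constant samples count as
# non-normal so the rank test is used)
is_normal <- function(x, alpha = 0.05) {
  if (length(unique(x)) < 3L || length(x) < 3L) return(FALSE)
  shapiro.test(x)$p.value > alpha
}

#' Post-feedback confidence-change tests
#'
#' Computes, per participant and within level, the trial-to-trial confidence
#' change following correct and following incorrect trials, averages it per
#' participant, removes participant-level outliers by the 1.5 x IQR rule
#' (within group x condition), and then tests (a) within each group whether
#' the mean change differs from zero and (b) between groups whether the
#' changes differ. Parametric tests (one-sample / two-sample t-test) are
#' replaced by Wilcoxon signed-rank / rank-sum tests when Shapiro-Wilk
#' indicates non-normality (or Levene indicates variance heterogeneity for
#' the between-group comparison). Bonferroni correction is applied within
#' two families: the four within-group tests, and the two between-group
#' comparisons.
#'
#' @param cohort An `rs_cohort`.
#' @param aggregate `"participant"` (default; test participant-level means)
#'   or `"trial"` (pool trials, within-group tests only become one-sample
#'   tests on trials).
#' @return A tibble with one row per test: `family`, `group`, `condition`,
#'   `n`, `method`, `statistic`, `p_value`, `p_adj`, `mean_change`.
#' @export
feedback_change_tests <- function(cohort,
                                  aggregate = c("participant", "trial")) {
  aggregate <- match.arg(aggregate)
  if (any(table(cohort$demographics$group) < 3L)) {
    abort("Each group needs at least 3 participants.")
  }
  deltas <- cohort$trials |>
    dplyr::group_by(.data$participant_id, .data$level) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(
      d_conf = .data$confidence - dplyr::lag(.data$confidence),
      prev_outcome = dplyr::lag(.data$outcome)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$d_conf)) |>
    dplyr::mutate(condition = ifelse(.data$prev_outcome == 1,
                                     "post-correct", "post-incorrect"))

  per_part <- deltas |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(d_conf = mean(.data$d_conf), .groups = "drop") |>
    dplyr::left_join(
      dplyr::select(cohort$demographics, "participant_id", "group"),
      by = "participant_id"
    )

  samples <- if (aggregate == "participant") per_part else
    dplyr::left_join(
      dplyr::select(deltas, "participant_id", "condition", "d_conf"),
      dplyr::select(cohort$demographics, "participant_id", "group"),
      by = "participant_id"
    )

  samples <- samples |>
    dplyr::group_by(.data$group, .data$condition) |>
    dplyr::filter(iqr_keep(.data$d_conf)) |>
    dplyr::ungroup()

  within_rows <- samples |>
    dplyr::group_by(.data$group, .data$condition) |>
    dplyr::group_map(function(df, key) {
      x <- df$d_conf
      if (is_normal(x)) {
        tt <- t.test(x)
        tibble(family = "within-group", group = as.character(key$group),
               condition = key$condition, n = length(x),
               method = "one-sample t-test", statistic = unname(tt$statistic),
               p_value = tt$p.value, mean_change = mean(x))
      } else {
        wt <- suppressWarnings(wilcox.test(x))
        tibble(family = "within-group", group = as.character(key$group),
               condition = key$condition, n = length(x),
               method = "Wilcoxon signed-rank", statistic = unname(wt$statistic),
               p_value = wt$p.value, mean_change = mean(x))
      }
    }) |> dplyr::bind_rows()
  within_rows$p_adj <- pmin(1, within_rows$p_value * nrow(within_rows))

  between_rows <- purrr::map(unique(samples$condition), function(cond) {
    df <- dplyr::filter(samples, .data$condition == cond)
    x <- df$d_conf[df$group == "OCD"]
    y <- df$d_conf[df$group != "OCD"]
    lev_p <- car::leveneTest(d_conf ~ factor(group), data = df)[1, "Pr(>F)"]
    if (is_normal(x) && is_normal(y) && lev_p > 0.05) {
      tt <- t.test(x, y, var.equal = TRUE)
      tibble(family = "between-group", group = "OCD vs control",
             condition = cond, n = nrow(df), method = "two-sample t-test",
             statistic = unname(tt$statistic), p_value = tt$p.value,
             mean_change = mean(x) - mean(y))
    } else {
      wt <- suppressWarnings(wilcox.test(x, y))
      tibble(family = "between-group", group = "OCD vs control",
             condition = cond, n = nrow(df), method = "Wilcoxon rank-sum",
             statistic = unname(wt$statistic), p_value = wt$p.value,
             mean_change = mean(x) - mean(y))
    }
  }) |> dplyr::bind_rows()
  between_rows$p_adj <- pmin(1, between_rows$p_value * nrow(between_rows))

  dplyr::bind_rows(within_rows, between_rows)
}

#' Within-participant correlation of General and Choice Certainty
#'
#' Spearman rank correlation of the two observer traces per participant;
#' participants with a constant trace (undefined correlation) are excluded
#' and flagged.
#'
#' @param traces Trial log with `gc_pre`/`cc_pre` columns
#'   (see [run_observer()]).
#' @param timing `"pre"` or `"post"` traces.
#' @return A list with `mean`, `sd`, `n`, and `by_participant` (tibble with
#'   `participant_id`, `rho`, `excluded`).
#' @export
within_subject_correlation <- function(traces, timing = c("pre", "post")) {
  timing <- match.arg(timing)
  gc_col <- paste0("gc_", timing)
  cc_col <- paste0("cc_", timing)
  by_part <- traces |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      constant = sd(.data[[gc_col]]) == 0 || sd(.data[[cc_col]]) == 0,
      rho = if (constant[1L] || n_trials[1L] < 10L) NA_real_ else
        suppressWarnings(cor(.data[[gc_col]], .data[[cc_col]],
                             method = "spearman")),
      .groups = "drop"
    ) |>
    dplyr::mutate(excluded = is.na(.data$rho))
  ok <- by_part$rho[!by_part$excluded]
  list(mean = mean(ok), sd = sd(ok), n = length(ok),
       by_participant = dplyr::select(by_part, "participant_id", "rho",
                                      "excluded"))
}

#' Mixed-design repeated-measures ANOVA on per-level means
#'
#' Group (between-subject) x difficulty level (within-subject) ANOVA on the
#' per-participant x level mean of accuracy or confidence, fitted with
#' `stats::aov` and an `Error(participant/level)` stratum.
#'
#' @param cohort An `rs_cohort`.
#' @param metric `"accuracy"` or `"confidence"`.
#' @return A tibble with `effect`, `df1`, `df2`, `statistic` (F) and
#'   `p_value` for the group, level and group x level effects.
#' @export
rm_anova <- function(cohort, metric = c("accuracy", "confidence")) {
  metric <- match.arg(metric)
  cell <- cohort$trials |>
    dplyr::group_by(.data$participant_id, .data$level) |>
    dplyr::summarise(
      value = if (metric == "accuracy") mean(.data$outcome) else
        mean(.data$confidence),
      .groups = "drop"
    )
  n_lev <- length(unique(cell$level))
  counts <- table(cell$participant_id)
  if (any(counts < n_lev)) {
    abort("Every participant must contribute all levels to the ANOVA.")
  }
  df <- cell |>
    dplyr::left_join(
      dplyr::select(cohort$demographics, "participant_id", "group"),
      by = "participant_id"
    ) |>
    dplyr::mutate(
      pid = factor(.data$participant_id),
      level_f = factor(.data$level),
      group = factor(.data$group, levels = c("control", "OCD"))
    )
  fit <- aov(value ~ group * level_f + Error(pid / level_f), data = df)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: pid"]][[1]])
  within <- as.data.frame(sm[["Error: pid:level_f"]][[1]])
  pick <- function(tab, name, label) {
    i <- which(trimws(rownames(tab)) == name)
    resid <- which(trimws(rownames(tab)) == "Residuals")
    tibble(effect = label, df1 = tab$Df[i], df2 = tab$Df[resid],
           statistic = tab$`F value`[i], p_value = tab$`Pr(>F)`[i])
  }
  dplyr::bind_rows(
    pick(between, "group", "group"),
    pick(within, "level_f", "level"),
    pick(within, "group:level_f", "group:level")
  )
}
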