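test_that("confidence-change tests report calibrated Bonferroni families", {
  res <- feedback_change_tests(default_cohort())
  within <- res[res$family == "within-group", ]
  between <- res[res$family == "between-group", ]
  expect_equal(nrow(within), 4L)
  expect_equal(nrow(between), 2L)
  # Bonferroni: adjusted p = min(1, m * p) with m the family size
  expect_equal(within$p_adj, pmin(1, within$p_value * 4))
  expect_equal(between$p_adj, pmin(1, between$p_value * 2))
  # signs: confidence rises after correct, falls after errors, in both groups
  # (the post-feedback change is dominated by the General-Certainty reset
  # dynamics, which both groups weight equally, so no group contrast is
  # asserted here; the group difference in feedback coupling surfaces in the
  # lagged-accuracy x group interaction of the feedback model instead)
  expect_true(all(within$mean_change[within$condition == "post-correct"] > 0))
  expect_true(all(within$mean_change[within$condition == "post-incorrect"] < 0))
  expect_true(all(within$p_adj[within$condition == "post-correct"] < 0.05))
})

test_that("feedback-blind confidence produces near-zero changes", {
  sp <- default_group_specs(n = 6L)
  flat <- agent_params(w_cc = 0, w_gc = 0)
  sp$ocd$param_means <- flat
  sp$control$param_means <- flat
  sp$ocd$param_sds$w_cc <- 0; sp$ocd$param_sds$w_gc <- 0
  sp$control$param_sds$w_cc <- 0; sp$control$param_sds$w_gc <- 0
  co <- suppressWarnings(simulate_cohort(sp$ocd, sp$control, seed = 91))
  res <- feedback_change_tests(co)
  expect_true(all(abs(res$mean_change[res$family == "within-group"]) < 2))
  expect_error(
    feedback_change_tests(list(trials = co$trials,
                               demographics = co$demographics[1:8, ])),
    "at least 3"
  )
})

test_that("within-subject GC-CC correlations behave at the boundaries", {
  mk_traces <- function(vals_by_part) {
    dplyr::bind_rows(lapply(names(vals_by_part), function(id) {
      v <- vals_by_part[[id]]
      tibble::tibble(participant_id = id, gc_pre = v$gc, cc_pre = v$cc)
    }))
  }
  x <- withr::with_seed(5, runif(50, 0, 100))
  y <- withr::with_seed(6, runif(50, 0, 100))
  res1 <- within_subject_correlation(mk_traces(list(
    a = list(gc = x, cc = x), b = list(gc = y, cc = y)
  )))
  expect_equal(res1$mean, 1)
  expect_equal(res1$sd, 0)

  res2 <- within_subject_correlation(mk_traces(list(
    a = list(gc = x, cc = y)
  )))
  expect_lt(abs(res2$mean), 0.3)

  res3 <- within_subject_correlation(mk_traces(list(
    a = list(gc = x, cc = x), b = list(gc = rep(1, 50), cc = y)
  )))
  expect_equal(res3$n, 1L)
  expect_true(res3$by_participant$excluded[res3$by_participant$participant_id == "b"])

  # competent synthetic agents: positive on average
  res4 <- within_subject_correlation(default_traces())
  expect_gt(res4$mean, 0)
  expect_equal(res4$n, 58L)
})

test_that("the mixed-design ANOVA matches a hand-computed decomposition", {
  # tiny balanced design: 2 groups x 2 participants x 3 levels
  vals <- c(70, 65, 55,   74, 67, 57,    # controls
            60, 52, 40,   58, 54, 44)    # patients
  trials <- tibble::tibble(
    participant_id = rep(c("c1", "c2", "o1", "o2"), each = 3),
    level = rep(1:3, 4),
    outcome = 1L,
    confidence = vals
  )
  demo <- tibble::tibble(
    participant_id = c("c1", "c2", "o1", "o2"),
    group = c("control", "control", "OCD", "OCD")
  )
  res <- rm_anova(list(trials = trials, demographics = demo), "confidence")

  # independent textbook computation of the mixed-design sums of squares
  m <- matrix(vals, nrow = 4, byrow = TRUE)
  grand <- mean(m)
  n_g <- 2; n_p <- 2; n_l <- 3
  part_means <- rowMeans(m)
  group_means <- c(mean(m[1:2, ]), mean(m[3:4, ]))
  level_means <- colMeans(m)
  cell_means <- rbind(colMeans(m[1:2, ]), colMeans(m[3:4, ]))
  ss_group <- n_p * n_l * sum((group_means - grand)^2)
  ss_subj_within <- n_l * sum((part_means - rep(group_means, each = n_p))^2)
  ss_level <- n_g * n_p * sum((level_means - grand)^2)
  ss_inter <- n_p * sum((cell_means - outer(group_means, rep(1, n_l)) -
                           outer(rep(1, n_g), level_means) + grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_group - ss_subj_within - ss_level - ss_inter
  df_group <- n_g - 1; df_sw <- n_g * (n_p - 1)
  df_level <- n_l - 1; df_int <- df_group * df_level
  df_err <- df_sw * df_level
  f_group <- (ss_group / df_group) / (ss_subj_within / df_sw)
  f_level <- (ss_level / df_level) / (ss_err / df_err)
  f_int <- (ss_inter / df_int) / (ss_err / df_err)

  expect_equal(res$statistic, c(f_group, f_level, f_int))
  expect_equal(res$df1, c(df_group, df_level, df_int))
  expect_equal(res$df2, c(df_sw, df_err, df_err))
  expect_equal(res$effect, c("group", "level", "group:level"))

  expect_error(rm_anova(list(trials = trials[-1, ], demographics = demo),
                        "confidence"), "all levels")
})

test_that("level difficulty drives the accuracy ANOVA in synthetic cohorts", {
  res <- rm_anova(default_cohort(), "accuracy")
  lev <- res[res$effect == "level", ]
  expect_lt(lev$p_value, 0.001)
  expect_equal(lev$df1, 2)
  expect_equal(lev$df2, 2 * (58 - 2))
  grp <- res[res$effect == "group", ]
  expect_gt(grp$p_value, 0.05)
  # confidence: strong group effect by construction
  resc <- rm_anova(default_cohort(), "confidence")
  expect_lt(resc$p_value[resc$effect == "group"], 0.01)
})
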