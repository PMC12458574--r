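test_that("default level design has its documented trial structure", {
  levels <- make_default_levels()
  nt <- vapply(levels, function(l) l$n_blocks * l$trials_per_block, 0L)
  expect_equal(nt, c(60L, 70L, 70L))
  expect_equal(sum(nt), 200L)
  expect_equal(vapply(levels, function(l) l$n_stimuli, 0L), c(2L, 2L, 3L))
  expect_equal(vapply(levels, function(l) length(l$dimensions), 0L),
               c(2L, 3L, 3L))
  expect_equal(levels[[1]]$n_blocks, 2L)
  expect_equal(levels[[1]]$trials_per_block, 30L)
})

test_that("level validation rejects malformed designs", {
  expect_error(
    level_spec(1, 2, list(a = c("x", "y"), b = c("x", "z")), 1, 10),
    "unique"
  )
  expect_error(
    level_spec(1, 3, list(a = c("x", "y"), b = c("p", "q", "r")), 1, 10),
    "exactly"
  )
})

test_that("shift schedules respect the 6-11 trial gap bounds", {
  level1 <- make_default_levels()[[1]]
  all_gaps <- unlist(lapply(1:1000, function(s) {
    sched <- sample_shift_schedule(level1, seed = s)
    diff(c(0L, sched$trial))
  }))
  expect_true(all(all_gaps >= 6 & all_gaps <= 11))
  # exhaustive sampling reaches both bounds
  expect_equal(min(all_gaps), 6L)
  expect_equal(max(all_gaps), 11L)
  # no shift on the first trial of a level
  firsts <- vapply(1:200, function(s) {
    sample_shift_schedule(level1, seed = s)$trial[1]
  }, 0L)
  expect_true(all(firsts >= 6L))
})

test_that("empirical gap distribution is uniform on 6..11", {
  level1 <- make_default_levels()[[1]]
  gaps <- unlist(lapply(1:2000, function(s) {
    diff(c(0L, sample_shift_schedule(level1, seed = s)$trial))
  }))
  tab <- table(factor(gaps, levels = 6:11))
  p <- chisq.test(tab)$p.value
  expect_gt(p, 1e-4)
})

test_that("a 12-trial level holds exactly one shift and invalid seeds error", {
  lev <- level_spec(1, 2, list(colour = c("orange", "blue"),
                               shape = c("round", "star")),
                    n_blocks = 1, trials_per_block = 12)
  for (s in 1:50) {
    expect_equal(nrow(sample_shift_schedule(lev, seed = s)), 1L)
  }
  expect_error(sample_shift_schedule(lev, seed = "a"), "integer")
  expect_error(sample_shift_schedule(lev, seed = c(1, 2)), "integer")
})

test_that("both shift types occur in every block with enough shifts", {
  for (lev in make_default_levels()) {
    for (s in 1:100) {
      sched <- sample_shift_schedule(lev, seed = s)
      blocks <- sched$trial %/% lev$trials_per_block
      for (b in unique(blocks)) {
        tb <- sched$shift_type[blocks == b]
        if (length(tb) >= 2) expect_setequal(unique(tb), c("ID", "ED"))
      }
      # ID keeps the dimension, ED changes it
      expect_true(all((sched$shift_type == "ID") ==
                        (sched$old_dim == sched$new_dim)))
      expect_true(all(sched$old_dim != sched$new_dim |
                        sched$old_feature != sched$new_feature))
    }
  }
})

test_that("trial layouts partition all features across stimuli", {
  for (lev in make_default_levels()) {
    feats <- sort(unlist(lev$dimensions, use.names = FALSE))
    for (s in 1:50) {
      disp <- sample_trial_layout(lev, seed = s)
      expect_equal(dim(disp), c(length(lev$dimensions), lev$n_stimuli))
      # every feature appears exactly once; each stimulus has one per dim
      expect_equal(sort(as.vector(disp)), feats)
      expect_true(all(apply(disp, 1, anyDuplicated) == 0))
    }
  }
  expect_identical(sample_trial_layout(make_default_levels()[[1]], seed = 7),
                   sample_trial_layout(make_default_levels()[[1]], seed = 7))
})

test_that("exactly one stimulus yields reward for any rule on display", {
  lev <- make_default_levels()[[3]]
  for (s in 1:20) {
    disp <- sample_trial_layout(lev, seed = s)
    for (d in names(lev$dimensions)) {
      for (f in lev$dimensions[[d]]) {
        rule <- list(dimension = d, feature = f)
        hits <- vapply(seq_len(ncol(disp)), function(j)
          evaluate_choice(disp, j, rule), 0L)
        expect_equal(sum(hits), 1L)
      }
    }
  }
  expect_error(evaluate_choice(disp, 4, rule), "index")
  expect_error(evaluate_choice(disp, 0, rule), "index")
})

test_that("run_level produces consistent, reproducible trial records", {
  lev <- make_default_levels()[[1]]
  log <- run_level(lev, policy_random(), seed = 5)
  expect_equal(nrow(log), 60L)
  expect_identical(log, run_level(lev, policy_random(), seed = 5))
  expect_equal(unique(log$block), c(0L, 1L))

  # outcomes agree with re-evaluating the choice against the logged rule
  displays <- parse_log_displays(log)
  re_eval <- vapply(seq_len(nrow(log)), function(t) {
    evaluate_choice(displays[[t]], log$choice[t],
                    list(dimension = log$rule_dim[t],
                         feature = log$rule_feature[t]))
  }, 0L)
  expect_equal(log$outcome, re_eval)

  # an always-pick-first policy scores exactly when stimulus 1 holds the target
  log1 <- run_level(lev, function(display, history) 1L, seed = 6)
  holds <- vapply(seq_len(nrow(log1)), function(t) {
    as.integer(log1$rule_feature[t] %in% strsplit(log1$stim1[t], ";")[[1]])
  }, 0L)
  expect_equal(log1$outcome, holds)

  expect_error(run_level(lev, function(display, history) 99L, seed = 1),
               "invalid")
})

test_that("a random policy scores at one over the number of stimuli", {
  for (lev in make_default_levels()) {
    n_runs <- ceiling(2000 / (lev$n_blocks * lev$trials_per_block))
    accs <- unlist(lapply(seq_len(n_runs), function(s) {
      run_level(lev, policy_random(), seed = 7000 + s)$outcome
    }))
    p <- 1 / lev$n_stimuli
    se <- sqrt(p * (1 - p) / length(accs))
    expect_lt(abs(mean(accs) - p), 3 * se)
  }
})

test_that("run_task covers all levels for one participant", {
  log <- run_task(policy = policy_random(), seed = 3, participant_id = "x")
  expect_equal(nrow(log), 200L)
  expect_equal(unique(log$level), c(1L, 2L, 3L))
  expect_true(all(is.na(log$stim3[log$level < 3])))
  expect_true(all(!is.na(log$stim3[log$level == 3])))
})
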