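test_that("beliefs initialise flat and validate their inputs", {
  b4 <- init_beliefs(c("A", "B", "C", "D"))
  expect_equal(unname(unclass(b4)), rep(0.25, 4))
  b2 <- init_beliefs(c("A", "B"))
  expect_equal(unname(unclass(b2)), c(0.5, 0.5))
  expect_equal(posterior_entropy(init_beliefs(letters[1:6])), log2(6))
  expect_error(init_beliefs(c("A", "A", "B")), "unique")
  expect_error(init_beliefs("A"), "at least 2")
})

test_that("entropy follows the 0 log 0 convention", {
  expect_equal(posterior_entropy(init_beliefs(c("A", "B", "C", "D"))), 2)
  point <- structure(c(A = 1, B = 0, C = 0, D = 0), class = "rs_belief")
  expect_equal(posterior_entropy(point), 0)
  half <- structure(c(A = 0.5, B = 0.5, C = 0, D = 0), class = "rs_belief")
  expect_equal(posterior_entropy(half), 1)
})

test_that("general certainty maps entropy onto the 0-100 scale", {
  uniform <- init_beliefs(c("A", "B", "C", "D"))
  point <- structure(c(A = 1, B = 0, C = 0, D = 0), class = "rs_belief")
  half <- structure(c(A = 0.5, B = 0.5, C = 0, D = 0), class = "rs_belief")
  expect_equal(general_certainty(uniform), 0)
  expect_equal(general_certainty(point), 100)
  expect_equal(general_certainty(half), 50)
  # strictly decreasing in entropy
  mixtures <- lapply(seq(0, 1, by = 0.1), function(a) {
    p <- (1 - a) * c(1, 0, 0, 0) + a * rep(0.25, 4)
    structure(setNames(p, c("A", "B", "C", "D")), class = "rs_belief")
  })
  gc <- vapply(mixtures, general_certainty, 0)
  s <- vapply(mixtures, posterior_entropy, 0)
  expect_true(all(diff(s) > 0))
  expect_true(all(diff(gc) < 0))
  # the printed variant is only kept for sensitivity analysis
  expect_equal(general_certainty(half, variant = "printed"), 100)
  expect_error(general_certainty(structure(c(A = 1), class = "rs_belief")),
               "at least 2")
})

test_that("feedback likelihood spreads evidence over the correct feature sets", {
  disp2 <- mk_display(c("A", "C"), c("B", "D"))
  expect_equal(outcome_likelihood("A", 1, disp2, 1), 1 / 2)
  expect_equal(outcome_likelihood("C", 1, disp2, 1), 1 / 2)
  expect_equal(outcome_likelihood("B", 1, disp2, 1), 0)
  expect_equal(outcome_likelihood("A", 0, disp2, 1), 0)
  expect_equal(outcome_likelihood("B", 0, disp2, 1), 1 / 2)

  # three stimuli x two differing dimensions: four pooled unchosen features
  disp3 <- mk_display(c("A", "D"), c("B", "E"), c("C", "F"))
  expect_equal(outcome_likelihood("B", 0, disp3, 1), 1 / 4)
  expect_equal(outcome_likelihood("F", 0, disp3, 1), 1 / 4)
  expect_equal(outcome_likelihood("B", 1, disp3, 1), 0)
  expect_equal(outcome_likelihood("A", 1, disp3, 1), 1 / 2)
  expect_error(outcome_likelihood("Z", 1, disp2, 1), "not on the display")
})

test_that("belief updates implement Bayes rule with the reset guard", {
  disp <- mk_display(c("A", "C"), c("B", "D"))
  uniform <- init_beliefs(c("A", "B", "C", "D"))

  up <- update_beliefs(uniform, disp, choice = 1, outcome = 1)
  expect_false(up$reset)
  expect_equal(unclass(up$belief)[c("A", "C", "B", "D")],
               c(A = 0.5, C = 0.5, B = 0, D = 0))

  point <- structure(c(A = 1, B = 0, C = 0, D = 0), class = "rs_belief")
  up2 <- update_beliefs(point, disp, choice = 1, outcome = 0)
  expect_true(up2$reset)
  expect_equal(unname(unclass(up2$belief)), rep(0.25, 4))

  # rewarded feedback with belief already confined to the chosen stimulus
  conf <- structure(c(A = 0.7, C = 0.3, B = 0, D = 0), class = "rs_belief")
  up3 <- update_beliefs(conf, disp, choice = 1, outcome = 1)
  expect_false(up3$reset)
  expect_equal(unclass(up3$belief)[c("A", "C")], c(A = 0.7, C = 0.3))

  other <- init_beliefs(c("X", "Y"))
  expect_error(update_beliefs(other, disp, 1, 1), "feature set")
})

test_that("choice certainty sums the chosen stimulus's posterior mass", {
  disp <- mk_display(c("A", "C"), c("B", "D"))
  uniform <- init_beliefs(c("A", "B", "C", "D"))
  expect_equal(choice_certainty(uniform, disp, 1), 50)
  point <- structure(c(A = 1, B = 0, C = 0, D = 0), class = "rs_belief")
  expect_equal(choice_certainty(point, disp, 1), 100)
  expect_equal(choice_certainty(point, disp, 2), 0)
  # partition invariant: certainties across stimuli sum to 100
  disp3 <- mk_display(c("A", "D"), c("B", "E"), c("C", "F"))
  b <- init_beliefs(LETTERS[1:6])
  for (s in 1:20) {
    withr::with_seed(s, {
      w <- runif(6)
      b2 <- structure(setNames(w / sum(w), LETTERS[1:6]), class = "rs_belief")
    })
    total <- sum(vapply(1:3, function(j) choice_certainty(b2, disp3, j), 0))
    expect_equal(total, 100)
  }
})

test_that("observer traces start flat per level and align pre/post values", {
  log <- run_task(policy = policy_random(), seed = 21)
  tr <- run_observer(log)
  first <- tr[tr$trial == 0, ]
  expect_equal(first$gc_pre, rep(0, 3))
  # cc_pre of trial 0 is chosen-set size over N
  expect_equal(first$cc_pre[first$level == 1], 100 * 2 / 4)
  expect_equal(first$cc_pre[first$level == 3], 100 * 3 / 9)
  # the report-aligned trace at t equals the post-feedback trace at t-1
  for (lv in 1:3) {
    ch <- tr[tr$level == lv, ]
    expect_equal(ch$gc_pre[-1], ch$gc_post[-nrow(ch)])
  }
  # reset trials carry an exactly uniform posterior
  n_feat <- c(`1` = 4, `2` = 6, `3` = 9)
  rs <- tr[tr$reset, ]
  expect_true(nrow(rs) > 0)
  expect_equal(rs$gc_post, rep(0, nrow(rs)))
  expect_equal(rs$entropy_bits, log2(n_feat[as.character(rs$level)]),
               ignore_attr = TRUE)
})

test_that("an informative run converges to a point mass on the true feature", {
  lev <- mini_level(2L, 30L)
  sched <- sample_shift_schedule(lev, seed = 1)[0, ]  # no shifts
  attr(sched, "initial_rule") <- list(dimension = "colour", feature = "blue")
  log <- run_level(lev, policy_random(), seed = 4, schedule = sched)
  tr <- run_observer(log)
  expect_equal(tr$gc_post[nrow(tr)], 100)
  expect_equal(tr$entropy_bits[nrow(tr)], 0)
  expect_false(any(tr$reset))
  # once converged, the chosen-or-not certainty tracks the true feature
  last <- nrow(tr)
  has_true <- "blue" %in% strsplit(log$stim1[last], ";")[[1]]
  expect_equal(tr$cc_post[last], if (log$choice[last] == 1) {
    if (has_true) 100 else 0
  } else {
    if (has_true) 0 else 100
  })
})

test_that("posterior support matches the consistent-hypothesis oracle", {
  for (s in 1:40) {
    lev <- mini_level(if (s %% 2) 2L else 3L, 20L)
    log <- run_level(lev, policy_random(), seed = 9000 + s)
    displays <- parse_log_displays(log)
    feats <- sort(unique(as.vector(displays[[1]])))
    oracle <- oracle_trajectory(displays, log$choice, log$outcome, feats)

    belief <- init_beliefs(feats)
    for (t in seq_len(nrow(log))) {
      up <- update_beliefs(belief, displays[[t]], log$choice[t], log$outcome[t])
      belief <- up$belief
      expect_equal(up$reset, oracle$resets[t])
      p <- unclass(belief)
      expect_setequal(names(p)[p > 0], oracle$supports[[t]])
      expect_lt(max(abs(p[feats] - oracle$posteriors[[t]][feats])), 1e-10)
    }
  }
})

test_that("equal-set levels keep the posterior uniform on its support", {
  # chosen and pooled-unchosen feature counts match at two-stimulus levels,
  # so likelihood weights cancel and the posterior is flat on its support
  for (s in 1:10) {
    lev <- mini_level(2L, 20L)
    log <- run_level(lev, policy_random(), seed = 500 + s)
    displays <- parse_log_displays(log)
    feats <- sort(unique(as.vector(displays[[1]])))
    belief <- init_beliefs(feats)
    for (t in seq_len(nrow(log))) {
      belief <- update_beliefs(belief, displays[[t]], log$choice[t],
                               log$outcome[t])$belief
      p <- unclass(belief)
      on <- p[p > 0]
      expect_equal(unname(on), rep(1 / length(on), length(on)))
    }
  }
})

test_that("general and choice certainty correlate for a competent agent", {
  log <- suppressWarnings(simulate_participant(seed = 77))
  tr <- run_observer(log)
  r <- suppressWarnings(cor(tr$gc_pre, tr$cc_pre, method = "spearman"))
  expect_gt(r, 0)
})
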