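#' Generative parameters of a synthetic participant
#'
#' A synthetic participant chooses by softmax over the per-stimulus Choice
#' Certainty of its own Bayes-optimal belief (with a lapse mixture) and
#' reports confidence as a noisy linear read-out of its normative certainty:
#' `confidence = clip(b + w_cc * z(CC) + w_gc * z(GC) + noise, 1, 100)`,
#' with CC/GC standardised within participant.
#'
#' @param inv_temp Softmax inverse temperature per Choice-Certainty unit
#'   (0-100 scale); 0 = random choice.
#' @param lapse Probability of a uniformly random choice.
#' @param conf_intercept Baseline confidence `b`, slider units.
#' @param w_cc,w_gc Confidence read-out weights, slider units per SD of
#'   Choice/General Certainty.
#' @param conf_noise_sd Trial-level confidence noise SD, slider units.
#' @param rt_mu,rt_sigma Lognormal reaction-time parameters (log seconds).
#' @return An `rs_agent_params` list.
#' @export
agent_params <- function(inv_temp = 0.12, lapse = 0.05, conf_intercept = 69,
                         w_cc = 7, w_gc = 3, conf_noise_sd = 10,
                         rt_mu = 0.7, rt_sigma = 0.35) {
  p <- list(
    inv_temp = inv_temp, lapse = lapse, conf_intercept = conf_intercept,
    w_cc = w_cc, w_gc = w_gc, conf_noise_sd = conf_noise_sd,
    rt_mu = rt_mu, rt_sigma = rt_sigma
  )
  if (p$lapse < 0 || p$lapse > 1) abort("`lapse` must be in [0, 1].")
  if (p$conf_noise_sd <= 0) abort("`conf_noise_sd` must be positive.")
  if (p$inv_temp < 0) abort("`inv_temp` must be nonnegative.")
  structure(p, class = "rs_agent_params")
}

#' Specification of a simulated participant group
#'
#' Participant-level generative parameters are drawn from independent
#' normals (truncated into their valid ranges) around the group means.
#' Gender is coded as in the study data: 1 = female, 2 = male,
#' 0 = non-binary/other.
#'
#' @param label Group label, `"OCD"` or `"control"`.
#' @param n Number of participants (>= 2).
#' @param param_means An [agent_params()] object of group means.
#' @param param_sds Named list of between-participant SDs for any subset of
#'   the parameter fields (unlisted fields get SD 0).
#' @param age_mean,age_sd Age distribution (years, truncated to 18-55).
#' @param gender_probs Probabilities of gender codes 1, 2, 0.
#' @param iq_mean,iq_sd IQ-proxy (cognitive test sum score) distribution.
#' @return An `rs_group_spec` list.
#' @export
group_spec <- function(label, n = 29L, param_means = agent_params(),
                       param_sds = list(conf_intercept = 8, w_cc = 2,
                                        w_gc = 1.5, conf_noise_sd = 2,
                                        inv_temp = 0.02, lapse = 0.02),
                       age_mean = 31, age_sd = 11,
                       gender_probs = c(female = 0.475, male = 0.475,
                                        nonbinary = 0.05),
                       iq_mean = 40, iq_sd = 8) {
  if (n < 2L) abort("`n` must be at least 2.")
  structure(
    list(label = label, n = as.integer(n), param_means = param_means,
         param_sds = param_sds, age_mean = age_mean, age_sd = age_sd,
         gender_probs = gender_probs / sum(gender_probs),
         iq_mean = iq_mean, iq_sd = iq_sd),
    class = "rs_group_spec"
  )
}

#' Default OCD and control group presets
#'
#' Both groups share choice parameters (so accuracy is matched by
#' construction); the OCD group's confidence intercept is shifted by
#' `delta_b` slider units (default -12, a stable negative metacognitive
#' bias) and its Choice-Certainty read-out weight by `delta_w` (default +3,
#' stronger coupling of confidence to choice-specific evidence).
#'
#' @param delta_b OCD-minus-control confidence intercept difference.
#' @param delta_w OCD-minus-control Choice-Certainty weight difference.
#' @param n Participants per group.
#' @return A list with elements `control` and `ocd` ([group_spec()]s).
#' @export
default_group_specs <- function(delta_b = -12, delta_w = 3, n = 29L) {
  ctrl <- group_spec("control", n = n)
  ocd_means <- agent_params(
    conf_intercept = ctrl$param_means$conf_intercept + delta_b,
    w_cc = ctrl$param_means$w_cc + delta_w
  )
  ocd <- group_spec("OCD", n = n, param_means = ocd_means)
  list(control = ctrl, ocd = ocd)
}

draw_agent_params <- function(spec) {
  m <- spec$param_means
  s <- spec$param_sds
  draw <- function(field, lo = -Inf, hi = Inf) {
    sd <- s[[field]] %||% 0
    min(max(m[[field]] + rnorm(1L, 0, sd), lo), hi)
  }
  agent_params(
    inv_temp = draw("inv_temp", lo = 0),
    lapse = draw("lapse", lo = 0, hi = 1),
    conf_intercept = draw("conf_intercept"),
    w_cc = draw("w_cc"),
    w_gc = draw("w_gc"),
    conf_noise_sd = max(draw("conf_noise_sd"), 0.5),
    rt_mu = draw("rt_mu"),
    rt_sigma = max(draw("rt_sigma"), 0.05)
  )
}

# all permutations of 1..k, as a list of integer vectors
perm_table <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- perm_table(k - 1L)
  out <- list()
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- c(out, lapply(sub, function(p) c(i, rest[p])))
  }
  out
}

# fast inner simulation of one level: belief updates, softmax choices and
# normative traces in feature-index space (labels only materialised at the end)
simulate_level_agent <- function(level, params) {
  schedule <- sample_shift_schedule(level)
  nt <- n_trials(level)
  rules <- rule_sequence(schedule, nt)
  dims <- level$dimensions
  labels <- unlist(dims, use.names = FALSE)
  nfeat <- length(labels)
  ndim <- length(dims)
  k <- level$n_stimuli
  offset <- cumsum(c(0L, lengths(dims)))[seq_len(ndim)]
  rule_idx <- match(rules$feature, labels)
  max_s <- log2(nfeat)

  shift_flag <- logical(nt)
  shift_type <- rep("none", nt)
  if (nrow(schedule)) {
    shift_flag[schedule$trial + 1L] <- TRUE
    shift_type[schedule$trial + 1L] <- schedule$shift_type
  }

  # pre-draw one feature permutation per dimension and trial
  perms <- perm_table(k)
  perm_idx <- matrix(sample.int(length(perms), nt * ndim, replace = TRUE),
                     nrow = nt, ncol = ndim)
  lapse_draw <- runif(nt) < params$lapse
  lapse_pick <- sample.int(k, nt, replace = TRUE)
  soft_u <- runif(nt)

  prior <- rep(1 / nfeat, nfeat)
  choices <- integer(nt)
  outcomes <- integer(nt)
  gc_pre <- cc_pre <- numeric(nt)
  layout <- matrix(0L, nrow = ndim, ncol = k)
  uniform <- prior
  beta <- params$inv_temp

  for (t in seq_len(nt)) {
    for (d in seq_len(ndim)) layout[d, ] <- offset[d] + perms[[perm_idx[t, d]]]
    # per-stimulus choice certainty under the current (pre-feedback) belief
    cc_stim <- numeric(k)
    for (j in seq_len(k)) cc_stim[j] <- 100 * sum(prior[layout[, j]])
    if (lapse_draw[t] || beta == 0) {
      ch <- lapse_pick[t]
    } else {
      w <- exp(beta * (cc_stim - max(cc_stim)))
      cw <- cumsum(w)
      ch <- which(cw >= soft_u[t] * cw[k])[1L]
    }
    chosen <- layout[, ch]
    out <- as.integer(rule_idx[t] %in% chosen)

    p <- prior[prior > 0]
    gc_pre[t] <- 100 * (max_s + sum(p * log2(p))) / max_s
    cc_pre[t] <- cc_stim[ch]

    lik <- numeric(nfeat)
    if (out == 1L) lik[chosen] <- 1 / ndim else lik[-chosen] <- 1 / (nfeat - ndim)
    unnorm <- lik * prior
    unnorm[unnorm < 1e-15] <- 0
    z <- sum(unnorm)
    prior <- if (z <= 1e-12) uniform else unnorm / z

    choices[t] <- ch
    outcomes[t] <- out
  }

  # stimulus label strings, vectorised over trials
  stim_str <- matrix(NA_character_, nrow = nt, ncol = 3L)
  for (j in seq_len(k)) {
    parts <- lapply(seq_len(ndim), function(d) {
      labels[offset[d] + vapply(perms, `[[`, 0L, j)[perm_idx[, d]]]
    })
    stim_str[, j] <- do.call(paste, c(parts, sep = ";"))
  }

  tibble::new_tibble(
    list(
      level = rep(level$level_id, nt),
      block = (seq_len(nt) - 1L) %/% level$trials_per_block,
      trial = seq_len(nt) - 1L,
      stim1 = stim_str[, 1L], stim2 = stim_str[, 2L], stim3 = stim_str[, 3L],
      rule_dim = rules$dim, rule_feature = rules$feature,
      shift = shift_flag, shift_type = shift_type,
      choice = choices, outcome = outcomes,
      gc_pre = gc_pre, cc_pre = cc_pre
    ),
    nrow = nt
  )
}

#' Simulate one synthetic participant's full task run
#'
#' Runs the agent described in [agent_params()] through all levels: choices
#' by softmax over per-stimulus Choice Certainty with a lapse mixture;
#' confidence as a clipped noisy linear read-out of within-participant
#' standardised CC and GC; lognormal reaction times.
#'
#' @param levels List of [level_spec()]s.
#' @param params An [agent_params()] object.
#' @param seed Integer seed (`NULL` = current stream).
#' @param participant_id Identifier written into the log.
#' @return A trial-log tibble ([run_level()] schema with `confidence` and
#'   `rt` filled). The fraction of confidence values hit by clipping is
#'   attached as attribute `"clip_rate"` (a warning is raised above 10%).
#' @export
simulate_participant <- function(levels = make_default_levels(),
                                 params = agent_params(), seed = NULL,
                                 participant_id = "p1") {
  with_seed_if(seed, {
    log <- dplyr::bind_rows(lapply(levels, simulate_level_agent, params = params))
    n <- nrow(log)
    raw <- params$conf_intercept +
      params$w_cc * zscore(log$cc_pre) +
      params$w_gc * zscore(log$gc_pre) +
      rnorm(n, 0, params$conf_noise_sd)
    clipped <- pmin(pmax(raw, 1), 100)
    clip_rate <- mean(raw < 1 | raw > 100)
    if (clip_rate > 0.10) {
      warn(sprintf("Confidence clipping rate %.1f%% exceeds 10%% for %s.",
                   100 * clip_rate, participant_id))
    }
    out <- log |>
      dplyr::mutate(
        participant_id = participant_id,
        confidence = as.integer(round(clipped)),
        rt = rlnorm(n, params$rt_mu, params$rt_sigma)
      ) |>
      dplyr::select(
        "participant_id", "level", "block", "trial",
        "stim1", "stim2", "stim3", "rule_dim", "rule_feature",
        "shift", "shift_type", "choice", "outcome", "confidence", "rt"
      )
    attr(out, "clip_rate") <- clip_rate
    out
  })
}

simulate_group <- function(spec, levels, seed, id_prefix) {
  ids <- sprintf("%s%02d", id_prefix, seq_len(spec$n))
  per <- vector("list", spec$n)
  demo <- vector("list", spec$n)
  pars <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    s <- child_seed(seed, i)
    with_seed_if(s, {
      p <- draw_agent_params(spec)
      age <- round(min(max(rnorm(1L, spec$age_mean, spec$age_sd), 18), 55))
      gender <- sample(c(1L, 2L, 0L), 1L, prob = spec$gender_probs)
      iq <- round(rnorm(1L, spec$iq_mean, spec$iq_sd), 1L)
      per[[i]] <- simulate_participant(levels, p, seed = NULL,
                                       participant_id = ids[i])
      clip <- attr(per[[i]], "clip_rate")
      attr(per[[i]], "clip_rate") <- NULL
      demo[[i]] <- tibble(participant_id = ids[i], group = spec$label,
                          age = age, gender = gender, iq = iq)
      pars[[i]] <- tibble(participant_id = ids[i], group = spec$label,
                          !!!unclass(p), clip_rate = clip)
    })
  }
  list(trials = dplyr::bind_rows(per), demographics = dplyr::bind_rows(demo),
       agent_params = dplyr::bind_rows(pars))
}

#' Simulate a two-group cohort
#'
#' @param ocd,control [group_spec()]s (defaults: [default_group_specs()],
#'   29 + 29 participants, matched accuracy, OCD confidence intercept 12
#'   slider units lower and Choice-Certainty weight 3 units higher).
#' @param seed Integer master seed; all participant-level randomness is
#'   derived from it, so a fixed seed reproduces the cohort exactly.
#' @param levels List of [level_spec()]s.
#' @return An `rs_cohort`: list with `trials` (all participants' logs),
#'   `demographics` (`participant_id`, `group`, `age`, `gender`, `iq`) and
#'   `agent_params` (ground-truth generative parameters).
#' @export
simulate_cohort <- function(ocd = default_group_specs()$ocd,
                            control = default_group_specs()$control,
                            seed = NULL, levels = make_default_levels()) {
  if (!is.null(seed)) check_seed(seed)
  seed_c <- if (is.null(seed)) NULL else child_seed(seed, 1000L)
  seed_o <- if (is.null(seed)) NULL else child_seed(seed, 2000L)
  g_c <- simulate_group(control, levels, seed_c %||% sample.int(2^31 - 1, 1L), "c")
  g_o <- simulate_group(ocd, levels, seed_o %||% sample.int(2^31 - 1, 1L), "o")
  structure(
    list(
      trials = dplyr::bind_rows(g_c$trials, g_o$trials),
      demographics = dplyr::bind_rows(g_c$demographics, g_o$demographics),
      agent_params = dplyr::bind_rows(g_c$agent_params, g_o$agent_params)
    ),
    class = "rs_cohort"
  )
}

#' @export
print.rs_cohort <- function(x, ...) {
  ng <- table(x$demographics$group)
  cat(sprintf("<rs_cohort> %d participants (%s), %d trials\n",
              nrow(x$demographics),
              paste(sprintf("%s: %d", names(ng), ng), collapse = ", "),
              nrow(x$trials)))
  invisible(x)
}

as_cohort <- function(trials, demographics, agent_params = NULL) {
  structure(list(trials = trials, demographics = demographics,
                 agent_params = agent_params), class = "rs_cohort")
}
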