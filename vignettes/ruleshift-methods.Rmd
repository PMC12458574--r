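---
title: "Models and methods behind ruleshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ruleshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruleshift)
```

`ruleshift` studies two dissociable aspects of metacognition in
rule-shifting tasks: a stable *metacognitive bias* (an offset in reported
confidence that does not depend on trial-wise evidence) and *evidence
tracking* (how strongly trial-wise confidence co-varies with normative
certainty). Its motivating application is the comparison of people with
obsessive-compulsive disorder (OCD) against matched controls, where lowered
overall confidence can coexist with intact — or even heightened — coupling
of confidence to the available evidence. The package provides everything
needed to study that dissociation end to end on synthetic data: the task,
the normative observer, a generative participant model, and the statistical
pipeline.

## The rule-shifting task

Participants see two or three stimuli, each described by several dimensions
(colour, shape, "hair"); within each dimension every displayed stimulus
carries a distinct feature. One feature is covertly rewarded; choosing the
stimulus that carries it yields deterministic positive feedback. The rule
changes without warning every 6–11 trials, either within the relevant
dimension (intra-dimensional, ID) or to a different dimension
(extra-dimensional, ED). The default design has three levels:

| level | stimuli | dimensions | trials | unique features N |
|------:|--------:|-----------:|-------:|------------------:|
| 1     | 2       | 2          | 60 (2 × 30) | 4 |
| 2     | 2       | 3          | 70 (2 × 35) | 6 |
| 3     | 3       | 3          | 70 (2 × 35) | 9 |

Design choices that the task description leaves open, fixed here once:

* **Level-2 dimensionality.** "Additional dimensions" at level 2 is realised
  as three dimensions (versus two at level 1), the minimal increment that
  still adds features while keeping two stimuli. Configurable through
  `level_spec()`.
* **Full feature display.** Every feature of every dimension appears exactly
  once per trial, one per stimulus, with assignments re-randomised each
  trial. This guarantees that exactly one stimulus carries the rewarded
  feature, and makes the feature sets of the stimuli a partition — which in
  turn gives Choice Certainty its sum-to-100 property (below).
* **Shift sequencing.** Each shift is ID or ED with probability 1/2,
  re-drawn until every block containing at least two shifts contains both
  types. Gaps are i.i.d. uniform on {6, …, 11}; no shift lands on a level's
  first trial; block boundaries do not reset the gap counter. The last gap
  of a level is censored by the level end, so the *observed* gap
  distribution slightly favours small gaps even though the draws are
  uniform.
* **Shift-distance convention.** The first trial governed by a new rule has
  distance +1 (the "trial 1" of shift-aligned figures), the last trial under
  the old rule −1; there is no distance 0. Accuracy therefore dips at
  distance +1. Confidence dips at +2 instead: the rating at +1 is given
  *before* the first feedback under the new rule, so the participant cannot
  yet know the rule changed.
* **Shift schedules are sampled per participant** (fresh randomness from
  each participant's seed), not frozen across the cohort; the engine accepts
  a pre-sampled `schedule` argument when a yoked design is wanted.

## The Bayes-optimal observer

The observer maintains a belief \(P_t(f_k)\) over the \(N\) unique features
of a level, initialised uniform (\(1/N\)) at each level start. After seeing
the choice and its outcome \(r_t \in \{0, 1\}\), it updates by Bayes' rule,

\[
P_t(f_k) \propto \Pr(r_t \mid f_k)\, P_{t-1}(f_k),
\]

with a likelihood that spreads the evidence uniformly over the implicated
feature set: on a rewarded trial, \(1/n^c\) for each of the \(n^c\) features
of the chosen stimulus and 0 elsewhere; on an unrewarded trial, 0 for chosen
features and \(1/n^u\) for each of the \(n^u\) features pooled across all
unchosen stimuli. If feedback invalidates every currently supported
hypothesis (the normalising constant is zero), the belief is **reset** to
uniform — the observer knows covert shifts happen, and this reset is its
only shift-handling mechanism (no hazard-rate inference, no leak).

Two certainty read-outs, both on the participants' 0–100 confidence scale:

* **General Certainty (GC)** — the proportion of maximal uncertainty
  eliminated: with posterior entropy \(S_t = -\sum_k P_t(f_k)\log_2
  P_t(f_k)\) (using \(0 \log 0 = 0\)),
  \(\mathrm{GC}_t = 100\,(\log_2 N - S_t)/\log_2 N\). GC is 0 at uniform,
  100 at a point mass, and strictly decreasing in entropy. A variant that
  takes the logarithm of the entropy itself (`variant = "printed"`) is
  retained for sensitivity analysis only: it is dimensionally inconsistent,
  diverges as \(S_t \to 0\), and is nonzero at uniform, so it is not the
  default.
* **Choice Certainty (CC)** — the posterior mass on the chosen stimulus:
  \(\mathrm{CC}_t = 100 \sum_{f \in F^c_t} P_t(f)\). Because the displayed
  feature sets partition the features, CC across the displayed stimuli sums
  to 100 on every trial.

**Timing.** Confidence is reported before feedback, so the regressor aligned
with it uses the belief updated through trial \(t-1\) plus the trial-\(t\)
choice: these are the `gc_pre`/`cc_pre` columns of `run_observer()` and the
default regressors everywhere. The post-feedback traces
(`gc_post`/`cc_post`) are also emitted — they are the natural values for
shift-locked time-course plots, where the reset at the shift trial (GC
collapsing to 0, CC at \(100\,n^c/N\)) is visible — but they never silently
replace the pre-feedback trace in a regression.

**Numerics.** Probabilities below 1e-15 are truncated to 0 before the
zero-denominator test, so resets are robust to floating-point residue;
non-reset posteriors renormalise to within 1e-10 of 1. At two-stimulus
levels the chosen and pooled-unchosen feature counts coincide, so the
posterior stays uniform on its support (hypothesis elimination in the
strict sense); with three stimuli the unequal counts produce graded
posteriors. Both regimes are verified in the tests against a brute-force
oracle that recomputes normalised likelihood products from scratch.

## The synthetic cohort

No generative participant model is fitted to data anywhere in this package;
the agent is the simplest mechanism that produces the three phenomena the
analysis pipeline is meant to detect: matched accuracy across groups, a
stable confidence offset, and group-dependent coupling of confidence to
choice-specific evidence.

* **Choice**: softmax over the per-stimulus Choice Certainty of the agent's
  own Bayes-optimal belief, \(\Pr(j) \propto \exp(\beta\,\mathrm{CC}_j)\),
  mixed with a lapse rate of uniformly random choices. Defaults
  \(\beta = 0.12\) per CC unit and lapse 0.05 give mean accuracies of about
  0.75 / 0.74 / 0.65 across levels 1–3 — declining with difficulty, as the
  ideal-observer ceiling does (≈ 0.77 / 0.76 / 0.67, which the gap structure
  alone imposes). Human cohorts show a steeper drop at level 3 (closer to
  0.55) than this agent reproduces: people fall further below the normative
  ceiling when the hypothesis space grows, an attentional/working-memory
  effect the softmax-on-CC agent does not model. Conclusions about absolute
  level-3 performance therefore do not transfer from these simulations.
* **Confidence**: `clip(b + w_cc * z(CC) + w_gc * z(GC) + noise, 1, 100)`,
  rounded to integer slider units, with CC/GC standardised within
  participant and Gaussian trial noise (default SD 10). Participant-level
  parameters are drawn from independent truncated normals around the group
  means (SDs: intercept 8, w_cc 2, w_gc 1.5).
* **Group presets** (`default_group_specs()`): both groups share all choice
  parameters (accuracy matched by construction); the OCD group's confidence
  intercept is lower by `delta_b` (default 12 slider units — inside the 6.5
  to 17-unit per-level gaps reported for real cohorts; control intercept 69)
  and its CC weight higher by `delta_w` (default +3 against a control weight
  of 7, deliberately modest). Clipping at the scale ends affects a few
  percent of trials for high-intercept participants; the per-participant
  clipping rate is recorded in the ground-truth table and a warning is
  raised above 10%.
* **Demographics**: age normal(31, 11) truncated to 18–55, IQ-proxy
  normal(40, 8), gender codes sampled with a small (5%) non-binary
  probability in both groups so the three-level categorical coding path is
  exercised; codes are 1 = female, 2 = male, 0 = non-binary/other, always
  modelled as an unordered factor.

One property of this generator deserves emphasis because it is easy to get
wrong: the group difference in CC coupling does **not** show up as a group
difference in the average post-correct/post-incorrect confidence *change*.
Those changes are dominated by the GC term — feedback-driven belief resets
move GC far more than they move the standardised CC of the next choice —
and GC is weighted equally in both groups. The coupling difference is
recovered where it lives: in the previous-accuracy × group interaction of
the feedback model and the CC × group interaction of the normative model.
Tests assert exactly that, and no more.

## The analysis pipeline

Preprocessing mirrors standard confidence-task practice:

* **Participant exclusions** (`apply_exclusions()`): overall accuracy at or
  below chance, where the default threshold is the trial-weighted chance
  level across levels, \((60 \cdot \tfrac12 + 70 \cdot \tfrac12 + 70 \cdot
  \tfrac13)/200 \approx 0.442\) ("at or below chance overall" is ambiguous
  when chance differs by level; a per-level variant is available via
  `mode = "per_level"`); and insufficient use of the confidence scale (one
  value on more than 90% of trials).
* **RT filter** (`rt_outlier_filter()`): per participant × level, log-RTs
  beyond 3 SD are dropped; the first trial of each block is excluded from
  both the threshold computation and the filtering. A zero SD removes
  nothing. The filter is applied to the *modelled* rows only — the observer
  always replays the complete log, since its beliefs must see every
  feedback.
* **Outlier removal for the group contrasts**: participant-level summaries
  outside median ± 1.5 IQR bounds (Q1 − 1.5·IQR, Q3 + 1.5·IQR) are removed
  within group × condition before testing.

Inference uses lme4/lmerTest mixed models with z-scored continuous
predictors (categorical predictors untouched; group is a factor with
control as reference):

* **Post-shift recovery** (`fit_recovery_model()`): accuracy (logistic) or
  confidence (linear) over the five post-shift trials, with the distance
  functional form — linear (z-scored), logarithmic, or quadratic in centred
  orthogonal polynomials of the observed distances — selectable by BIC
  (`select_functional_form()`, maximum likelihood, random intercept per
  participant; ties break toward fewer parameters, then candidate order).
  Orthogonal-polynomial coefficients live on their own scale and are not
  comparable in magnitude to raw-distance coefficients.
* **Feedback sensitivity** (`fit_feedback_model()`): confidence on lagged
  accuracy (lag never crosses a level boundary), group and their
  interaction, covariates age, gender, IQ, with a random lagged-accuracy
  slope per participant and a random intercept per level.
* **Normative tracking** (`fit_normative_model()`): confidence on GC, CC,
  group, GC × group, CC × group and covariates (`spec = "joint"`), or with
  the CC terms dropped (`spec = "gc_only"`). Variance inflation factors are
  computed on the main-effects fixed design via a generalised-VIF auxiliary
  regression; interaction columns are excluded from the VIF because
  products of z-scored predictors with group dummies are structurally
  collinear with their parents, which says nothing about the identifiability
  of interest.
* **Random-effects policy**: each model starts from the structure above and
  walks a simplification ladder — drop the slope-intercept correlation, then
  the slope — only when the *participant-level* random part degenerates
  (zero slope variance or |correlation| ≈ 1) or optimisation fails. A zero
  variance of the three-level task-level intercept also makes lme4 flag the
  fit as singular, but that is harmless and does not justify removing the
  participant slope (dropping it would badly understate the uncertainty of
  the between-participant interaction terms). For the same reason the
  random structure is fixed per model rather than selected by information
  criteria: with three levels and modest group sizes, BIC frequently
  prefers dropping the participant slope, which trades a little fit for
  badly anti-conservative interaction tests. Any simplification is flagged
  in the result.
* **Descriptives**: mixed-design group × level ANOVA on per-participant
  level means (`rm_anova()`, via `aov` with an `Error(participant/level)`
  stratum; demographic covariates enter the regression models only — the
  ANOVA is the covariate-free descriptive contrast), shift-aligned means ± SE (`shift_aligned_summary()`), and
  within-participant Spearman correlations of the GC and CC traces
  (`within_subject_correlation()`; constant traces are excluded with a
  flag).
* **Confidence-change tests** (`feedback_change_tests()`): participant-level
  mean confidence change after correct and after incorrect trials
  (trial-level pooling available via `aggregate = "trial"`); one-sample
  t-tests, replaced by Wilcoxon signed-rank when Shapiro–Wilk rejects
  normality at α = 0.05; between-group t-tests replaced by rank-sum tests on
  non-normality or Levene-detected variance heterogeneity. Bonferroni
  families: the four within-group tests form one family (adjusted p =
  min(1, 4p)), the two between-group comparisons another (min(1, 2p)).

## Parameter recovery

`recovery_experiment()` closes the loop: simulate a cohort with known
`delta_b` and `delta_w`, run exclusions, observer, RT filter and the joint
normative model, and record the estimated group intercept effect and
CC × group interaction. With the default presets (−12 / +3) and 29 per
group, both effects are recovered with the correct sign and p < 0.05 in
well over 90% of replicates, with negligible bias; under null presets the
interaction rejects at the nominal 5% rate. Replicate-to-replicate spread
includes the sampling of the *true* cohort-level effect (participant
parameters are drawn around the group means), so the RMSE reported by
`summary()` is dominated by between-cohort variation at small n and shrinks
as group size grows (checked at 15, 29 and 60 per group).

Problem sizes used in the shipped checks: 50 preset replicates and 200 null
replicates at 29 per group for the recovery surface; 500 random short logs
for the observer-versus-oracle equivalence; ~10⁴ random-policy trials per
level for the chance-rate checks.

## What the synthetic data does and does not establish

The generator reproduces the *structure* the pipeline assumes — determinism
of feedback, covert shift timing, a confidence report linearly coupled to
normative certainty with participant-level heterogeneity, matched-accuracy
groups differing in intercept and CC coupling. Passing tests therefore show
that the pipeline measures what it claims to measure on data of that
structure. They do not show that real confidence ratings are a linear
read-out of CC and GC, that real accuracy profiles match the agent's
(level 3 in particular), or that real effect sizes equal the presets; the
observer's certainty traces on real data also depend on choices the
package cannot verify (e.g., that participants saw every trial the log
records). Real-data coefficients are deliberately not targets anywhere in
the test suite.
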