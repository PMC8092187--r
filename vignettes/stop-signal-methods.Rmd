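---
title: "Models and methods behind stopsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stopsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopsignal)
```

This vignette is the package's own account of its science: the task and
generative model, the estimator and its conventions, the quality-control and
statistical choices, and — importantly — what a green test does *not*
establish.

## 1. Task structure and staircase

A session is a randomized sequence of `n_trials` (default 256) two-choice
colour classifications over 8 stimuli, 4 per category (`food`, `control`),
colour-balanced within category. A proportion `p_stop` (default 0.25, i.e. 64
trials) are stop trials, split as evenly as possible across categories (32/32
at the defaults) so that each category can support its own SSRT estimate.
Randomization is an unconstrained uniform shuffle; no run-length constraints
are imposed because none are part of the emulated protocol.

The stop-signal delay (SSD) follows a 1-up/1-down tracking rule per
category: +50 ms after a successful stop, −50 ms after any response on a
stop trial (including premature responses before the signal), clamped to
[50, 900] ms, starting at 200 ms. This converges on ~50% response rate given
a signal, which maximizes the information available to the integration
method. The colour→key mapping is a fixed session-level bijection
(red→left by default, configurable); counterbalancing across participants is
not modelled.

## 2. The generative model (what the simulator emulates)

Each simulated participant carries latent parameters:

* **Go finishing time**: ex-Gaussian with parameters (`go_mu`, `go_sigma`,
  `go_tau`) in ms. The ex-Gaussian is the conventional model for
  right-skewed RT distributions. The person-level *mean* go RT
  (`go_mu + go_tau`) is what covariates act on; the within-person shape
  (`go_sigma` = 60 ms, `go_tau` = 150 ms) is a conventional choice — no
  study-level summary constrains trial-level variance, so these stay
  configurable and fixed across persons.
* **Stop latency**: Gaussian truncated at 0 with person mean
  `ssrt_true_mean` and trial SD `ssrt_trial_sd` (default 30 ms, also
  unobservable and conventional).
* **Lapses**: go omissions with probability 0.02 (on any trial; a lapsed go
  process on a stop trial yields a trivially successful stop) and choice
  errors with probability 0.02 on responded go trials.

A stop trial produces a response iff the sampled go time beats
`SSD + stop latency` — the independent horse-race assumption. Premature
responses (`T_go < SSD`) are emitted naturally by the race and count as
failed stops for the staircase, matching the emulated protocol.

Cohort-level defaults state the emulated world: two arms (48 gamified, 52
nongamified), ~30% overweight (BMI ≥ 25; BMI strata drawn from truncated
normals at 21.3 (2.3) and 28.6 (3.6) kg/m²), arm-specific age distributions
(29.6 (11.3) vs 25.3 (7.2) years, ≥18), and additive effects on person
means: condition +196 ms go RT and +86 ms SSRT; overweight +80 ms go RT and
+35 ms SSRT; an age slope of +2 ms/year on SSRT (calibrated to give a
positive age–SSRT correlation); a configurable direct BMI slope on SSRT
(default 0 — the BMI–SSRT association arises through the overweight
contrast). Between-person SDs of 85 ms (go) and 40 ms (SSRT) give realistic
spread. DEBQ eating-behaviour scores and state hunger are generated to match
the emulated sample's descriptives but are causally inert. Heights are
sampled independently (170 (9) cm) so the height-plausibility QC rule is
exercisable end to end.

**What the generator does not emulate**: attrition, attention-check
failures, learning/fatigue trends, strategic waiting, context dependence
between categories, or any mood/user-experience dynamics. A green test
therefore establishes that the *pipeline* behaves correctly under the race
model — not that real behavioural data satisfy the race model.

## 3. The integration estimator and its conventions

For each participant × category:

1. `p = p(respond | signal)`: responses over all stop trials (premature
   responses included).
2. Go-RT vector: all go-trial RTs including choice errors, each omission
   replaced by the participant's **maximum** observed go RT, sorted.
3. `Q_go` = element at rank `ceil(p × n_go)`, 1-based, no interpolation —
   the standard integration-method convention, pinned for bit-exact tests.
4. `SSRT = Q_go − mean(SSD)` with the mean over **all** stop trials of the
   category (not only successful ones).

Estimates at `p ∈ {0, 1}` are flagged invalid (the staircase failed to
bracket the race; at `p = 0` the rank is 0 and SSRT is undefined). Choice
errors remain in the go distribution (consensus default). The max-RT
replacement rule is the consensus recommendation and is documented as an
assumption, not derived.

A known property, quantified here by simulation and deliberately not
"corrected": the integration estimate carries a small negative bias
(≈ −10 ms in the default world) even at large trial counts. Three
components: the staircase's stationary mean SSD overshoots the 50% point
because the psychometric curve `F_go(SSD + SSRT)` is right-skewed (steeper
below its median than above); go-process lapses on stop trials push the SSD
up; and stop-latency variability adds a small convolution asymmetry. These
are faithful consequences of the task and estimator, and they shrink with
`go_tau`.

## 4. Quality control

Participant-level exclusions (whole participant): missing behavioural data;
self-reported height outside [147, 200] cm (a configurable stand-in for a
95% population interval); stopping probability `1 − p(respond | signal)`
strictly outside [0.25, 0.75] in **any** category (boundary values comply —
the rule says *outside*). Race-model violations (mean signal-respond RT ≥
mean go RT) reject only the affected per-category value, because a violation
invalidates that SSRT estimate, not the participant. Categories with no
signal-respond trials are not evaluable and pass with a warning. Whether the
band is expressed on the stopping or responding axis is immaterial — it is
symmetric around 0.5. The QC report counts every reason, and reruns on a
cleaned cohort are no-ops.

## 5. Statistics

**Mixed model**: `value ~ age + group × overweight × stimulus` with a random
intercept per subject, fitted by `nlme::lme` (REML), F tests from the
sequential `anova.lme` with **containment** denominator degrees of freedom.
This convention reproduces, exactly, the between-subject stratum of a
split-plot decomposition — the test suite checks F, p and df of the
between-subject terms against an independent `lm`-on-subject-means route.
With unbalanced cells the sequential within-subject rows have no simple
closed-form counterpart; they are reported as nlme computes them. Degenerate
designs (a factor with one level, constant response) raise errors naming the
problem. Simple-effects questions are answered by subgroup refits, labelled
as such, because a pooled-error simple-effects convention is not fully
specified by the emulated analysis.

**Correlation**: product-moment r between BMI and SSRT over all valid
participant × category records, CI by Fisher transform, N printed explicitly
(records, not participants; the two records of a participant share BMI, so
the CI leans on an independence idealization — the package reports N so the
reader can judge). The outlier sensitivity analysis re-computes r after
removing records outside median ± 3×MAD of SSRT: a reproducible stand-in for
"visual inspection", and pluggable.

**Power**: the a-priori sample size for a one-sided test of zero correlation
uses the exact sampling distribution of r under bivariate normality via the
identity `sqrt(n−2)·R/sqrt(1−R²) =d (ρ′·χ_{n−1} + Z)/(χ_{n−2}/sqrt(n−2))`
with `ρ′ = ρ/sqrt(1−ρ²)`: conditioning on the χ draw makes the statistic
noncentral t, so power is a single quadrature over the χ density
(`rel.tol = 1e-10`). For ρ = 0.35, α = .05, power = .80 this yields **49**
per group; the Fisher-z closed form `n = ((z_{1−α}+z_{power})/atanh ρ)² + 3`
yields 50 and is exposed for comparison. The identity was verified against a
50,000-replicate Monte-Carlo simulation before the value was frozen into the
tests.

## 6. Numerical and design choices

* Seeds: every stochastic entry point takes a seed and restores the ambient
  RNG state; cohort runs derive per-participant sub-seeds (< 2³¹) from the
  master seed, so a run is a pure function of (config, seed).
* `simulate_session` pre-samples all per-trial draws in design order and
  threads the staircase in one pass — distributionally identical to a
  trial-by-trial loop (the race depends only on the category's current SSD)
  but fast enough for 500-replicate calibration studies. The exported
  `simulate_trial` draws from the ambient stream for single-trial work.
* The type-I-error criterion fits the mixed model on estimator output
  without the QC stage: exclusions are orthogonal to the null calibration of
  the condition F test, and omitting them keeps 500 replicates well inside
  the time budget.
* The CI-coverage test uses single-category sessions (one record per
  participant) so the Fisher CI's independence assumption actually holds in
  the tested world; the recovery criterion likewise uses single-category
  sessions so each estimate rests on all 64 stop trials, matching the
  "≥ 50 stop trials" premise it operationalizes.
* Truncated normals are sampled by inverse-CDF so `sd = 0` degenerates
  cleanly; ex-Gaussian RTs are floored at 1 ms; staircase arithmetic is pure
  ±step with clamping, so SSDs stay on the 50 ms grid.
* Stop trials split across categories as evenly as possible; with the
  default 64 stop trials the split is exact (32/32). A remainder goes to the
  first categories in the order given — deterministic, documented, and only
  reachable in non-default designs.

## 7. Known limitations

* The simulator's covariate effects are additive and homoscedastic;
  real gamification effects may be distributional (e.g. heavier tails), which
  the calibration deliberately does not attempt.
* The arm-specific between-person SD of mean go RT is single-valued; the
  emulated study reports a larger spread in its gamified arm than the
  default reproduces. Orderings, not SDs, are what the qualitative
  acceptance check asserts.
* Containment df are one convention among several (Satterthwaite,
  Kenward-Roger); results for the between-subject effects at these sample
  sizes are insensitive to the choice, but small-sample within-subject
  inference could differ.
* The exact-power routine assumes bivariate normality; for heavy-tailed
  SSRT distributions the planned n is approximate.
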