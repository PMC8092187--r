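# Cohort simulator under the independent horse-race model.
#
# Each participant carries latent generative parameters: an ex-Gaussian go
# finishing-time distribution (mu, sigma, tau), a Gaussian stop latency
# truncated at zero, and lapse probabilities for go omissions and choice
# errors. Covariate effects (task condition, overweight, age) act additively
# on the person-level mean go RT and mean stop latency.

#' Default cohort configuration
#'
#' Generative defaults calibrated to a two-arm web experiment comparing a
#' gamified and a plain stop-signal task in an adult convenience sample with
#' roughly 30% overweight participants: 48 vs 52 participants per arm, go RT
#' centred at 607 ms in the plain arm with a +196 ms gamification effect and a
#' +80 ms overweight effect, true SSRT centred at 297 ms with +86 ms
#' (gamification) and +35 ms (overweight) shifts, and a small positive age
#' slope on SSRT. Eating-behaviour scores (DEBQ) and state hunger are emitted
#' as inert covariates. Every value can be overridden via `...`.
#'
#' @param ... Named overrides of any default element.
#' @return A named list of generative parameters (class `cohort_config`).
#' @export
default_cohort_config <- function(...) {
  cfg <- list(
    n_gamified = 48L, n_nongamified = 52L,
    p_overweight = 0.30,
    # BMI strata, kg/m^2 (overweight = BMI >= 25)
    bmi_normal_mean = 21.3, bmi_normal_sd = 2.3,
    bmi_overweight_mean = 28.6, bmi_overweight_sd = 3.6,
    # demographics
    age_mean_gamified = 29.6, age_sd_gamified = 11.3,
    age_mean_nongamified = 25.3, age_sd_nongamified = 7.2,
    age_min = 18,
    height_mean = 170, height_sd = 9,
    p_female = 0.41,
    # inert questionnaire covariates
    debq_restrained_mean = 17.0, debq_restrained_sd = 9.3,
    debq_emotional_mean = 20.6, debq_emotional_sd = 12.7,
    debq_external_mean = 23.1, debq_external_sd = 6.0,
    hunger_mean = 38.2, hunger_sd = 31.6,
    # person-level mean go RT, ms
    go_rt_base = 607, effect_condition_go = 196, effect_overweight_go = 80,
    age_slope_go = 0, sd_person_go = 85,
    # within-person go RT shape (ex-Gaussian), ms
    go_sigma = 60, go_tau = 150,
    # person-level mean stop latency, ms
    ssrt_base = 297, effect_condition_ssrt = 86, effect_overweight_ssrt = 35,
    age_slope_ssrt = 2, bmi_slope_ssrt = 0, sd_person_ssrt = 40,
    ssrt_trial_sd = 30,
    age_center = 27,
    # lapses
    p_go_omission = 0.02, p_choice_error = 0.02
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop("unknown cohort config fields: ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg <- modifyList(cfg, over)
  }
  structure(cfg, class = c("cohort_config", "list"))
}

#' Null cohort configuration
#'
#' All covariate effects are zero and both arms are drawn from one population
#' (identical age distributions), so any estimated group difference is pure
#' sampling noise. Used for type-I-error and coverage simulations.
#'
#' @param ... Named overrides passed on to [default_cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(...) {
  default_cohort_config(
    effect_condition_go = 0, effect_overweight_go = 0, age_slope_go = 0,
    effect_condition_ssrt = 0, effect_overweight_ssrt = 0,
    age_slope_ssrt = 0, bmi_slope_ssrt = 0,
    age_mean_gamified = 27, age_sd_gamified = 9,
    age_mean_nongamified = 27, age_sd_nongamified = 9,
    ...
  )
}

# truncated-normal sampler via inverse CDF (deterministic under set.seed)
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (all(sd == 0)) return(pmin(upper, pmax(lower, rep_len(mean, n))))
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Sample latent participant profiles for a cohort
#'
#' Draws per-participant covariates (group, BMI stratum, age, gender, height,
#' questionnaire scores) and latent generative parameters (ex-Gaussian go
#' parameters, mean/SD of the stop latency, lapse rates) whose population
#' expectations follow the configuration.
#'
#' @param config A `cohort_config`, see [default_cohort_config()].
#' @param seed Integer seed; identical seeds give identical profiles.
#' @return A data.frame with one row per participant: identifiers and
#'   covariates plus latent truth columns (`go_mu`, `go_sigma`, `go_tau`,
#'   `ssrt_true_mean`, `ssrt_true_sd`, `p_go_omission`, `p_choice_error`).
#' @export
sample_cohort_profiles <- function(config = default_cohort_config(),
                                   seed = NULL) {
  cf <- config
  if (cf$n_gamified < 0 || cf$n_nongamified < 0)
    stop("group sizes must be non-negative", call. = FALSE)
  for (p in c("p_overweight", "p_female", "p_go_omission", "p_choice_error"))
    if (cf[[p]] < 0 || cf[[p]] > 1)
      stop("`", p, "` must lie in [0, 1]", call. = FALSE)

  with_seed(seed, {
    n <- cf$n_gamified + cf$n_nongamified
    if (n == 0L) stop("empty cohort", call. = FALSE)
    group <- rep(c("gamified", "nongamified"),
                 c(cf$n_gamified, cf$n_nongamified))
    gam <- group == "gamified"
    overweight <- runif(n) < cf$p_overweight
    bmi <- ifelse(overweight,
                  rtnorm(n, cf$bmi_overweight_mean, cf$bmi_overweight_sd,
                         25, 55),
                  rtnorm(n, cf$bmi_normal_mean, cf$bmi_normal_sd, 15, 24.99))
    age <- rtnorm(n,
                  ifelse(gam, cf$age_mean_gamified, cf$age_mean_nongamified),
                  ifelse(gam, cf$age_sd_gamified, cf$age_sd_nongamified),
                  cf$age_min, 80)
    gender <- ifelse(runif(n) < cf$p_female, "female", "male")
    height_cm <- rtnorm(n, cf$height_mean, cf$height_sd, 140, 210)

    mean_go <- cf$go_rt_base +
      gam * cf$effect_condition_go +
      overweight * cf$effect_overweight_go +
      cf$age_slope_go * (age - cf$age_center) +
      rnorm(n, 0, cf$sd_person_go)
    go_mu <- pmax(mean_go - cf$go_tau, 100)

    ssrt_true_mean <- pmax(
      cf$ssrt_base +
        gam * cf$effect_condition_ssrt +
        overweight * cf$effect_overweight_ssrt +
        cf$age_slope_ssrt * (age - cf$age_center) +
        cf$bmi_slope_ssrt * (bmi - 24) +
        rnorm(n, 0, cf$sd_person_ssrt),
      80)

    data.frame(
      id = sprintf("P%03d", seq_len(n)),
      group = group,
      bmi = bmi, age = age, gender = gender, height_cm = height_cm,
      debq_restrained = pmax(
        rnorm(n, cf$debq_restrained_mean, cf$debq_restrained_sd), 0),
      debq_emotional = pmax(
        rnorm(n, cf$debq_emotional_mean, cf$debq_emotional_sd), 0),
      debq_external = pmax(
        rnorm(n, cf$debq_external_mean, cf$debq_external_sd), 0),
      hunger = rtnorm(n, cf$hunger_mean, cf$hunger_sd, 0, 100),
      go_mu = go_mu, go_sigma = cf$go_sigma, go_tau = cf$go_tau,
      ssrt_true_mean = ssrt_true_mean, ssrt_true_sd = cf$ssrt_trial_sd,
      p_go_omission = cf$p_go_omission, p_choice_error = cf$p_choice_error,
      stringsAsFactors = FALSE
    )
  })
}

# ex-Gaussian draws; tau = 0 degenerates to the Gaussian component
rexgauss <- function(n, mu, sigma, tau) {
  x <- rnorm(n, mu, sigma)
  if (any(tau > 0)) x <- x + rexp(n, 1 / pmax(tau, .Machine$double.eps)) *
      (tau > 0)
  pmax(x, 1)
}

# stop latency: Gaussian truncated at zero (sd = 0 degenerates to the mean)
rstop_latency <- function(n, mean, sd) {
  if (all(sd == 0)) return(pmax(rep_len(mean, n), 0))
  rtnorm(n, mean, sd, lower = 0)
}

#' Simulate a single trial under the race model
#'
#' Go trials: the response is omitted with `p_go_omission`; otherwise the RT
#' is an ex-Gaussian draw and the wrong key is pressed with `p_choice_error`.
#' Stop trials: the go and stop processes race independently; the participant
#' responds iff the sampled go finishing time beats `SSD + stop latency`
#' (premature responses, go time < SSD, are a special case and count as failed
#' stops). Draws come from the ambient RNG stream: call `set.seed()` first for
#' reproducibility.
#'
#' @param profile One row of a profile table from [sample_cohort_profiles()].
#' @param spec One row of a design from [generate_design()].
#' @param state A `staircase_state` supplying the current SSD for the trial's
#'   category (stop trials only).
#' @return A one-row data.frame: the spec columns plus `ssd_ms` (NA on go
#'   trials), `responded`, `rt_ms` (NA when no response) and `correct`.
#' @export
simulate_trial <- function(profile, spec, state) {
  stopifnot(nrow(profile) == 1L, nrow(spec) == 1L)
  go_time <- rexgauss(1L, profile$go_mu, profile$go_sigma, profile$go_tau)
  omitted <- runif(1L) < profile$p_go_omission
  if (spec$trial_type == "go") {
    responded <- !omitted
    wrong <- runif(1L) < profile$p_choice_error
    out <- data.frame(spec, ssd_ms = NA_real_, responded = responded,
                      rt_ms = if (responded) go_time else NA_real_,
                      correct = responded && !wrong)
  } else {
    ssd <- state$ssd_ms[[spec$stimulus_category]]
    lat <- rstop_latency(1L, profile$ssrt_true_mean, profile$ssrt_true_sd)
    responded <- !omitted && go_time < ssd + lat
    out <- data.frame(spec, ssd_ms = ssd, responded = responded,
                      rt_ms = if (responded) go_time else NA_real_,
                      correct = !responded)
  }
  rownames(out) <- NULL
  out
}

#' Simulate a full session, threading the SSD staircase
#'
#' Produces one [simulate_trial()]-equivalent outcome per design row, updating
#' the per-category SSD staircase after every stop trial (success raises the
#' SSD by one step, any response lowers it). All random draws are pre-sampled
#' in design order, so the function is a pure function of
#' `(profile, design, seed)`.
#'
#' @param profile One profile row.
#' @param design A design from [generate_design()].
#' @param seed Integer seed; `NULL` uses the ambient RNG state.
#' @param staircase A `staircase_state`; defaults to [new_staircase()] over
#'   the design's categories.
#' @return A data.frame with the design columns plus `ssd_ms`, `responded`,
#'   `rt_ms`, `correct`.
#' @export
simulate_session <- function(profile, design, seed = NULL, staircase = NULL) {
  stopifnot(nrow(profile) == 1L)
  cats <- unique(design$stimulus_category)
  if (is.null(staircase)) staircase <- new_staircase(cats)
  n <- nrow(design)
  is_stop <- design$trial_type == "stop"

  with_seed(seed, {
    go_time <- rexgauss(n, profile$go_mu, profile$go_sigma, profile$go_tau)
    omitted <- runif(n) < profile$p_go_omission
    wrong <- runif(n) < profile$p_choice_error
    lat <- numeric(n)
    lat[is_stop] <- rstop_latency(sum(is_stop), profile$ssrt_true_mean,
                                  profile$ssrt_true_sd)

    responded <- !omitted
    rt <- ifelse(responded, go_time, NA_real_)
    correct <- responded & !wrong
    ssd <- rep(NA_real_, n)

    # staircase state per category; only stop trials touch it
    cur <- staircase$ssd_ms
    step <- staircase$step_ms
    lo <- staircase$floor_ms
    hi <- staircase$ceiling_ms
    for (i in which(is_stop)) {
      cat_i <- design$stimulus_category[i]
      s <- cur[[cat_i]]
      ssd[i] <- s
      resp <- !omitted[i] && go_time[i] < s + lat[i]
      responded[i] <- resp
      rt[i] <- if (resp) go_time[i] else NA_real_
      correct[i] <- !resp
      cur[[cat_i]] <- min(hi, max(lo, s + if (resp) -step else step))
    }

    out <- design
    out$ssd_ms <- ssd
    out$responded <- responded
    out$rt_ms <- rt
    out$correct <- correct
    out
  })
}

#' Simulate a whole cohort
#'
#' Draws (or accepts) participant profiles, generates a fresh randomized
#' design per participant, and simulates each session. Per-participant seeds
#' are derived from `seed`, so the whole cohort is reproducible from
#' `(config, seed)` alone.
#'
#' @param config A `cohort_config`.
#' @param seed Integer master seed.
#' @param profiles Optional pre-sampled profile table (bypasses
#'   [sample_cohort_profiles()]).
#' @param design_args Named list of overrides for [generate_design()].
#' @return A list with `trials` (trial-log data.frame, one row per trial:
#'   `participant_id, group, trial_index, trial_type, stimulus_category,
#'   stimulus_id, ssd_ms, responded, rt_ms, correct`) and `participants`
#'   (the profile table).
#' @export
simulate_cohort <- function(config = default_cohort_config(), seed = 1L,
                            profiles = NULL, design_args = list()) {
  if (is.null(profiles))
    profiles <- sample_cohort_profiles(config, seed = seed)
  n <- nrow(profiles)
  sub_seeds <- with_seed(seed, matrix(sample.int(2147483646L, 2L * n), n))
  logs <- vector("list", n)
  for (i in seq_len(n)) {
    design <- do.call(generate_design,
                      c(list(seed = sub_seeds[i, 1L]), design_args))
    logs[[i]] <- simulate_session(profiles[i, , drop = FALSE], design,
                                  seed = sub_seeds[i, 2L])
  }
  n_each <- vapply(logs, nrow, integer(1L))
  pull <- function(col) unlist(lapply(logs, `[[`, col), use.names = FALSE)
  trials <- data.frame(
    participant_id = rep(profiles$id, n_each),
    group = rep(profiles$group, n_each),
    trial_index = pull("index"),
    trial_type = pull("trial_type"),
    stimulus_category = pull("stimulus_category"),
    stimulus_id = pull("stimulus_id"),
    ssd_ms = pull("ssd_ms"),
    responded = pull("responded"),
    rt_ms = pull("rt_ms"),
    correct = pull("correct"),
    stringsAsFactors = FALSE
  )
  list(trials = trials, participants = profiles)
}
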