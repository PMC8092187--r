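test_that("forced lapses behave as specified on single trials", {
  spec_go <- generate_design(8L, 0.25, seed = 1)
  spec_go <- spec_go[spec_go$trial_type == "go", ][1, ]
  st <- new_staircase()

  set.seed(1)
  res <- simulate_trial(make_profile(p_om = 1), spec_go, st)
  expect_false(res$responded)
  expect_true(is.na(res$rt_ms))

  set.seed(1)
  res <- simulate_trial(make_profile(p_err = 1), spec_go, st)
  expect_true(res$responded)
  expect_false(res$correct)
})

test_that("a stop that always wins the race yields a successful stop", {
  spec_stop <- generate_design(8L, 0.25, seed = 1)
  spec_stop <- spec_stop[spec_stop$trial_type == "stop", ][1, ]
  st <- new_staircase(start_ms = 50)  # minimal SSD; go_mu >> ssd + latency
  prof <- make_profile(go_mu = 5000, go_sigma = 0, go_tau = 0,
                       ssrt_mean = 100, ssrt_sd = 0)
  set.seed(2)
  res <- simulate_trial(prof, spec_stop, st)
  expect_false(res$responded)
  expect_true(res$correct)
  expect_true(is.na(res$rt_ms))
})

test_that("trial-level respond probability matches a Monte-Carlo race oracle", {
  prof <- make_profile(go_mu = 420, go_sigma = 50, go_tau = 120,
                       ssrt_mean = 280, ssrt_sd = 30)
  ssd <- 250
  spec_stop <- generate_design(8L, 0.25, seed = 1)
  spec_stop <- spec_stop[spec_stop$trial_type == "stop", ][1, ]
  st <- new_staircase(start_ms = ssd)

  set.seed(10)
  hits <- vapply(1:10000, function(i)
    simulate_trial(prof, spec_stop, st)$responded, logical(1))

  # independent oracle: P(T_go < SSD + T_stop) by direct draws, 1e6 each
  set.seed(11)
  n <- 1e6
  t_go <- pmax(rnorm(n, 420, 50) + rexp(n, 1 / 120), 1)
  u <- runif(n, pnorm(0, 280, 30), 1)
  t_stop <- qnorm(u, 280, 30)
  p_oracle <- mean(t_go < ssd + t_stop)

  expect_lt(abs(mean(hits) - p_oracle), 0.02)
})

test_that("cohort profiles match the configured population", {
  big <- default_cohort_config(n_gamified = 1000L, n_nongamified = 1000L)
  prof <- sample_cohort_profiles(big, seed = 5)
  expect_equal(nrow(prof), 2000L)
  expect_lt(abs(mean(prof$bmi >= 25) - 0.30), 0.03)
  expect_true(all(prof$bmi > 0))
  expect_true(all(prof$age >= 18))
  expect_true(all(prof$hunger >= 0 & prof$hunger <= 100))
  # additive calibration: group contrast of latent means near the configured
  # effects (age slope contributes through the group age difference)
  d_ssrt <- mean(prof$ssrt_true_mean[prof$group == "gamified"]) -
    mean(prof$ssrt_true_mean[prof$group == "nongamified"])
  expect_lt(abs(d_ssrt - (86 + 2 * (29.6 - 25.3))), 10)
  expect_identical(sample_cohort_profiles(seed = 7),
                   sample_cohort_profiles(seed = 7))
})

test_that("null configuration draws both groups from one population", {
  diffs <- vapply(1:40, function(s) {
    p <- sample_cohort_profiles(null_cohort_config(n_gamified = 30L,
                                                   n_nongamified = 30L),
                                seed = s)
    mean(p$ssrt_true_mean[p$group == "gamified"]) -
      mean(p$ssrt_true_mean[p$group == "nongamified"])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3.5 * se + 1e-9)
})

test_that("profile configuration errors are caught", {
  expect_error(sample_cohort_profiles(default_cohort_config(n_gamified = -1L)),
               "non-negative")
  expect_error(
    sample_cohort_profiles(default_cohort_config(p_overweight = 1.2)),
    "p_overweight")
  expect_error(default_cohort_config(not_a_field = 1), "unknown")
})

test_that("sessions thread the staircase: floor and ceiling are reachable", {
  design <- generate_design(256L, 0.25, seed = 4)
  # stop latency enormous: the go process always wins -> always responds
  always_responds <- make_profile(go_mu = 300, go_sigma = 20, go_tau = 50,
                                  ssrt_mean = 1e6, ssrt_sd = 0)
  s <- simulate_session(always_responds, design, seed = 8)
  ssd <- s$ssd_ms[s$trial_type == "stop" & s$stimulus_category == "food"]
  expect_true(all(diff(ssd) <= 0))
  expect_equal(min(ssd), 50)
  # go process hopeless: always stops successfully
  always_stops <- make_profile(go_mu = 1e6, go_sigma = 0, go_tau = 0,
                               ssrt_mean = 1, ssrt_sd = 0)
  s2 <- simulate_session(always_stops, design, seed = 8)
  ssd2 <- s2$ssd_ms[s2$trial_type == "stop" & s2$stimulus_category == "food"]
  expect_true(all(diff(ssd2) >= 0))
  expect_equal(max(ssd2), 900)
})

test_that("sessions are seed-deterministic", {
  design <- generate_design(64L, 0.25, seed = 5)
  prof <- make_profile()
  expect_identical(simulate_session(prof, design, seed = 9),
                   simulate_session(prof, design, seed = 9))
})

test_that("signal-respond RTs are censored below go RTs (race property)", {
  design <- generate_design(256L, 0.25, seed = 6)
  prof <- make_profile(p_om = 0.02, p_err = 0.02)
  viol <- 0L
  for (s in 1:40) {
    ses <- simulate_session(prof, design, seed = s)
    sr <- ses$rt_ms[ses$trial_type == "stop" & ses$responded]
    go <- ses$rt_ms[ses$trial_type == "go" & ses$responded]
    if (length(sr) >= 20 && mean(sr) >= mean(go)) viol <- viol + 1L
  }
  expect_lte(viol, 1L)
})

test_that("cohort simulation is reproducible and well-formed", {
  cfg <- default_cohort_config(n_gamified = 3L, n_nongamified = 3L)
  a <- simulate_cohort(cfg, seed = 12)
  b <- simulate_cohort(cfg, seed = 12)
  expect_identical(a, b)
  expect_equal(nrow(a$trials), 6L * 256L)
  expect_setequal(unique(a$trials$participant_id), a$participants$id)
  # stop trials with no response carry no RT; RTs are positive
  st <- a$trials[a$trials$trial_type == "stop" & !a$trials$responded, ]
  expect_true(all(is.na(st$rt_ms)))
  expect_true(all(a$trials$rt_ms[!is.na(a$trials$rt_ms)] > 0))
})
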