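test_that("overweight classification uses the BMI >= 25 threshold", {
  expect_true(classify_overweight(29.28))
  expect_false(classify_overweight(24.99))
  expect_true(classify_overweight(25.0))
  expect_error(classify_overweight(0), "positive")
  expect_error(classify_overweight(-3), "positive")
})

cohort_table <- function(seed, config = default_cohort_config()) {
  sim <- simulate_cohort(config, seed = seed)
  qc <- apply_exclusions(sim$trials, sim$participants)
  build_analysis_table(qc$estimates, qc$participants)
}

test_that("mixed model recovers a simulated condition effect on SSRT", {
  tab <- cohort_table(101)
  an <- fit_mixed_model(tab, "ssrt")
  expect_setequal(
    an$effect,
    c("age", "group", "overweight", "stimulus", "group:overweight",
      "group:stimulus", "overweight:stimulus", "group:overweight:stimulus"))
  expect_lt(an$p[an$effect == "group"], 0.05)
  means <- tapply(tab$ssrt_ms[tab$valid], tab$group[tab$valid], mean)
  expect_gt(means[["gamified"]], means[["nongamified"]])
  expect_true(all(an$p >= 0 & an$p <= 1, na.rm = TRUE))
})

test_that("degenerate designs are rejected with a named factor", {
  tab <- cohort_table(102)
  expect_error(fit_mixed_model(tab[tab$group == "gamified", ], "ssrt"),
               "'group'")
  const <- tab
  const$ssrt_ms <- 300
  expect_error(fit_mixed_model(const, "ssrt"), "degenerate response")
})

test_that("simulated effects are recovered with sign and magnitude", {
  # age slope silenced so the group contrast carries only the condition effect
  cfg <- default_cohort_config(age_slope_ssrt = 0)
  co <- vapply(1:12, function(s) {
    tab <- cohort_table(200 + s, cfg)
    d <- tab[tab$valid, ]
    fit <- lm(ssrt_ms ~ group + overweight + category, data = d)
    c(-coef(fit)[["groupnongamified"]], coef(fit)[["overweightTRUE"]])
  }, numeric(2))
  for (i in 1:2) {
    truth <- c(86, 35)[i]
    se <- sd(co[i, ]) / sqrt(ncol(co))
    expect_lt(abs(mean(co[i, ]) - truth), 3.5 * se + 5)
  }
})

test_that("BMI-SSRT correlation handles exact and degenerate inputs", {
  tab <- data.frame(participant_id = sprintf("P%d", 1:6),
                    group = "gamified", overweight = FALSE,
                    bmi = 20:25, age = 25, category = "food",
                    mean_go_rt_ms = 600, ssrt_ms = 300 + 10 * (20:25),
                    valid = TRUE, stringsAsFactors = FALSE)
  r <- bmi_ssrt_correlation(tab)
  expect_equal(r$r, 1.0)
  expect_equal(r$N, 6L)
  expect_error(bmi_ssrt_correlation(tab[1:3, ]), "at least 4")
  flat <- tab
  flat$ssrt_ms <- 42
  expect_error(bmi_ssrt_correlation(flat), "zero variance")
})

test_that("correlation CI covers zero at the nominal rate under the null", {
  # single-category sessions: one record per participant, so the Fisher CI's
  # independence assumption holds
  cfg <- null_cohort_config(n_gamified = 20L, n_nongamified = 20L)
  covered <- vapply(1:150, function(s) {
    sim <- simulate_cohort(cfg, seed = 3000 + s,
                           design_args = list(n_trials = 64L,
                                              categories = "food"))
    est <- estimate_cohort(sim$trials)
    tab <- build_analysis_table(est, sim$participants)
    ci <- bmi_ssrt_correlation(tab)$ci
    ci[1] <= 0 && ci[2] >= 0
  }, logical(1))
  expect_gt(mean(covered), 0.89)
  expect_lte(mean(covered), 1.0)
})

test_that("a positive BMI slope produces positive correlations", {
  cfg <- default_cohort_config(bmi_slope_ssrt = 4,
                               effect_overweight_ssrt = 0)
  rs <- vapply(1:5, function(s) {
    bmi_ssrt_correlation(cohort_table(400 + s, cfg))$r
  }, numeric(1))
  expect_gte(sum(rs > 0), 4L)
})

test_that("outlier sensitivity removes injected extremes and is idempotent", {
  tab <- cohort_table(103)
  clean <- outlier_sensitivity(tab)
  if (clean$n_outliers == 0)
    expect_equal(clean$r, bmi_ssrt_correlation(tab)$r)
  # inject a wild value: 10 SD above the mean
  spiked <- tab
  i <- which(spiked$valid)[1]
  spiked$ssrt_ms[i] <- mean(tab$ssrt_ms, na.rm = TRUE) +
    10 * sd(tab$ssrt_ms, na.rm = TRUE)
  sens <- outlier_sensitivity(spiked)
  expect_gte(sens$n_outliers, 1L)
  expect_equal(sens$N, sum(spiked$valid & is.finite(spiked$ssrt_ms)) -
                 sens$n_outliers)
  r_clean <- bmi_ssrt_correlation(tab)$r
  expect_lt(abs(sens$r - r_clean), abs(bmi_ssrt_correlation(spiked)$r - r_clean) + 0.05)
  expect_error(outlier_sensitivity(tab, rule = function(x) rep(TRUE, length(x))),
               "every record")
})

test_that("exact and Fisher power routes bracket the textbook example", {
  expect_equal(required_n_correlation(0.35, 0.05, 0.80, "one", "exact"), 49L)
  expect_equal(required_n_correlation(0.35, 0.05, 0.80, "one", "fisher"), 50L)
  # boundary behaviour of the search
  expect_gte(correlation_power(49, 0.35, 0.05, "one"), 0.80)
  expect_lt(correlation_power(48, 0.35, 0.05, "one"), 0.80)
  # a near-perfect correlation needs only the method floor
  expect_equal(required_n_correlation(0.999, 0.05, 0.80, "one"), 4L)
  # two-sided tests need more samples; power is monotone in n
  expect_gt(required_n_correlation(0.35, 0.05, 0.80, "two"),
            required_n_correlation(0.35, 0.05, 0.80, "one"))
  expect_error(required_n_correlation(1.2), "rho")
  expect_error(required_n_correlation(0.35, alpha = 0), "alpha")
  expect_error(required_n_correlation(0.01, power = 0.999, n_max = 50L),
               "unattainable")
})

test_that("between-subject F tests match a split-plot oracle to 6 decimals", {
  # dual route: on balanced data (both categories valid per subject) the
  # mixed model's between-subject stratum must reproduce, exactly, the
  # sequential ANOVA of the per-subject means — an independent lm route
  for (seed in c(501, 502, 503)) {
    tab <- cohort_table(seed)
    n_ok <- with(tab, tapply(valid, participant_id, sum))
    tb <- tab[tab$participant_id %in% names(n_ok)[n_ok == 2] & tab$valid, ]
    an <- fit_mixed_model(tb, "ssrt")
    expect_equal(nrow(an), 8L)
    expect_true(all(is.finite(an$F)))

    agg <- aggregate(ssrt_ms ~ participant_id + group + overweight + age,
                     tb, mean)
    oracle <- anova(lm(ssrt_ms ~ age + group * overweight, data = agg))
    for (term in c("age", "group", "overweight", "group:overweight")) {
      expect_equal(an$F[an$effect == term], oracle[term, "F value"],
                   tolerance = 1e-8, label = paste("F", term, seed))
      expect_equal(an$p[an$effect == term], oracle[term, "Pr(>F)"],
                   tolerance = 1e-6, label = paste("p", term, seed))
      expect_equal(an$denDF[an$effect == term], oracle["Residuals", "Df"])
    }
  }
})
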