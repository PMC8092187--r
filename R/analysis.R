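# Cohort-level statistics: overweight classification, mixed-effects models of
# go RT and SSRT, BMI-SSRT correlation with outlier sensitivity.

#' Overweight classification from BMI
#'
#' @param bmi Body-mass index, kg/m^2; must be positive.
#' @return `TRUE` iff `bmi >= 25`.
#' @export
classify_overweight <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("`bmi` must be positive and finite", call. = FALSE)
  bmi >= 25
}

#' Build the participant x category analysis table
#'
#' Joins QC'd SSRT estimates with participant covariates into the long table
#' the models consume: one record per participant and stimulus category.
#'
#' @param estimates An [estimate_cohort()] table (typically the `estimates`
#'   element of [apply_exclusions()]).
#' @param participants Participant table keyed by `id` with `group`, `bmi`,
#'   `age`.
#' @return A data.frame: `participant_id`, `group`, `overweight`, `bmi`,
#'   `age`, `category`, `mean_go_rt_ms`, `ssrt_ms`, `valid`.
#' @export
build_analysis_table <- function(estimates, participants) {
  idx <- match(estimates$participant_id, participants$id)
  if (any(is.na(idx)))
    stop("estimates reference participants absent from the participant table",
         call. = FALSE)
  data.frame(
    participant_id = estimates$participant_id,
    group = participants$group[idx],
    overweight = classify_overweight(participants$bmi[idx]),
    bmi = participants$bmi[idx],
    age = participants$age[idx],
    category = estimates$category,
    mean_go_rt_ms = estimates$mean_go_rt_ms,
    ssrt_ms = estimates$ssrt_ms,
    valid = estimates$valid,
    stringsAsFactors = FALSE
  )
}

#' Linear mixed-effects model of go RT or SSRT
#'
#' Fits the repeated-measures model `value ~ age + group * overweight *
#' stimulus` with a random intercept per participant (via [nlme::lme()]),
#' where `stimulus` is the within-subject category factor and `group` /
#' `overweight` are between-subject factors and `age` a continuous covariate.
#' Only records with `valid = TRUE` and a finite response enter; the model
#' tolerates unbalanced data (participants missing one category).
#' Denominator degrees of freedom follow nlme's containment convention.
#'
#' @param table A [build_analysis_table()] data.frame.
#' @param response `"ssrt"` (uses `ssrt_ms`) or `"go_rt"`
#'   (uses `mean_go_rt_ms`).
#' @return A data.frame of F-tests: `effect`, `numDF`, `denDF`, `F`, `p`.
#' @export
fit_mixed_model <- function(table, response = c("ssrt", "go_rt")) {
  response <- match.arg(response)
  value <- if (response == "ssrt") table$ssrt_ms else table$mean_go_rt_ms
  d <- data.frame(
    value = value,
    age = table$age,
    group = factor(table$group),
    overweight = factor(ifelse(table$overweight, "overweight", "normal")),
    stimulus = factor(table$category),
    participant_id = table$participant_id,
    stringsAsFactors = FALSE
  )
  d <- d[table$valid & is.finite(d$value), , drop = FALSE]
  for (f in c("group", "overweight", "stimulus")) {
    d[[f]] <- droplevels(d[[f]])
    if (nlevels(d[[f]]) < 2L)
      stop("degenerate design: factor '", f,
           "' has fewer than two levels after filtering", call. = FALSE)
  }
  if (stats::var(d$value) == 0)
    stop("degenerate response: '", response, "' values are constant",
         call. = FALSE)
  fit <- nlme::lme(value ~ age + group * overweight * stimulus,
                   random = ~ 1 | participant_id, data = d,
                   na.action = stats::na.omit)
  tab <- anova(fit)
  out <- data.frame(effect = rownames(tab), numDF = tab$numDF,
                    denDF = tab$denDF, F = tab$`F-value`,
                    p = tab$`p-value`, stringsAsFactors = FALSE)
  out <- out[out$effect != "(Intercept)", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "model") <- fit
  out
}

#' Product-moment correlation between BMI and SSRT
#'
#' Correlates BMI with SSRT over all valid participant x category records,
#' with a 95% CI by the Fisher z transform. N counts records, not
#' participants, and is reported explicitly.
#'
#' @param table A [build_analysis_table()] data.frame.
#' @param conf_level Confidence level (default 0.95).
#' @return A list (class `sst_correlation`): `r`, `ci` (length 2), `N`, `p`.
#' @export
bmi_ssrt_correlation <- function(table, conf_level = 0.95) {
  d <- table[table$valid & is.finite(table$ssrt_ms), , drop = FALSE]
  if (nrow(d) < 4L)
    stop("need at least 4 valid records for a correlation", call. = FALSE)
  if (stats::var(d$bmi) == 0 || stats::var(d$ssrt_ms) == 0)
    stop("zero variance in BMI or SSRT: correlation undefined",
         call. = FALSE)
  ct <- cor.test(d$bmi, d$ssrt_ms, conf.level = conf_level)
  structure(list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
                 N = nrow(d), p = ct$p.value),
            class = "sst_correlation")
}

#' @export
print.sst_correlation <- function(x, ...) {
  cat(sprintf("r = %.3f, 95%% CI [%.3f, %.3f], N = %d, p = %.4g\n",
              x$r, x$ci[1], x$ci[2], x$N, x$p))
  invisible(x)
}

#' Median +/- k MAD outlier rule
#'
#' @param k Multiplier on the median absolute deviation (default 3).
#' @return A function mapping a numeric vector to a logical is-outlier
#'   vector.
#' @export
mad_outlier_rule <- function(k = 3) {
  force(k)
  function(x) {
    m <- median(x, na.rm = TRUE)
    s <- mad(x, na.rm = TRUE)
    if (s == 0) return(rep(FALSE, length(x)))
    abs(x - m) > k * s
  }
}

#' BMI-SSRT correlation after outlier removal
#'
#' Sensitivity analysis: recomputes [bmi_ssrt_correlation()] after dropping
#' records whose SSRT an outlier rule flags. The default rule (median +/- 3
#' MAD) replaces the irreproducible "visual inspection" criterion.
#'
#' @param table A [build_analysis_table()] data.frame.
#' @param rule Function from SSRT values to a logical is-outlier vector.
#' @param conf_level Confidence level.
#' @return An `sst_correlation` with an extra `n_outliers` element.
#' @export
outlier_sensitivity <- function(table, rule = mad_outlier_rule(3),
                                conf_level = 0.95) {
  d <- table[table$valid & is.finite(table$ssrt_ms), , drop = FALSE]
  out <- rule(d$ssrt_ms)
  if (all(out))
    stop("outlier rule removed every record", call. = FALSE)
  res <- bmi_ssrt_correlation(d[!out, , drop = FALSE], conf_level)
  res$n_outliers <- sum(out)
  res
}
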