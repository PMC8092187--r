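# Participant-level quality control preceding analysis.
#
# Three participant-level rules (missing behavioural data, implausible
# self-reported height, stopping probability outside the 25-75% band in any
# condition) drop the whole participant; a race-model violation (mean
# signal-respond RT at or above mean go RT) rejects only the affected
# per-category SSRT value.

#' Default QC configuration
#'
#' @param pstop_lower,pstop_upper Inclusive bounds on the stopping
#'   probability `1 - p(respond | signal)` (defaults 0.25 / 0.75; boundary
#'   values are compliant).
#' @param height_lower_cm,height_upper_cm Plausible adult height bounds for
#'   self-report screening (defaults 147 / 200 cm).
#' @return A named list (class `qc_config`).
#' @export
qc_config <- function(pstop_lower = 0.25, pstop_upper = 0.75,
                      height_lower_cm = 147, height_upper_cm = 200) {
  structure(list(pstop_lower = pstop_lower, pstop_upper = pstop_upper,
                 height_lower_cm = height_lower_cm,
                 height_upper_cm = height_upper_cm),
            class = c("qc_config", "list"))
}

#' Stopping-probability range check
#'
#' Flags an estimate whose stopping probability `1 - p(respond | signal)`
#' falls strictly outside the band (default the 25-75% interquartile
#' interval); boundary values comply.
#'
#' @param estimate A one-row [integration_ssrt()] result.
#' @param config A [qc_config()].
#' @return `TRUE` if the estimate violates the rule.
#' @export
check_pstop <- function(estimate, config = qc_config()) {
  p_stop <- 1 - estimate$p_respond_signal
  p_stop < config$pstop_lower | p_stop > config$pstop_upper
}

#' Race-model plausibility check
#'
#' Under the independent race model, signal-respond RTs are censored go RTs
#' and their mean must fall below the mean go RT. The flag is carried per
#' category; categories with no signal-respond trials are not evaluable and
#' pass with a warning.
#'
#' @param estimate A one-row (or multi-row) [integration_ssrt()] /
#'   [estimate_cohort()] result.
#' @return Logical vector, `TRUE` where the race assumption is violated.
#' @export
check_race_assumption <- function(estimate) {
  msr <- estimate$mean_signal_respond_rt_ms
  if (any(is.na(msr)))
    warning("no signal-respond trials in ", sum(is.na(msr)),
            " record(s); race assumption not evaluable, treated as compliant",
            call. = FALSE)
  !is.na(msr) & msr >= estimate$mean_go_rt_ms
}

#' Apply participant-level exclusions
#'
#' Computes (or accepts) SSRT estimates, evaluates all QC rules and returns
#' the cleaned cohort. Participants are removed for missing behavioural data,
#' implausible height, or a stopping probability outside the band in any
#' category; race-model violations invalidate the affected per-category value
#' only.
#'
#' @param trials Cohort trial log.
#' @param participants Participant table keyed by `id`; an optional
#'   `height_cm` column feeds the height rule.
#' @param config A [qc_config()].
#' @param estimates Optional precomputed [estimate_cohort()] table.
#' @return A list: `estimates` (rows of included participants; race-violating
#'   rows have `valid = FALSE`), `participants` (included rows), `flags`
#'   (per-participant flag table), `report` (counts per exclusion reason).
#' @export
apply_exclusions <- function(trials, participants, config = qc_config(),
                             estimates = NULL) {
  if (!all(unique(trials$participant_id) %in% participants$id))
    stop("trial log contains participant ids absent from the participant ",
         "table", call. = FALSE)

  ids <- participants$id
  has_behavior <- ids %in% trials$participant_id
  if (is.null(estimates) && any(has_behavior))
    estimates <- estimate_cohort(
      trials[trials$participant_id %in% ids[has_behavior], , drop = FALSE])

  height <- if ("height_cm" %in% names(participants))
    participants$height_cm else rep(NA_real_, length(ids))
  implausible_height <- !is.na(height) &
    (height < config$height_lower_cm | height > config$height_upper_cm)

  pstop_viol <- vapply(ids, function(id) {
    est <- estimates[estimates$participant_id == id, , drop = FALSE]
    nrow(est) > 0L && any(check_pstop(est, config))
  }, logical(1L))

  race_flags <- withCallingHandlers(
    check_race_assumption(estimates),
    warning = function(w) invokeRestart("muffleWarning"))

  flags <- data.frame(
    participant_id = ids,
    missing_behavior = !has_behavior,
    implausible_height = implausible_height,
    pstop_out_of_range = pstop_viol,
    race_violation = vapply(ids, function(id)
      any(race_flags[estimates$participant_id == id]), logical(1L)),
    stringsAsFactors = FALSE
  )
  flags$included <- !(flags$missing_behavior | flags$implausible_height |
                        flags$pstop_out_of_range)

  keep_ids <- ids[flags$included]
  est_out <- estimates[estimates$participant_id %in% keep_ids, , drop = FALSE]
  race_out <- race_flags[estimates$participant_id %in% keep_ids]
  est_out$valid <- est_out$valid & !race_out
  est_out$race_violation <- race_out

  report <- list(
    n_total = length(ids),
    n_missing_behavior = sum(flags$missing_behavior),
    n_implausible_height = sum(flags$implausible_height),
    n_pstop_excluded = sum(flags$pstop_out_of_range & !flags$missing_behavior &
                             !flags$implausible_height),
    n_race_values_rejected = sum(race_out),
    n_included = sum(flags$included)
  )

  list(estimates = est_out,
       participants = participants[flags$included, , drop = FALSE],
       flags = flags, report = report)
}
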