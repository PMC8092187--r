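# Integration-method SSRT estimation, per stimulus category.
#
# SSRT = nth go RT - mean SSD, where the nth go RT is the go-RT quantile at
# the probability of responding given a stop-signal (rank ceil(p * n_go),
# 1-based, no interpolation) and go omissions are replaced by the
# participant's maximum observed go RT before ranking. Mean SSD averages over
# all stop trials of the category.

.trials_for <- function(trials, category) {
  trials[trials$stimulus_category == category, , drop = FALSE]
}

#' Probability of responding given a stop-signal
#'
#' Fraction of a category's stop trials on which any response was recorded;
#' premature responses count as responses.
#'
#' @param trials Trial-level results for one participant (trial-log columns).
#' @param category Stimulus category.
#' @return A proportion in `[0, 1]`.
#' @export
p_respond_given_signal <- function(trials, category) {
  st <- .trials_for(trials, category)
  st <- st[st$trial_type == "stop", , drop = FALSE]
  if (nrow(st) == 0L)
    stop("no stop trials in category '", category, "'", call. = FALSE)
  mean(st$responded)
}

#' Ordered go-RT distribution with omission replacement
#'
#' Collects all go-trial RTs of a category (correct and choice-error
#' responses alike), replaces each go omission by the participant's maximum
#' observed go RT, and returns the vector sorted ascending.
#'
#' @inheritParams p_respond_given_signal
#' @return Sorted numeric vector of length `n_go`.
#' @export
go_rt_vector <- function(trials, category) {
  gt <- .trials_for(trials, category)
  gt <- gt[gt$trial_type == "go", , drop = FALSE]
  rts <- gt$rt_ms[gt$responded]
  n_om <- sum(!gt$responded)
  if (length(rts) == 0L)
    stop("all go trials omitted in category '", category,
         "': go-RT distribution undefined", call. = FALSE)
  sort(c(rts, rep(max(rts), n_om)))
}

#' Integration-method SSRT estimate for one category
#'
#' Computes `p(respond | signal)`, the go-RT quantile at that probability
#' (rank `ceil(p * n_go)`, 1-based), the mean SSD over all the category's
#' stop trials, and their difference, the SSRT. Estimates with
#' `p(respond | signal)` of exactly 0 or 1 are flagged invalid (the staircase
#' failed to bracket the race), with the SSRT undefined at p = 0.
#'
#' @inheritParams p_respond_given_signal
#' @return A one-row data.frame: `category`, `p_respond_signal`,
#'   `mean_ssd_ms`, `nth_go_rt_ms`, `ssrt_ms`, `mean_go_rt_ms`,
#'   `mean_signal_respond_rt_ms`, `n_go`, `n_stop`, `n_go_omissions`,
#'   `valid`.
#' @examples
#' d <- generate_design(n_trials = 16, seed = 2)
#' prof <- sample_cohort_profiles(default_cohort_config(
#'   n_gamified = 1, n_nongamified = 0), seed = 2)
#' s <- simulate_session(prof, d, seed = 3)
#' integration_ssrt(s, "food")
#' @export
integration_ssrt <- function(trials, category) {
  out <- .integration_core(trials, category)
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.integration_core <- function(trials, category) {
  in_cat <- trials$stimulus_category == category
  is_stop <- in_cat & trials$trial_type == "stop"
  is_go <- in_cat & trials$trial_type == "go"
  if (!any(is_stop))
    stop("no stop trials in category '", category, "'", call. = FALSE)
  st_resp <- trials$responded[is_stop]
  go_resp <- trials$responded[is_go]
  rts <- trials$rt_ms[is_go][go_resp]
  if (length(rts) == 0L)
    stop("all go trials omitted in category '", category,
         "': go-RT distribution undefined", call. = FALSE)

  p <- mean(st_resp)
  g <- sort(c(rts, rep(max(rts), sum(!go_resp))))
  n_go_total <- length(g)
  mean_ssd <- mean(trials$ssd_ms[is_stop])
  rank <- ceiling(p * n_go_total)
  nth <- if (rank >= 1L) g[rank] else NA_real_
  srrt <- trials$rt_ms[is_stop][st_resp]

  list(
    category = category,
    p_respond_signal = p,
    mean_ssd_ms = mean_ssd,
    nth_go_rt_ms = nth,
    ssrt_ms = if (is.na(nth)) NA_real_ else nth - mean_ssd,
    mean_go_rt_ms = mean(rts),
    mean_signal_respond_rt_ms =
      if (length(srrt)) mean(srrt) else NA_real_,
    n_go = n_go_total,
    n_stop = sum(is_stop),
    n_go_omissions = sum(!go_resp),
    valid = p > 0 && p < 1
  )
}

#' SSRT estimates for every participant and category in a trial log
#'
#' @param trials A cohort trial log (columns `participant_id`, `group`,
#'   `trial_type`, `stimulus_category`, `ssd_ms`, `responded`, `rt_ms`).
#' @return A data.frame of [integration_ssrt()] rows with `participant_id`
#'   and `group` prepended, one row per participant x category.
#' @export
estimate_cohort <- function(trials) {
  if (nrow(trials) == 0L)
    stop("empty trial log: nothing to estimate", call. = FALSE)
  cats <- unique(trials$stimulus_category)
  idx <- split(seq_len(nrow(trials)), trials$participant_id)
  m <- length(idx) * length(cats)
  out <- list(participant_id = character(m), group = character(m),
              category = character(m), p_respond_signal = numeric(m),
              mean_ssd_ms = numeric(m), nth_go_rt_ms = numeric(m),
              ssrt_ms = numeric(m), mean_go_rt_ms = numeric(m),
              mean_signal_respond_rt_ms = numeric(m), n_go = integer(m),
              n_stop = integer(m), n_go_omissions = integer(m),
              valid = logical(m))
  k <- 0L
  for (ix in idx) {
    # light per-participant view; integration_ssrt only touches these columns
    tr <- list(trial_type = trials$trial_type[ix],
               stimulus_category = trials$stimulus_category[ix],
               ssd_ms = trials$ssd_ms[ix],
               responded = trials$responded[ix],
               rt_ms = trials$rt_ms[ix])
    for (ct in cats) {
      k <- k + 1L
      est <- .integration_core(tr, ct)
      out$participant_id[k] <- trials$participant_id[ix[1L]]
      out$group[k] <- trials$group[ix[1L]]
      for (col in names(est)) out[[col]][k] <- est[[col]]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
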