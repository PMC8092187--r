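# File-based pipeline: CSV/JSON schemas, run configuration, orchestration.
# Every artifact round-trips losslessly through its reader/writer pair, and a
# full run is a pure function of (config, seed).

.TRIAL_COLS <- c("participant_id", "group", "trial_index", "trial_type",
                 "stimulus_category", "stimulus_id", "ssd_ms", "responded",
                 "rt_ms", "correct")
.EST_COLS <- c("participant_id", "group", "category", "p_respond_signal",
               "mean_ssd_ms", "nth_go_rt_ms", "ssrt_ms", "mean_go_rt_ms",
               "mean_signal_respond_rt_ms", "n_go", "n_stop",
               "n_go_omissions", "valid")

.read_csv_checked <- function(file) {
  tryCatch(read.csv(file, stringsAsFactors = FALSE),
           error = function(e)
             stop("schema violation in '", file, "': ",
                  conditionMessage(e), call. = FALSE))
}

.check_schema <- function(df, cols, file, min_rows = 1L) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema violation in '", file, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) < min_rows)
    stop("schema violation in '", file, "': no data rows", call. = FALSE)
  invisible(df)
}

#' Read / write a trial log
#'
#' One row per trial: `participant_id, group, trial_index, trial_type,
#' stimulus_category, stimulus_id, ssd_ms, responded, rt_ms, correct`.
#'
#' @param trials Trial-log data.frame.
#' @param file Path to a CSV file.
#' @return `read_trial_log()` returns the validated data.frame;
#'   `write_trial_log()` returns `file` invisibly.
#' @export
write_trial_log <- function(trials, file) {
  write.csv(trials[, .TRIAL_COLS], file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(file) {
  df <- .read_csv_checked(file)
  .check_schema(df, .TRIAL_COLS, file)
  df
}

#' Read / write a participant table
#'
#' @param participants Participant data.frame (keyed by `id`).
#' @param file Path to a CSV file.
#' @param latent Keep latent truth columns (`go_mu`, `ssrt_true_mean`, ...)
#'   when writing? Default `TRUE`; set `FALSE` to emit observables only.
#' @return The table (reader) or `file` invisibly (writer).
#' @export
write_participants <- function(participants, file, latent = TRUE) {
  df <- participants
  if (!latent) {
    drop <- c("go_mu", "go_sigma", "go_tau", "ssrt_true_mean", "ssrt_true_sd",
              "p_go_omission", "p_choice_error")
    df <- df[, setdiff(names(df), drop), drop = FALSE]
  }
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_participants
#' @export
read_participants <- function(file) {
  df <- .read_csv_checked(file)
  .check_schema(df, c("id", "group", "bmi", "age"), file)
  df
}

#' Read / write an SSRT estimates table
#'
#' @param estimates An [estimate_cohort()] data.frame.
#' @param file Path to a CSV file.
#' @return The table (reader) or `file` invisibly (writer).
#' @export
write_estimates <- function(estimates, file) {
  write.csv(estimates[, intersect(c(.EST_COLS, "race_violation"),
                                  names(estimates))],
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(file) {
  df <- .read_csv_checked(file)
  .check_schema(df, .EST_COLS, file)
  df
}

#' Assemble a run configuration
#'
#' A run configuration bundles the design parameters, the generative cohort
#' configuration, the QC bounds and analysis options; together with a seed it
#' fully determines a pipeline run. Serializable to JSON via
#' [write_run_config()].
#'
#' @param design Named list of [generate_design()] overrides (e.g.
#'   `n_trials`, `p_stop`).
#' @param cohort A `cohort_config`.
#' @param qc A [qc_config()].
#' @param outlier_k MAD multiplier for the correlation sensitivity analysis.
#' @param seed Integer master seed.
#' @return A named list (class `run_config`).
#' @export
run_config <- function(design = list(), cohort = default_cohort_config(),
                       qc = qc_config(), outlier_k = 3, seed = 1L) {
  structure(list(design = design, cohort = unclass(cohort),
                 qc = unclass(qc), outlier_k = outlier_k,
                 seed = as.integer(seed)),
            class = c("run_config", "list"))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param file Path to a JSON file.
#' @export
write_run_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname run_config
#' @export
read_run_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  run_config(design = as.list(x$design),
             cohort = do.call(default_cohort_config, as.list(x$cohort)[
               names(x$cohort) %in% names(default_cohort_config())]),
             qc = do.call(qc_config, as.list(x$qc)),
             outlier_k = x$outlier_k, seed = x$seed)
}

# order-stable FNV-1a hash of the JSON serialization, for run provenance
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # h * 16777619 mod 2^32 without exceeding double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Run the full pipeline
#'
#' Simulate a cohort, estimate SSRTs, apply QC, fit both mixed models,
#' compute the BMI-SSRT correlation with its outlier sensitivity, and (when
#' `out_dir` is given) write every artifact: trial log, participant table,
#' estimates, QC report and a JSON analysis report carrying the seed and a
#' configuration hash.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   file output.
#' @param verbose Print progress.
#' @return A list: `trials`, `participants`, `estimates`, `qc`, `table`,
#'   `anova_go_rt`, `anova_ssrt`, `correlation`, `sensitivity`, `report`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  cohort_cfg <- do.call(default_cohort_config, config$cohort)
  say("simulating cohort (seed ", config$seed, ")")
  sim <- simulate_cohort(cohort_cfg, seed = config$seed,
                         design_args = config$design)
  say("estimating SSRTs")
  est <- estimate_cohort(sim$trials)
  say("applying QC")
  qc <- apply_exclusions(sim$trials, sim$participants,
                         config = do.call(qc_config, config$qc),
                         estimates = est)
  tab <- build_analysis_table(qc$estimates, qc$participants)
  say("fitting models")
  an_go <- fit_mixed_model(tab, "go_rt")
  an_ssrt <- fit_mixed_model(tab, "ssrt")
  corr <- bmi_ssrt_correlation(tab)
  sens <- outlier_sensitivity(tab, mad_outlier_rule(config$outlier_k))

  report <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    qc = qc$report,
    anova_go_rt = an_go, anova_ssrt = an_ssrt,
    correlation = unclass(corr)[c("r", "ci", "N", "p")],
    sensitivity = unclass(sens)[c("r", "ci", "N", "p", "n_outliers")],
    group_means = aggregate(
      cbind(mean_go_rt_ms, ssrt_ms) ~ group, data = tab[tab$valid, ], mean)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
      stop("cannot create output directory '", out_dir, "'", call. = FALSE)
    write_run_config(config, file.path(out_dir, "config.json"))
    write_trial_log(sim$trials, file.path(out_dir, "trials.csv"))
    write_participants(sim$participants,
                       file.path(out_dir, "participants.csv"))
    write_estimates(qc$estimates, file.path(out_dir, "estimates.csv"))
    write.csv(qc$flags, file.path(out_dir, "qc_flags.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(tab, file.path(out_dir, "analysis_table.csv"),
              row.names = FALSE, quote = FALSE)
    report_json <- report
    report_json$anova_go_rt <- an_go
    report_json$anova_ssrt <- an_ssrt
    jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
    say("artifacts written to ", out_dir)
  }

  invisible(list(trials = sim$trials, participants = sim$participants,
                 estimates = qc$estimates, qc = qc, table = tab,
                 anova_go_rt = an_go, anova_ssrt = an_ssrt,
                 correlation = corr, sensitivity = sens, report = report))
}
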