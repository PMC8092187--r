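# Independent oracles and fixture builders. Oracle code is deliberately
# naive and shares nothing with the package's estimation path.

# brute-force integration-method SSRT: literal sort / rank / mean arithmetic
oracle_ssrt <- function(trials, category) {
  tr <- trials[trials$stimulus_category == category, , drop = FALSE]
  go <- tr[tr$trial_type == "go", , drop = FALSE]
  st <- tr[tr$trial_type == "stop", , drop = FALSE]
  p <- sum(st$responded) / nrow(st)
  obs <- go$rt_ms[go$responded]
  vec <- c(obs, rep(max(obs), times = sum(!go$responded)))
  vec <- vec[order(vec)]
  mean_ssd <- sum(st$ssd_ms) / nrow(st)
  r <- ceiling(p * length(vec))
  nth <- if (r >= 1) vec[r] else NA_real_
  list(p = p, mean_ssd = mean_ssd, nth = nth,
       ssrt = if (is.na(nth)) NA_real_ else nth - mean_ssd)
}

# hand-assembled single-participant, single-category session
fixture_session <- function(go_rts, stop_ssd, stop_rt,
                            category = "food", id = "P1") {
  go <- data.frame(
    participant_id = id, group = "nongamified",
    trial_index = seq_along(go_rts) - 1L, trial_type = "go",
    stimulus_category = category, stimulus_id = "pizza",
    ssd_ms = NA_real_, responded = !is.na(go_rts), rt_ms = go_rts,
    correct = !is.na(go_rts), stringsAsFactors = FALSE)
  st <- data.frame(
    participant_id = id, group = "nongamified",
    trial_index = length(go_rts) + seq_along(stop_ssd) - 1L,
    trial_type = "stop", stimulus_category = category,
    stimulus_id = "pizza", ssd_ms = stop_ssd,
    responded = !is.na(stop_rt), rt_ms = stop_rt,
    correct = is.na(stop_rt), stringsAsFactors = FALSE)
  rbind(go, st)
}

# random small session over both categories (omissions, ties, boundary p)
random_session <- function(seed) {
  set.seed(seed)
  out <- list()
  for (cat in c("food", "control")) {
    n_go <- sample(4:25, 1)
    n_stop <- sample(2:10, 1)
    go_rts <- round(runif(n_go, 300, 900), 1)
    go_rts[runif(n_go) < 0.15] <- NA  # omissions
    if (all(is.na(go_rts))) go_rts[1] <- 500
    resp <- runif(n_stop) < runif(1, 0.1, 0.9)  # includes p = 0 and p = 1
    stop_rt <- ifelse(resp, round(runif(n_stop, 250, 800), 1), NA)
    out[[cat]] <- fixture_session(go_rts, 50 * sample(1:18, n_stop, TRUE),
                                  stop_rt, category = cat)
  }
  do.call(rbind, out)
}

# single-row profile with direct control over the latent parameters
make_profile <- function(go_mu = 450, go_sigma = 60, go_tau = 150,
                         ssrt_mean = 300, ssrt_sd = 30,
                         p_om = 0, p_err = 0, group = "nongamified",
                         bmi = 22, age = 25, id = "P1") {
  data.frame(id = id, group = group, bmi = bmi, age = age, gender = "female",
             height_cm = 170, debq_restrained = 17, debq_emotional = 21,
             debq_external = 23, hunger = 38,
             go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
             ssrt_true_mean = ssrt_mean, ssrt_true_sd = ssrt_sd,
             p_go_omission = p_om, p_choice_error = p_err,
             stringsAsFactors = FALSE)
}
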