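# Independent oracles and small fixture builders.

# Written-out Cox log partial likelihood (Breslow ties) for one covariate on
# counting-process rows: risk set of an event at day t is {j : start_j < t
# <= stop_j}. Independent of the fitting path (used with optimize()).
oracle_cox_loglik <- function(beta, start, stop, event, x) {
  days <- sort(unique(stop[event == 1]))
  ll <- 0
  for (t in days) {
    ev <- event == 1 & stop == t
    risk <- start < t & t <= stop
    ll <- ll + sum(x[ev]) * beta - sum(ev) * log(sum(exp(x[risk] * beta)))
  }
  ll
}

oracle_cox_mle <- function(start, stop, event, x, interval = c(-10, 10)) {
  stats::optimize(function(b) oracle_cox_loglik(b, start, stop, event, x),
                  interval, maximum = TRUE, tol = 1e-10)$maximum
}

# Definition-level AUC: double loop over all case-control pairs, ties 1/2.
oracle_auc <- function(cases, controls) {
  wins <- 0
  for (a in cases) for (b in controls)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(cases) * length(controls))
}

# One-landmark stacked data frame around a single covariate named x.
toy_stacked <- function(start, stop, event, x, landmark = 1L) {
  structure(data.frame(recruit_id = seq_along(stop), landmark = landmark,
                       start = start, stop = stop, event = event, x = x),
            terms = "x", tv_items = character(0), coding = "s_minus_1",
            duration_weeks = 24L, class = c("stacked_landmarks", "data.frame"))
}

# lp table + outcomes realizing given case/control score sets at day t with
# window 7: cases drop exactly at day t, controls complete training.
toy_eval <- function(case_lp, control_lp, t = 28) {
  n1 <- length(case_lp); n0 <- length(control_lp)
  ids <- seq_len(n1 + n0)
  outcomes <- data.frame(
    recruit_id = ids,
    time = c(rep(t, n1), rep(168L, n0)),
    status = c(rep(1L, n1), rep(0L, n0)))
  lps <- data.frame(recruit_id = ids, landmark = 3L,
                    lp = c(case_lp, control_lp))
  list(lps = lps, outcomes = outcomes)
}

# Small simulated cohort + its preprocessed form, cached per call site.
sim_clean <- function(n = 250, seed = 7L, ...) {
  cfg <- generator_config(n_recruits = n, seed = seed, ...)
  cohort <- simulate_cohort(cfg)
  list(config = cfg, cohort = cohort, clean = preprocess_cohort(cohort))
}
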