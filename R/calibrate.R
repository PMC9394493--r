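# Calibration of the weekly base hazard.
#
# The default base hazard is geometric, h0_w = a * r^(w-1), with (a, r)
# solved once so that, under the default generator configuration, the
# expected total dropout fraction is 54.8% and the expected share of
# dropouts occurring in the first four weeks is 22%. Both expectations are
# exact functions of the simulated covariate population (no event noise):
# a recruit's dropout probability by week w is 1 - prod_{v<=w}(1 - p_v) with
# p_v = 1 - exp(-h0_v exp(LP_v)). The calibrated pair below ships as the
# package default; analysis/00_calibrate_hazard.R re-derives it.

.calibrated_base <- list(a = 0.082822509795159746, r = 0.9873602407717017)

#' Default calibrated weekly base hazard
#'
#' Geometric weekly base hazard with scale and decay calibrated to the
#' cohort-level dropout targets (54.8% overall, 22% of dropouts within four
#' weeks) under the default generator configuration.
#'
#' @param duration_weeks number of weeks (default 24).
#' @return numeric vector of length `duration_weeks`.
#' @export
default_base_hazard <- function(duration_weeks = 24L) {
  .calibrated_base$a * .calibrated_base$r^(seq_len(duration_weeks) - 1)
}

# Expected total dropout fraction and early (first 4 weeks) share of
# dropouts for base hazard a * r^(w-1), given the exp(LP) matrix.
expected_dropout <- function(elp, a, r, early_weeks = 4L) {
  W <- ncol(elp)
  base <- a * r^(seq_len(W) - 1)
  q <- exp(-sweep(elp, 2, base, `*`))          # 1 - p_w, recruits x weeks
  surv <- t(apply(q, 1, cumprod))
  total <- mean(1 - surv[, W])
  early <- mean(1 - surv[, early_weeks]) / total
  c(total = total, early = early)
}

#' Calibrate the geometric base hazard to cohort dropout targets
#'
#' Solves (a, r) of h0_w = a * r^(w-1) by nested root finding on the exact
#' expected-dropout equations over a large simulated covariate population:
#' the inner root sets the scale `a` to hit the total dropout target at a
#' given decay `r`; the outer root moves `r` to hit the early-dropout share.
#'
#' @param target_total expected overall dropout fraction (default 0.548).
#' @param target_early expected share of dropouts within `early_weeks`
#'   (default 0.22).
#' @param n population size used to evaluate the expectations.
#' @param seed master seed of the calibration population.
#' @param early_weeks early window in weeks (default 4).
#' @param config optional [generator_config()] template; defaults to the
#'   standard configuration with a flat unit base hazard (the base hazard
#'   cancels out of the linear predictors).
#' @return list with `a`, `r`, the achieved `total` and `early`, and the
#'   calibrated `weekly_base_hazard` vector.
#' @export
calibrate_base_hazard <- function(target_total = 0.548, target_early = 0.22,
                                  n = 40000, seed = 20201L, early_weeks = 4L,
                                  config = NULL) {
  if (is.null(config))
    config <- generator_config(n_recruits = n, seed = seed,
                               weekly_base_hazard = rep(1, 24))
  baseline <- generate_baseline(config)
  traj <- generate_trajectories(baseline, config)
  elp <- exp(weekly_hazard(baseline, traj, config)$lp)
  solve_a <- function(r) {
    f <- function(la) expected_dropout(elp, exp(la), r, early_weeks)["total"] -
      target_total
    exp(stats::uniroot(f, c(log(1e-6), log(2)), tol = 1e-12)$root)
  }
  g <- function(r) {
    a <- solve_a(r)
    expected_dropout(elp, a, r, early_weeks)["early"] - target_early
  }
  r <- stats::uniroot(g, c(0.7, 1.5), tol = 1e-10)$root
  a <- solve_a(r)
  ach <- expected_dropout(elp, a, r, early_weeks)
  list(a = a, r = r, total = unname(ach["total"]), early = unname(ach["early"]),
       weekly_base_hazard = a * r^(seq_len(config$duration_weeks) - 1))
}
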