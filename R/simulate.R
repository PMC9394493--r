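# Synthetic cohort generator.
#
# Emulates a 24-week recruit training cohort: truncated-normal baseline
# anthropometrics and fitness, stationary AR(1) weekly Likert trajectories
# discretised to 1..10, weekly pain reports, and dropout from a discrete-time
# hazard whose weekly rate is the calibrated base hazard times
# exp(Z(s)(beta1 + beta2 code(s)) + X gamma) -- the exact model class the
# landmark supermodel estimates. A truth record retains every latent
# quantity so estimator checks can replay the data-generating hazard.

#' Generate baseline covariates
#'
#' Samples anthropometrics and fitness scores from normals truncated to the
#' eligibility limits, with pre-truncation means solved so the realised means
#' match the configured targets, plus an education category.
#'
#' @param config a [generator_config()].
#' @return data.frame with one row per recruit: `recruit_id`, `height` (m),
#'   `body_mass` (kg), `age` (y), `body_fat` (%), `cooper` (km), `pushups`,
#'   `situps`, `education` (factor unknown/level1/level2).
#' @export
generate_baseline <- function(config) {
  spec <- config$baseline_spec
  n <- config$n_recruits
  cols <- with_stream(config$seed, "baseline", {
    vals <- lapply(seq_len(nrow(spec)), function(i) {
      mu <- solve_truncnorm_mu(spec$mean[i], spec$sd[i],
                               spec$lower[i], spec$upper[i])
      rtruncnorm(n, mu, spec$sd[i], spec$lower[i], spec$upper[i])
    })
    names(vals) <- spec$covariate
    vals$education <- factor(
      sample(names(config$education_probs), n, replace = TRUE,
             prob = config$education_probs),
      levels = c("unknown", "level1", "level2"))
    vals
  })
  out <- data.frame(recruit_id = seq_len(n))
  for (nm in c("height", "body_mass", "age", "body_fat",
               "cooper", "pushups", "situps", "education"))
    out[[nm]] <- if (n == 0L) cols[[nm]][0] else cols[[nm]]
  out
}

#' Generate weekly Likert trajectories and pain reports
#'
#' Each recruit x item series is a stationary AR(1) around a recruit-level
#' intercept, discretised to the 1..10 Likert range by clamped rounding.
#' Pain reports arrive as weekly Bernoulli events with an NPRS severity
#' drawn 1..10.
#'
#' @param baseline output of [generate_baseline()].
#' @param config a [generator_config()].
#' @return list with `latent` (n x weeks x items array), `observed`
#'   (discretised array), `intercepts` (n x items), `pain` (n x weeks 0/1),
#'   `nprs` (n x weeks, NA when no pain), and `weekly`, the long-format
#'   observed table (one row per recruit-week, all weeks).
#' @export
generate_trajectories <- function(baseline, config) {
  n <- nrow(baseline)
  W <- config$duration_weeks
  items <- .likert_items
  k <- length(items)
  phi <- config$likert_ar_coef
  sd_e <- config$likert_noise_sd
  res <- with_stream(config$seed, "trajectories", {
    intercepts <- matrix(rnorm(n * k, rep(config$likert_item_means[items],
                                          each = n),
                               config$likert_intercept_sd),
                         n, k, dimnames = list(NULL, items))
    latent <- array(NA_real_, c(n, W, k), dimnames = list(NULL, NULL, items))
    sd_stat <- if (sd_e > 0) sd_e / sqrt(1 - phi^2) else 0
    for (j in seq_len(k)) {
      x <- intercepts[, j] + rnorm(n, 0, sd_stat)
      latent[, 1, j] <- x
      for (w in seq_len(W - 1L)) {
        x <- intercepts[, j] + phi * (x - intercepts[, j]) + rnorm(n, 0, sd_e)
        latent[, w + 1L, j] <- x
      }
    }
    pain <- matrix(runif(n * W) < config$injury_weekly_prob, n, W)
    nprs <- matrix(NA_integer_, n, W)
    if (any(pain)) nprs[pain] <- sample(1:10, sum(pain), replace = TRUE)
    list(intercepts = intercepts, latent = latent,
         pain = pain * 1L, nprs = nprs)
  })
  res$observed <- pmin(pmax(round(res$latent), 1), 10)
  weekly <- data.frame(
    recruit_id = rep(baseline$recruit_id, each = W),
    week = rep(seq_len(W), times = n))
  for (j in seq_along(items))
    weekly[[items[j]]] <- as.vector(t(res$observed[, , j]))
  weekly$pain_reported <- as.vector(t(res$pain))
  weekly$nprs <- as.vector(t(res$nprs))
  res$weekly <- weekly
  res
}

# Per-recruit weekly linear predictors, hazards and dropout probabilities
# implied by the generator's model. Week w >= 2 uses the landmark s = w - 1
# covariates and interaction code; week 1 (before the first landmark) uses
# the week-1 values with the s = 1 code.
weekly_hazard <- function(baseline, trajectories, config) {
  n <- nrow(baseline)
  W <- config$duration_weeks
  co <- config$true_coefficients
  xg <- drop(baseline_design(baseline) %*% co$gamma)
  ever_pain <- matrix(t(apply(trajectories$pain, 1, cummax)), n, W)
  lp <- haz <- matrix(NA_real_, n, W)
  items5 <- setdiff(names(co$beta1), "pain")
  for (w in seq_len(W)) {
    s_eff <- max(w - 1L, 1L)
    code <- landmark_code(s_eff, config$landmark_coding)
    zc <- matrix(0, n, length(items5) + 1L,
                 dimnames = list(NULL, c(items5, "pain")))
    for (it in items5) zc[, it] <- trajectories$observed[, s_eff, it] - 5
    zc[, "pain"] <- ever_pain[, s_eff]
    b <- co$beta1 + co$beta2 * code
    lp[, w] <- xg + drop(zc %*% b[colnames(zc)])
    haz[, w] <- config$weekly_base_hazard[w] * exp(lp[, w])
  }
  if (any(haz < 0)) stop("negative weekly hazard")
  list(lp = lp, hazard = haz, prob = 1 - exp(-haz), ever_pain = ever_pain)
}

#' Simulate dropout outcomes
#'
#' Draws each recruit's dropout week as the first success of the weekly
#' probabilities 1 - exp(-h_w) implied by the configured base hazard and true
#' coefficients, the dropout day uniform within that week; completers are
#' administratively censored at the last training day. A dropout reason is
#' drawn from the configured mixture (injury up-weighted for recruits with a
#' pain report by their dropout week) and an exit survey is generated for
#' dropouts with item means tied to the true reason.
#'
#' @param baseline output of [generate_baseline()].
#' @param trajectories output of [generate_trajectories()].
#' @param config a [generator_config()].
#' @return list with `outcomes` (recruit_id, time in days, status 0/1,
#'   dropout_week, reason, five exit-survey items) and `truth` (weekly `lp`,
#'   `hazard`, `prob`, `ever_pain` matrices).
#' @export
simulate_dropout <- function(baseline, trajectories, config) {
  n <- nrow(baseline)
  W <- config$duration_weeks
  truth <- weekly_hazard(baseline, trajectories, config)
  res <- with_stream(config$seed, "dropout", {
    u <- matrix(runif(n * W), n, W)
    first <- apply(u < truth$prob, 1, function(z) {
      w <- which(z); if (length(w)) w[1] else NA_integer_
    })
    day_in_week <- sample(1:7, n, replace = TRUE)
    list(first = first, day_in_week = day_in_week)
  })
  drop_week <- res$first
  is_drop <- !is.na(drop_week)
  time <- ifelse(is_drop, 7 * (drop_week - 1L) + res$day_in_week, 7 * W)
  reason <- rep("completed", n)
  if (any(is_drop)) {
    reason[is_drop] <- with_stream(config$seed, "reason", {
      vapply(which(is_drop), function(i) {
        wgt <- config$reason_mixture
        if (truth$ever_pain[i, drop_week[i]] > 0)
          wgt["injury"] <- wgt["injury"] * config$pain_reason_multiplier
        sample(names(wgt), 1, prob = wgt / sum(wgt))
      }, character(1))
    })
  }
  outcomes <- data.frame(recruit_id = baseline$recruit_id,
                         time = as.integer(time),
                         status = as.integer(is_drop),
                         dropout_week = drop_week,
                         reason = reason,
                         stringsAsFactors = FALSE)
  outcomes <- cbind(outcomes, generate_exit_survey(reason, is_drop, config))
  list(outcomes = outcomes, truth = truth)
}

# Exit-survey means by true reason; SD 1.5, clamped rounding to 1..10.
.exit_items <- c("exit_preparation", "exit_physical", "exit_mental",
                 "exit_physician", "exit_injury")
.exit_means <- list(
  injury             = c(3, 4, 4, 6, 8),
  individual_request = c(5, 5, 8, 2, 2),
  other              = c(4, 4, 4, 3, 3))

generate_exit_survey <- function(reason, is_drop, config) {
  n <- length(reason)
  out <- matrix(NA_integer_, n, 5, dimnames = list(NULL, .exit_items))
  idx <- which(is_drop)
  if (length(idx)) {
    vals <- with_stream(config$seed, "exit", {
      miss <- runif(length(idx)) < config$missingness$p_missing_exit
      v <- t(vapply(seq_along(idx), function(j) {
        mu <- .exit_means[[reason[idx[j]]]]
        pmin(pmax(round(rnorm(5, mu, 1.5)), 1), 10)
      }, numeric(5)))
      v[miss, ] <- NA_real_
      v
    })
    out[idx, ] <- as.integer(vals)
  }
  as.data.frame(out)
}

#' Simulate a complete cohort
#'
#' Runs baseline generation, weekly trajectories and dropout simulation under
#' one configuration, returning a `simulated_cohort`: the three observed
#' tables (with post-dropout weekly rows removed -- recruits respond up to
#' and including their dropout week) plus the truth record.
#'
#' @param config a [generator_config()].
#' @param degrade apply the configured missingness pattern (default TRUE).
#' @return object of class `simulated_cohort` with elements `baseline`,
#'   `weekly`, `outcomes`, `truth`, `config`.
#' @export
simulate_cohort <- function(config, degrade = TRUE) {
  baseline <- generate_baseline(config)
  traj <- generate_trajectories(baseline, config)
  sim <- simulate_dropout(baseline, traj, config)
  last_week <- ifelse(sim$outcomes$status == 1,
                      sim$outcomes$dropout_week, config$duration_weeks)
  weekly <- traj$weekly[traj$weekly$week <=
                          last_week[match(traj$weekly$recruit_id,
                                          sim$outcomes$recruit_id)], ,
                        drop = FALSE]
  rownames(weekly) <- NULL
  cohort <- structure(list(baseline = baseline,
                           weekly = weekly,
                           outcomes = sim$outcomes,
                           truth = c(sim$truth,
                                     list(latent = traj$latent,
                                          intercepts = traj$intercepts)),
                           config = config),
                      class = "simulated_cohort")
  if (degrade) cohort <- apply_missingness(cohort, config)
  cohort
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$baseline), "recruits,",
      x$config$duration_weeks, "weeks;",
      sum(x$outcomes$status), "dropouts (",
      round(100 * mean(x$outcomes$status), 1), "% )\n")
  invisible(x)
}

#' Degrade a complete cohort to the observed missingness pattern
#'
#' Applies, in order: erasure of baseline fields for a fraction of recruits;
#' left truncation (deletion of the first 1-3 status weeks) for a fraction;
#' full status erasure for week-1 dropouts (up to the configured fraction of
#' the cohort); and missing-not-at-random erasure of the mental-fitness item,
#' with erasure probability increasing in (10 - latent value) and the
#' intercept solved so the overall missing fraction matches the target.
#'
#' @param cohort a `simulated_cohort`.
#' @param config a [generator_config()]; defaults to the cohort's own.
#' @return the degraded `simulated_cohort`.
#' @export
apply_missingness <- function(cohort, config = cohort$config) {
  mc <- config$missingness
  n <- nrow(cohort$baseline)
  if (n == 0L) return(cohort)
  out <- cohort$outcomes
  num_fields <- c("height", "body_mass", "age", "body_fat",
                  "cooper", "pushups", "situps")

  if (mc$p_missing_baseline > 0) {
    cohort$baseline <- with_stream(config$seed, "miss_baseline", {
      hit <- which(runif(n) < mc$p_missing_baseline)
      b <- cohort$baseline
      for (i in hit) {
        fields <- unique(c(sample(num_fields, 1),
                           num_fields[runif(7) < 1 / 3]))
        b[i, fields] <- NA_real_
      }
      b
    })
  }

  wk <- cohort$weekly
  item_cols <- c(.likert_items, "pain_reported", "nprs")
  if (mc$p_left_truncated > 0) {
    wk <- with_stream(config$seed, "miss_truncation", {
      eligible <- out$recruit_id[out$status == 0 |
                                   (!is.na(out$dropout_week) &
                                      out$dropout_week >= 5)]
      n_trunc <- min(round(mc$p_left_truncated * n), length(eligible))
      chosen <- sample(eligible, n_trunc)
      kk <- sample(1:3, n_trunc, replace = TRUE)
      for (j in seq_along(chosen)) {
        rows <- wk$recruit_id == chosen[j] & wk$week <= kk[j]
        wk[rows, item_cols] <- NA
      }
      wk
    })
  }
  if (mc$p_week1_dropout_no_obs > 0) {
    wk <- with_stream(config$seed, "miss_week1", {
      w1 <- out$recruit_id[out$status == 1 & !is.na(out$dropout_week) &
                             out$dropout_week == 1]
      n_mask <- min(round(mc$p_week1_dropout_no_obs * n), length(w1))
      if (n_mask > 0) {
        chosen <- sample(w1, n_mask)
        wk[wk$recruit_id %in% chosen, item_cols] <- NA
      }
      wk
    })
  }
  if (mc$p_mnar_mentalfit > 0) {
    wk <- with_stream(config$seed, "miss_mnar", {
      obs <- which(!is.na(wk$mentalfit))
      lat <- cohort$truth$latent[cbind(wk$recruit_id[obs], wk$week[obs],
                                       rep(which(.likert_items == "mentalfit"),
                                           length(obs)))]
      sev <- mc$mnar_strength * (10 - lat)
      f <- function(a) mean(stats::plogis(a + sev)) - mc$p_mnar_mentalfit
      alpha <- stats::uniroot(f, c(-40, 40), tol = 1e-10)$root
      erase <- runif(length(obs)) < stats::plogis(alpha + sev)
      wk$mentalfit[obs[erase]] <- NA
      wk
    })
  }
  cohort$weekly <- wk
  cohort
}

#' Cohorts needed for a target predictor:event ratio
#'
#' Smallest number of cohorts `c` with
#' `c * recruits_per_cohort * dropout_rate >= target_events_per_predictor *
#' n_predictors`.
#'
#' @param target_events_per_predictor planned events per candidate predictor.
#' @param recruits_per_cohort average cohort size.
#' @param dropout_rate presumed dropout fraction.
#' @param n_predictors number of candidate predictors.
#' @return integer cohort count.
#' @export
required_cohorts <- function(target_events_per_predictor, recruits_per_cohort,
                             dropout_rate, n_predictors) {
  if (dropout_rate <= 0) stop("dropout_rate must be positive")
  stopifnot(target_events_per_predictor > 0, recruits_per_cohort > 0,
            n_predictors > 0)
  as.integer(ceiling(target_events_per_predictor * n_predictors /
                       (recruits_per_cohort * dropout_rate)))
}

#' Achieved events per predictor
#'
#' Planning arithmetic: the expected events per candidate predictor given a
#' sample size and presumed dropout rate, rounded to the nearest integer as
#' ratios are conventionally quoted.
#'
#' @param n_recruits recruits available.
#' @param dropout_rate presumed dropout fraction.
#' @param n_predictors number of candidate predictors.
#' @return integer events-per-predictor ratio.
#' @export
events_per_predictor <- function(n_recruits, dropout_rate, n_predictors) {
  stopifnot(n_recruits > 0, dropout_rate > 0, n_predictors > 0)
  as.integer(round(n_recruits * dropout_rate / n_predictors))
}
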