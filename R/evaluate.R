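# Time-dependent discrimination of the landmark supermodel.
#
# The incident/dynamic AUC at day t is the probability that a recruit
# dropping out around t carries a higher model score than a recruit still in
# training beyond t: cases are events within +/- window_days of t (scored at
# their latest landmark before the event), controls are recruits at risk
# beyond t + window_days (scored at the latest landmark at or before t).
# Ties count one half. No censoring weights are needed: windows are one
# week and censoring is administrative at the end of training.

#' Per-row linear predictors of a fitted supermodel
#'
#' @param fit a `supermodel_fit` (or named coefficient vector).
#' @param stacked a `stacked_landmarks` data frame.
#' @return data.frame with `recruit_id`, `landmark`, `lp`.
#' @export
landmark_lps <- function(fit, stacked) {
  beta <- if (inherits(fit, "supermodel_fit")) fit$coefficients else fit
  lp <- drop(as.matrix(stacked[, names(beta), drop = FALSE]) %*% beta)
  data.frame(recruit_id = stacked$recruit_id, landmark = stacked$landmark,
             lp = lp)
}

# Score each id at its latest landmark <= day/7; NA when none available.
score_at <- function(lps, ids, day) {
  ok <- lps$landmark * 7 <= day
  sub <- lps[ok & lps$recruit_id %in% ids, , drop = FALSE]
  if (!nrow(sub)) return(rep(NA_real_, length(ids)))
  o <- order(sub$recruit_id, sub$landmark)
  sub <- sub[o, ]
  last <- sub[!duplicated(sub$recruit_id, fromLast = TRUE), ]
  last$lp[match(ids, last$recruit_id)]
}

# Case/control sets and scores at evaluation day t.
case_control <- function(lps, outcomes, t, window_days) {
  case_ids <- outcomes$recruit_id[outcomes$status == 1 &
                                    outcomes$time >= t - window_days &
                                    outcomes$time <= t + window_days]
  ctrl_ids <- outcomes$recruit_id[outcomes$time > t + window_days]
  case_times <- outcomes$time[match(case_ids, outcomes$recruit_id)]
  case_lp <- if (length(case_ids))
    mapply(function(id, tm) score_at(lps, id, tm), case_ids, case_times) else
      numeric(0)
  ctrl_lp <- score_at(lps, ctrl_ids, t)
  list(case = case_lp[!is.na(case_lp)], control = ctrl_lp[!is.na(ctrl_lp)])
}

#' Incident/dynamic time-dependent AUC
#'
#' @param lps per-landmark linear predictors ([landmark_lps()] layout).
#' @param outcomes outcome table (`recruit_id`, `time`, `status`).
#' @param t evaluation day.
#' @param window_days half-width of the case window (default 7, the
#'   two-week smoothing window).
#' @return AUC in [0, 1], or NA when no cases or no controls fall in the
#'   window.
#' @export
dynamic_auc <- function(lps, outcomes, t, window_days = 7) {
  cc <- case_control(lps, outcomes, t, window_days)
  n1 <- length(cc$case); n0 <- length(cc$control)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(c(cc$case, cc$control))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Dynamic ROC curve with Youden-optimal threshold
#'
#' Sweeps all distinct linear-predictor thresholds (score >= threshold
#' classifies as dropout). The smoothed variant pools cases over the
#' +/- `window_days` window; `window_days = 0` gives the unsmoothed curve of
#' a single event day. The optimal threshold maximises Youden's J with ties
#' broken toward higher specificity.
#'
#' @inheritParams dynamic_auc
#' @return object of class `dynamic_roc`: `curve` (threshold, sensitivity,
#'   specificity), `auc`, `optimal` (threshold, sensitivity, specificity,
#'   youden), case/control counts; or NULL when undefined.
#' @export
dynamic_roc <- function(lps, outcomes, t, window_days = 7) {
  cc <- case_control(lps, outcomes, t, window_days)
  n1 <- length(cc$case); n0 <- length(cc$control)
  if (n1 == 0 || n0 == 0) return(NULL)
  thr <- c(Inf, sort(unique(c(cc$case, cc$control)), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(h) mean(cc$case >= h), numeric(1))
  spec <- vapply(thr, function(h) mean(cc$control < h), numeric(1))
  curve <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  j <- sens + spec - 1
  finite <- is.finite(thr)
  best <- which(finite)[order(-j[finite], -spec[finite])][1]
  structure(list(t = t, window_days = window_days,
                 n_cases = n1, n_controls = n0,
                 curve = curve, auc = auc,
                 optimal = list(threshold = thr[best],
                                sensitivity = sens[best],
                                specificity = spec[best],
                                youden = j[best])),
            class = "dynamic_roc")
}

#' @export
print.dynamic_roc <- function(x, ...) {
  cat(sprintf(
    "Dynamic ROC at day %d (+/- %d d): AUC %.3f (%d cases, %d controls)\n",
    x$t, x$window_days, x$auc, x$n_cases, x$n_controls))
  cat(sprintf("  optimal threshold %.3f: sensitivity %.2f, specificity %.2f\n",
              x$optimal$threshold, x$optimal$sensitivity,
              x$optimal$specificity))
  invisible(x)
}

# Internal: coefficients of a coxph fit on a subset of stacked rows.
fit_stacked_coef <- function(stacked, rows, terms, ties = "breslow") {
  sub <- stacked[rows, , drop = FALSE]
  dat <- data.frame(start = sub$start, stop = sub$stop, event = sub$event,
                    as.matrix(sub[, terms, drop = FALSE]),
                    check.names = TRUE)
  f <- stats::as.formula(paste("survival::Surv(start, stop, event) ~",
                               paste(make.names(terms), collapse = " + ")))
  fit <- survival::coxph(f, data = dat, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  stats::setNames(unname(stats::coef(fit)), terms)
}

#' Repeated stratified k-fold cross-validation of the supermodel
#'
#' Folds partition recruits (never rows), stratified by dropout status.
#' Each repeat refits the supermodel on k-1 folds and scores the held-out
#' recruits' landmark rows, assembling out-of-fold AUC(t) curves; a training
#' split without events is resampled and flagged. Deterministic given the
#' seed.
#'
#' @param clean a `clean_cohort`.
#' @param k number of folds (>= 2).
#' @param repeats number of repeats.
#' @param seed integer seed.
#' @param eval_days evaluation days (default 7, 28, 84).
#' @param window_days case half-window (default 7).
#' @param coding landmark interaction coding.
#' @param ties tie handling.
#' @return object of class `cv_result`: `auc` (repeat x day out-of-fold
#'   AUCs), `summary` (per-day mean and 2.5/97.5 percentiles), `apparent`
#'   (full-data AUCs), `folds` (per-repeat assignments), `resampled` count.
#' @export
cross_validate <- function(clean, k = 10, repeats = 20, seed = 1L,
                           eval_days = c(7, 28, 84), window_days = 7,
                           coding = c("s_minus_1", "s"),
                           ties = "breslow") {
  coding <- match.arg(coding)
  stopifnot(k >= 2)
  stacked <- stack_landmarks(clean, coding)
  terms <- attr(stacked, "terms")
  out <- clean$outcomes
  ids <- out$recruit_id
  if (k > length(ids)) stop("more folds than recruits")
  full <- fit_stacked_coef(stacked, seq_len(nrow(stacked)), terms, ties)
  app <- vapply(eval_days, function(t)
    dynamic_auc(landmark_lps(full, stacked), out, t, window_days), numeric(1))
  auc <- matrix(NA_real_, repeats, length(eval_days),
                dimnames = list(NULL, paste0("day", eval_days)))
  folds_out <- vector("list", repeats)
  resampled <- 0L
  for (r in seq_len(repeats)) {
    oof <- NULL
    with_stream(seed, paste0("cv_repeat_", r), {
      repeat {
        fold <- integer(length(ids))
        for (st in unique(out$status)) {
          idx <- which(out$status == st)
          fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
        ok <- TRUE
        lp_list <- vector("list", k)
        for (f in seq_len(k)) {
          test_ids <- ids[fold == f]
          train_rows <- !(stacked$recruit_id %in% test_ids)
          if (sum(stacked$event[train_rows]) == 0) { ok <- FALSE; break }
          beta <- fit_stacked_coef(stacked, which(train_rows), terms, ties)
          lp_list[[f]] <- landmark_lps(
            beta, stacked[stacked$recruit_id %in% test_ids, , drop = FALSE])
        }
        if (ok) { oof <- do.call(rbind, lp_list); break }
        resampled <- resampled + 1L
        if (resampled > 50L) stop("could not form event-bearing folds")
      }
      folds_out[[r]] <- data.frame(recruit_id = ids, fold = fold)
    })
    auc[r, ] <- vapply(eval_days, function(t)
      dynamic_auc(oof, out, t, window_days), numeric(1))
  }
  summ <- data.frame(
    day = eval_days,
    mean_auc = colMeans(auc, na.rm = TRUE),
    lo = apply(auc, 2, stats::quantile, 0.025, na.rm = TRUE),
    hi = apply(auc, 2, stats::quantile, 0.975, na.rm = TRUE),
    apparent = app, row.names = NULL)
  structure(list(auc = auc, summary = summ,
                 apparent = data.frame(day = eval_days, auc = app),
                 folds = folds_out, k = k, repeats = repeats,
                 resampled = resampled, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Repeated", x$k, "- fold cross-validation,", x$repeats, "repeats\n")
  print(transform(x$summary, mean_auc = round(mean_auc, 3),
                  lo = round(lo, 3), hi = round(hi, 3),
                  apparent = round(apparent, 3)), row.names = FALSE)
  invisible(x)
}

#' Compare the supermodel with a baseline-only Cox model
#'
#' Fits a conventional Cox proportional-hazards model on the nine baseline
#' covariates alone (time-to-dropout from day 0, no landmarking, no
#' time-varying terms) and returns AUC(t) for both models on the same
#' evaluation sets.
#'
#' @param clean a `clean_cohort`.
#' @param eval_days evaluation days (default 7, 28, 84).
#' @param window_days case half-window (default 7).
#' @param coding landmark interaction coding.
#' @return list with `auc` (day, auc_supermodel, auc_baseline), the
#'   `supermodel` fit, and `baseline_coef`.
#' @export
compare_baseline_only <- function(clean, eval_days = c(7, 28, 84),
                                  window_days = 7,
                                  coding = c("s_minus_1", "s")) {
  coding <- match.arg(coding)
  stacked <- stack_landmarks(clean, coding)
  fit <- fit_supermodel(stacked)
  lps_super <- landmark_lps(fit, stacked)
  xb <- baseline_design(clean$baseline)
  out <- clean$outcomes
  dat <- data.frame(time = out$time, status = out$status, xb,
                    check.names = TRUE)
  f <- stats::as.formula(paste("survival::Surv(time, status) ~",
                               paste(make.names(colnames(xb)),
                                     collapse = " + ")))
  bfit <- survival::coxph(f, data = dat, ties = "breslow")
  blp <- drop(xb %*% stats::coef(bfit))
  S <- clean$duration_weeks - 1L
  lps_base <- data.frame(
    recruit_id = rep(out$recruit_id, each = S),
    landmark = rep(seq_len(S), times = nrow(out)),
    lp = rep(blp, each = S))
  auc <- data.frame(
    day = eval_days,
    auc_supermodel = vapply(eval_days, function(t)
      dynamic_auc(lps_super, out, t, window_days), numeric(1)),
    auc_baseline = vapply(eval_days, function(t)
      dynamic_auc(lps_base, out, t, window_days), numeric(1)))
  list(auc = auc, supermodel = fit,
       baseline_coef = stats::setNames(stats::coef(bfit), colnames(xb)))
}

#' Summarize dropout reasons and early exit-survey statements
#'
#' Registered-reason frequencies over all dropouts, and -- for dropouts
#' within the early cutoff -- counts of exit-survey statements rated at or
#' above the agreement threshold (multiple statements per recruit allowed);
#' missing surveys are counted separately.
#'
#' @param outcomes outcome table including the exit-survey columns.
#' @param early_cutoff_weeks early-dropout window in weeks (default 4).
#' @param agree_threshold minimum rating treated as agreement (default 7).
#' @return list with `reason_counts`, `n_dropouts`, `early_share`, and
#'   `early` (`n`, per-statement `statement_counts`, `n_missing_survey`).
#' @export
summarize_dropout_reasons <- function(outcomes, early_cutoff_weeks = 4,
                                      agree_threshold = 7) {
  drops <- outcomes[outcomes$status == 1, , drop = FALSE]
  reason_counts <- table(factor(drops$reason,
                                levels = c("injury", "individual_request",
                                           "other")))
  early <- drops[drops$time <= 7 * early_cutoff_weeks, , drop = FALSE]
  items <- intersect(.exit_items, names(outcomes))
  has_survey <- rowSums(!is.na(early[, items, drop = FALSE])) > 0
  counts <- vapply(items, function(col)
    sum(early[[col]] >= agree_threshold, na.rm = TRUE), integer(1))
  list(reason_counts = reason_counts,
       n_dropouts = nrow(drops),
       early_share = if (nrow(drops)) nrow(early) / nrow(drops) else NA_real_,
       early = list(n = nrow(early),
                    statement_counts = counts,
                    n_missing_survey = sum(!has_survey)))
}
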