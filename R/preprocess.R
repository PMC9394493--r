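# Data cleaning reproducing the study's handling of missing data:
# single mean imputation of continuous baseline covariates, LOCF completion
# of the weekly status items, pain dichotomization with an absorbing carry,
# near-zero-variance / high-missingness predictor screening, and
# left-truncation entry weeks with exclusion of recruits who dropped out
# before any status observation.

#' Mean-impute continuous baseline covariates
#'
#' Replaces each missing numeric cell by the observed-sample mean of its
#' column. Categorical education is never imputed (the explicit "unknown"
#' level is its own reference category).
#'
#' @param baseline baseline table, possibly with missing numeric cells.
#' @return list with `baseline` (imputed) and `log`, a data.frame of the
#'   imputed cells (`recruit_id`, `field`, `value`).
#' @export
mean_impute_baseline <- function(baseline) {
  num <- names(baseline)[vapply(baseline, is.numeric, logical(1))]
  num <- setdiff(num, "recruit_id")
  log <- list()
  for (col in num) {
    miss <- is.na(baseline[[col]])
    if (!any(miss)) next
    if (all(miss)) stop("baseline column '", col, "' is entirely missing")
    fill <- mean(baseline[[col]][!miss])
    log[[col]] <- data.frame(recruit_id = baseline$recruit_id[miss],
                             field = col, value = fill)
    baseline[[col]][miss] <- fill
  }
  log <- if (length(log)) do.call(rbind, c(log, make.row.names = FALSE)) else
    data.frame(recruit_id = integer(), field = character(), value = numeric())
  list(baseline = baseline, log = log)
}

#' Last observation carried forward over weekly status
#'
#' For each recruit and item column, fills a missing week with the most
#' recent observed value at an earlier week; weeks before the first
#' observation stay missing ("unavailable"). Observed cells are never
#' altered, and the operation is idempotent.
#'
#' @param weekly long-format weekly table (one row per recruit-week) sorted
#'   or sortable by `recruit_id`, `week`.
#' @param items character vector of columns to complete.
#' @return list with `weekly` (completed, in recruit/week order) and
#'   `provenance`, a data.frame of flags (`"observed"`, `"locf"`,
#'   `"unavailable"`) of the same shape as the item columns.
#' @export
locf_complete <- function(weekly, items = intersect(.likert_items,
                                                    names(weekly))) {
  ord <- order(weekly$recruit_id, weekly$week)
  weekly <- weekly[ord, , drop = FALSE]
  rownames(weekly) <- NULL
  prov <- data.frame(recruit_id = weekly$recruit_id, week = weekly$week)
  for (col in items) {
    before <- weekly[[col]]
    weekly[[col]] <- stats::ave(before, weekly$recruit_id,
                                FUN = function(v) zoo::na.locf(v, na.rm = FALSE))
    prov[[col]] <- ifelse(!is.na(before), "observed",
                          ifelse(!is.na(weekly[[col]]), "locf", "unavailable"))
  }
  list(weekly = weekly, provenance = prov)
}

#' Dichotomize weekly pain reports
#'
#' A week is pain-positive when any location was marked (any NPRS score,
#' including 0 severity with a mark); the binary state is then carried over
#' subsequent weeks either as an absorbing ever-injured state (default,
#' the literal reading of the retention rule) or by LOCF.
#'
#' @param weekly weekly table with `pain_reported` (0/1/NA) and `nprs`.
#' @param carry `"absorbing"` (once positive, stays positive) or `"locf"`.
#' @return the weekly table with an added `pain` column (0/1, NA before any
#'   observation), in recruit/week order.
#' @export
dichotomize_pain <- function(weekly, carry = c("absorbing", "locf")) {
  carry <- match.arg(carry)
  if (any(!is.na(weekly$nprs) & (weekly$nprs < 0 | weekly$nprs > 10)))
    stop("NPRS scores must lie in 0..10")
  ord <- order(weekly$recruit_id, weekly$week)
  weekly <- weekly[ord, , drop = FALSE]
  rownames(weekly) <- NULL
  base <- as.numeric(weekly$pain_reported > 0)
  weekly$pain <- if (carry == "absorbing") {
    stats::ave(base, weekly$recruit_id, FUN = function(v) {
      filled <- zoo::na.locf(v, na.rm = FALSE)   # NA until first observation
      cummax(ifelse(is.na(filled), 0, filled)) + filled * 0
    })
  } else {
    stats::ave(base, weekly$recruit_id,
               FUN = function(v) zoo::na.locf(v, na.rm = FALSE))
  }
  weekly
}

#' Screen time-varying predictors
#'
#' Drops any item whose pre-completion missing fraction exceeds
#' `max_missing_frac` or whose observed variance falls below `min_variance`
#' (both strict inequalities, so an item exactly at a threshold is kept).
#'
#' @param weekly raw (pre-LOCF) weekly table.
#' @param max_missing_frac maximum tolerated missing fraction (default 0.5).
#' @param min_variance minimum observed variance (default 1e-3).
#' @param items candidate item columns (default the six Likert items).
#' @return list with `kept`, `dropped` and `report` (item, missing fraction,
#'   observed variance, decision).
#' @export
screen_predictors <- function(weekly, max_missing_frac = 0.5,
                              min_variance = 1e-3,
                              items = intersect(.likert_items,
                                                names(weekly))) {
  stats_ <- t(vapply(items, function(col) {
    v <- weekly[[col]]
    c(missing_frac = mean(is.na(v)),
      variance = if (sum(!is.na(v)) > 1) stats::var(v, na.rm = TRUE) else 0)
  }, numeric(2)))
  drop <- stats_[, "missing_frac"] > max_missing_frac |
    stats_[, "variance"] < min_variance
  if (all(drop)) stop("all time-varying predictors screened out")
  report <- data.frame(item = items,
                       missing_frac = stats_[, "missing_frac"],
                       variance = stats_[, "variance"],
                       dropped = drop, row.names = NULL)
  list(kept = items[!drop], dropped = items[drop], report = report)
}

#' Entry weeks and no-observation exclusions
#'
#' A recruit's follow-up starts at the first week with any observed status
#' (left truncation). Recruits whose dropout precedes any observation are
#' excluded with reason `"no_observations"`.
#'
#' @param weekly weekly table (raw or completed).
#' @param outcomes outcome table with `recruit_id`, `time`, `status`.
#' @param items status columns whose observation defines entry.
#' @return list with `entry` (recruit_id, entry_week) and `exclusions`
#'   (recruit_id, reason).
#' @export
determine_entry <- function(weekly, outcomes,
                            items = intersect(c(.likert_items, "pain_reported"),
                                              names(weekly))) {
  obs <- rowSums(!is.na(weekly[, items, drop = FALSE])) > 0
  first_obs <- tapply(ifelse(obs, weekly$week, NA_integer_),
                      weekly$recruit_id, function(w) {
                        w <- w[!is.na(w)]
                        if (length(w)) min(w) else NA_integer_
                      })
  entry <- data.frame(recruit_id = as.integer(names(first_obs)),
                      entry_week = as.integer(first_obs))
  entry <- entry[match(outcomes$recruit_id, entry$recruit_id), ]
  entry$recruit_id <- outcomes$recruit_id
  # no observations at all, or dropout before the first observed week's end
  no_obs <- is.na(entry$entry_week) |
    (outcomes$status == 1 & outcomes$time <= 7 * (entry$entry_week - 1))
  exclusions <- data.frame(recruit_id = outcomes$recruit_id[no_obs],
                           reason = rep("no_observations", sum(no_obs)))
  list(entry = entry[!no_obs, , drop = FALSE], exclusions = exclusions)
}

#' Preprocess a cohort for landmarking
#'
#' Orchestrates the cleaning pipeline: exclusion of recruits without usable
#' observations, baseline mean imputation, predictor screening on the raw
#' weekly table, pain dichotomization, and LOCF completion of the retained
#' items.
#'
#' @param cohort a `simulated_cohort`, or a list with `baseline`, `weekly`,
#'   `outcomes` tables in the documented schemas.
#' @param max_missing_frac,min_variance screening thresholds
#'   (see [screen_predictors()]).
#' @param pain_carry pain carry rule (see [dichotomize_pain()]).
#' @return object of class `clean_cohort`: imputed `baseline`,
#'   completed `weekly` (retained items + `pain`), `provenance`, `entry`,
#'   `exclusions`, `screen`, `imputation_log`, filtered `outcomes`,
#'   `tv_items` (retained items plus pain) and `duration_weeks`.
#' @export
preprocess_cohort <- function(cohort, max_missing_frac = 0.5,
                              min_variance = 1e-3,
                              pain_carry = c("absorbing", "locf")) {
  pain_carry <- match.arg(pain_carry)
  ent <- determine_entry(cohort$weekly, cohort$outcomes)
  keep <- !(cohort$outcomes$recruit_id %in% ent$exclusions$recruit_id)
  baseline <- cohort$baseline[keep, , drop = FALSE]
  outcomes <- cohort$outcomes[keep, , drop = FALSE]
  weekly <- cohort$weekly[cohort$weekly$recruit_id %in%
                            outcomes$recruit_id, , drop = FALSE]
  imp <- mean_impute_baseline(baseline)
  scr <- screen_predictors(weekly, max_missing_frac, min_variance)
  weekly <- dichotomize_pain(weekly, pain_carry)
  loc <- locf_complete(weekly, items = c(scr$kept, "pain"))
  duration <- if (!is.null(cohort$config)) cohort$config$duration_weeks else
    max(cohort$weekly$week)
  structure(list(baseline = imp$baseline,
                 weekly = loc$weekly,
                 provenance = loc$provenance,
                 entry = ent$entry,
                 exclusions = ent$exclusions,
                 screen = scr,
                 imputation_log = imp$log,
                 outcomes = outcomes,
                 tv_items = c(scr$kept, "pain"),
                 duration_weeks = as.integer(duration)),
            class = "clean_cohort")
}

#' @export
print.clean_cohort <- function(x, ...) {
  cat("Clean cohort:", nrow(x$baseline), "recruits (",
      nrow(x$exclusions), "excluded );",
      sum(x$outcomes$status), "dropouts; items:",
      paste(x$tv_items, collapse = ", "), "\n")
  invisible(x)
}
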