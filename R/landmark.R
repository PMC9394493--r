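# Landmark grid and the stacked supermodel dataset.
#
# Landmarks sit at the end of each training week (day 7s, s = 1..S with
# S = weeks - 1), each with a one-week prediction window (7s, 7(s+1)]:
# half-open on the left, closed on the right, so an event on day 7s belongs
# to the window ending at 7s. A recruit contributes a row at landmark s iff
# still in training at day 7s and entered (first status observation) by
# week s; the row carries the LOCF-completed week-s covariates and the
# landmark interactions Z(s) * code(s).

#' Build the landmark grid
#'
#' @param duration_weeks training length in weeks (>= 2).
#' @return data.frame with `s` (landmark index), `day` (7s) and
#'   `horizon_day` (7(s+1)).
#' @export
landmark_grid <- function(duration_weeks) {
  if (duration_weeks < 2) stop("duration_weeks must be at least 2")
  s <- seq_len(duration_weeks - 1L)
  data.frame(s = s, day = 7L * s, horizon_day = 7L * (s + 1L))
}

#' Build one landmark dataset
#'
#' Rows for all recruits still in training at day 7s with entry week <= s,
#' with the week-s time-varying covariates (LOCF-completed), the event
#' indicator for the window (7s, 7(s+1)], and the 21 centred design columns.
#'
#' @param clean a `clean_cohort`.
#' @param s landmark index.
#' @param coding landmark interaction coding, `"s_minus_1"` or `"s"`.
#' @return data.frame with `recruit_id`, `landmark`, `start`, `stop`,
#'   `event` and the design columns.
#' @export
build_landmark_dataset <- function(clean, s, coding = c("s_minus_1", "s")) {
  coding <- match.arg(coding)
  grid <- landmark_grid(clean$duration_weeks)
  if (!s %in% grid$s) stop("landmark s = ", s, " outside the grid 1..",
                           max(grid$s))
  out <- clean$outcomes
  ent <- clean$entry$entry_week[match(out$recruit_id, clean$entry$recruit_id)]
  at_risk <- out$time > 7 * s & !is.na(ent) & ent <= s
  ids <- out$recruit_id[at_risk]
  if (!length(ids)) return(NULL)
  wk <- clean$weekly[clean$weekly$week == s, , drop = FALSE]
  wk <- wk[match(ids, wk$recruit_id), , drop = FALSE]
  if (anyNA(wk$recruit_id))
    stop("missing week-", s, " status for at-risk recruit(s)")
  xb <- baseline_design(clean$baseline[match(ids, clean$baseline$recruit_id), ,
                                       drop = FALSE])
  zc <- tv_design(wk, clean$tv_items)
  if (anyNA(zc))
    stop("missing time-varying covariate at landmark ", s)
  code <- landmark_code(s, coding)
  design <- cbind(xb, zc, zc * code)
  colnames(design) <- predictor_terms(clean$tv_items)
  time <- out$time[at_risk]
  event <- as.integer(out$status[at_risk] == 1 & time <= 7 * (s + 1))
  data.frame(recruit_id = ids, landmark = s, start = 7 * s,
             stop = pmin(time, 7 * (s + 1)), event = event,
             design, check.names = FALSE)
}

#' Stack the landmark datasets
#'
#' Concatenates the per-landmark datasets over the full grid into the
#' supermodel design: one row per recruit-landmark at risk, 21 predictor
#' columns, and counting-process (start, stop] intervals that confine each
#' row's risk contribution to its own window.
#'
#' @param clean a `clean_cohort`.
#' @param coding landmark interaction coding (default `"s_minus_1"`).
#' @return data.frame of class `stacked_landmarks` with attributes
#'   `tv_items`, `coding`, `terms` and `duration_weeks`.
#' @export
stack_landmarks <- function(clean, coding = c("s_minus_1", "s")) {
  coding <- match.arg(coding)
  grid <- landmark_grid(clean$duration_weeks)
  parts <- lapply(grid$s, function(s)
    build_landmark_dataset(clean, s, coding))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) stop("empty risk set at every landmark")
  stacked <- do.call(rbind, parts)
  rownames(stacked) <- NULL
  structure(stacked,
            tv_items = clean$tv_items,
            coding = coding,
            terms = predictor_terms(clean$tv_items),
            duration_weeks = clean$duration_weeks,
            class = c("stacked_landmarks", "data.frame"))
}

#' Expected stacked row count
#'
#' Conservation identity of the stack: each recruit contributes one row per
#' landmark from entry to the last landmark at which they are still in
#' training, i.e. sum over recruits of (last landmark at risk - entry + 1).
#'
#' @param clean a `clean_cohort`.
#' @return integer row count.
#' @export
expected_stacked_rows <- function(clean) {
  out <- clean$outcomes
  ent <- clean$entry$entry_week[match(out$recruit_id, clean$entry$recruit_id)]
  S <- clean$duration_weeks - 1L
  last <- pmin(ceiling(out$time / 7) - 1L, S)   # last s with time > 7s
  sum(pmax(last - ent + 1L, 0L))
}
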