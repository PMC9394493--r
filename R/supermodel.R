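# Stacked Cox supermodel: partial-likelihood estimation (via survival's
# counting-process machinery), Breslow baseline hazard centred at the
# reference subject, Rubin pooling across imputed datasets, reference-
# centred linear predictors, and conditional dropout probabilities.

#' Fit the stacked landmark supermodel
#'
#' Maximises the Cox partial likelihood over event days pooled across the
#' stacked rows. The counting-process intervals (start, stop] confine each
#' row's risk contribution to its own landmark window, so risk sets are
#' formed within windows. Breslow tie handling and model-based variance by
#' default; `variance = "robust"` requests a recruit-clustered sandwich.
#'
#' @param stacked a `stacked_landmarks` data frame.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param variance `"model"` (default) or `"robust"`.
#' @return object of class `supermodel_fit`: `coefficients` (named
#'   21-vector), `coef_set` (a [coefficient_set()]), `vcov`, `summary`
#'   (term, coef, se, HR, 95% CI, p), `loglik` at the optimum,
#'   `baseline_hazard` (Breslow steps for the reference subject), counts,
#'   and the fitting options.
#' @export
fit_supermodel <- function(stacked, ties = c("breslow", "efron"),
                           variance = c("model", "robust")) {
  ties <- match.arg(ties)
  variance <- match.arg(variance)
  terms <- attr(stacked, "terms")
  if (is.null(terms))
    terms <- setdiff(names(stacked),
                     c("recruit_id", "landmark", "start", "stop", "event"))
  if (sum(stacked$event) == 0) stop("no events in the stacked data")
  X <- as.matrix(stacked[, terms, drop = FALSE])
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    stop("constant (collinear) design column(s): ",
         paste(terms[const], collapse = ", "))
  dat <- data.frame(start = stacked$start, stop = stacked$stop,
                    event = stacked$event, recruit_id = stacked$recruit_id,
                    X, check.names = TRUE)
  xn <- make.names(terms)
  f <- stats::as.formula(paste("survival::Surv(start, stop, event) ~",
                               paste(xn, collapse = " + ")))
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 100)
  fit <- if (variance == "robust")
    survival::coxph(f, data = dat, ties = ties, control = ctrl,
                    cluster = recruit_id, x = FALSE, y = FALSE) else
    survival::coxph(f, data = dat, ties = ties, control = ctrl,
                    x = FALSE, y = FALSE)
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("collinear design columns, no unique partial-likelihood maximum: ",
         paste(terms[is.na(beta)], collapse = ", "))
  names(beta) <- terms
  V <- stats::vcov(fit)
  dimnames(V) <- list(terms, terms)
  se <- sqrt(diag(V))
  summ <- data.frame(term = terms, coef = unname(beta), se = unname(se),
                     hr = exp(unname(beta)),
                     lo95 = exp(unname(beta - 1.96 * se)),
                     hi95 = exp(unname(beta + 1.96 * se)),
                     p = 2 * stats::pnorm(-abs(unname(beta / se))))
  tv_items <- attr(stacked, "tv_items")
  k <- length(tv_items)
  cs <- coefficient_set(gamma = beta[1:9],
                        beta1 = beta[9 + seq_len(k)],
                        beta2 = beta[9 + k + seq_len(k)])
  names(cs$beta1) <- names(cs$beta2) <- tv_items
  out <- structure(list(coefficients = beta,
                        coef_set = cs,
                        vcov = V,
                        summary = summ,
                        loglik = fit$loglik[2],
                        n = nrow(stacked), nevent = sum(stacked$event),
                        ties = ties, variance = variance,
                        coding = attr(stacked, "coding"),
                        tv_items = tv_items,
                        duration_weeks = attr(stacked, "duration_weeks"),
                        iter = fit$iter),
                   class = "supermodel_fit")
  out$baseline_hazard <- breslow_baseline(out, stacked)
  out
}

#' @export
print.supermodel_fit <- function(x, ...) {
  cat("Landmark Cox supermodel:", x$n, "stacked rows,", x$nevent,
      "events;", x$ties, "ties,", x$variance, "variance, coding",
      x$coding, "\n\n")
  s <- x$summary
  s[, -1] <- lapply(s[, -1], function(v) signif(v, 3))
  print(s, row.names = FALSE)
  invisible(x)
}

#' Breslow cumulative baseline hazard
#'
#' At each event day t the hazard increment is d_t / sum over the at-risk
#' rows (start < t <= stop) of exp(LP). With the design centred at the
#' reference subject this is the reference subject's hazard. The cumulative
#' function is a right-continuous nondecreasing step function.
#'
#' @param fit a `supermodel_fit`, or a named coefficient vector matching the
#'   stacked design columns.
#' @param stacked the `stacked_landmarks` data the fit was estimated on.
#' @return data.frame with `time` (event day), `increment` and `cumhaz`.
#' @export
breslow_baseline <- function(fit, stacked) {
  beta <- if (inherits(fit, "supermodel_fit")) fit$coefficients else fit
  terms <- names(beta)
  elp <- exp(drop(as.matrix(stacked[, terms, drop = FALSE]) %*% beta))
  days <- sort(unique(stacked$stop[stacked$event == 1]))
  inc <- vapply(days, function(t) {
    d <- sum(stacked$event == 1 & stacked$stop == t)
    d / sum(elp[stacked$start < t & t <= stacked$stop])
  }, numeric(1))
  data.frame(time = days, increment = inc, cumhaz = cumsum(inc))
}

# Cumulative baseline hazard evaluated at `day` (right-continuous).
cumhaz_at <- function(baseline_hazard, day) {
  vapply(day, function(d) {
    i <- baseline_hazard$time <= d
    if (any(i)) baseline_hazard$cumhaz[max(which(i))] else 0
  }, numeric(1))
}

#' Pool fits with Rubin's rules
#'
#' Combines coefficient estimates and variances across m fits on imputed
#' datasets: pooled estimate = mean; total variance = mean within-variance
#' plus (1 + 1/m) times the between-imputation variance; normal-quantile
#' confidence intervals.
#'
#' @param fits list of `supermodel_fit` objects (or lists with
#'   `coefficients` and `vcov`) with identical coefficient orderings.
#' @return data.frame with pooled `coef`, `se`, `hr`, 95% CI and `p` per
#'   term.
#' @export
pool_rubin <- function(fits) {
  stopifnot(length(fits) >= 1)
  nm <- names(fits[[1]]$coefficients)
  est <- sapply(fits, function(f) {
    if (!identical(names(f$coefficients), nm))
      stop("mismatched coefficient orderings across fits")
    f$coefficients
  })
  est <- matrix(est, nrow = length(nm), dimnames = list(nm, NULL))
  wi <- sapply(fits, function(f) diag(f$vcov))
  wi <- matrix(wi, nrow = length(nm))
  m <- length(fits)
  qbar <- rowMeans(est)
  wbar <- rowMeans(wi)
  b <- if (m > 1) apply(est, 1, stats::var) else rep(0, length(nm))
  total <- wbar + (1 + 1 / m) * b
  se <- sqrt(total)
  data.frame(term = nm, coef = unname(qbar), se = unname(se),
             between_var = unname(b), within_var = unname(wbar),
             hr = exp(unname(qbar)), lo95 = exp(unname(qbar - 1.96 * se)),
             hi95 = exp(unname(qbar + 1.96 * se)),
             p = 2 * stats::pnorm(-abs(unname(qbar / se))), row.names = NULL)
}

#' Reference-centred linear predictor
#'
#' The supermodel score LP = (Z(s) - Z_ref)(beta1 + beta2 code(s)) +
#' (X - X_ref) gamma. The reference subject scores exactly 0 at every
#' landmark.
#'
#' @param object a `supermodel_fit` or a [coefficient_set()].
#' @param subject named list of raw covariate values (as
#'   [reference_subject()]): `height`, `body_mass`, `age`, `education`,
#'   `body_fat`, `cooper`, `pushups`, `situps`, the Likert items, `pain`.
#' @param s landmark index.
#' @param coding interaction coding; defaults to the fit's own, or
#'   `"s_minus_1"` for a bare coefficient set.
#' @return numeric linear predictor.
#' @export
linear_predictor <- function(object, subject, s, coding = NULL) {
  if (inherits(object, "supermodel_fit")) {
    cs <- object$coef_set
    if (is.null(coding)) coding <- object$coding
  } else if (inherits(object, "coefficient_set")) {
    cs <- object
    if (is.null(coding)) coding <- "s_minus_1"
  } else stop("object must be a supermodel_fit or coefficient_set")
  tv_items <- names(cs$beta1)
  need <- c("height", "body_mass", "age", "education", "body_fat",
            "cooper", "pushups", "situps", tv_items)
  have <- intersect(need, names(subject))
  miss <- c(setdiff(need, names(subject)),
            have[vapply(have, function(nm) anyNA(subject[[nm]]), logical(1))])
  if (length(miss))
    stop("missing covariate(s): ", paste(unique(miss), collapse = ", "))
  bdf <- as.data.frame(subject[c("height", "body_mass", "age", "education",
                                 "body_fat", "cooper", "pushups", "situps")])
  xb <- baseline_design(bdf)
  zc <- tv_design(as.data.frame(subject[tv_items]), tv_items)
  code <- landmark_code(s, coding)
  drop(xb %*% cs$gamma + zc %*% (cs$beta1 + cs$beta2 * code))
}

#' Conditional dropout probability
#'
#' Probability that a recruit at risk at landmark s drops out within
#' `horizon_weeks`, holding covariates at their landmark-s values:
#' 1 - exp(-(H0(7(s+h)) - H0(7s)) exp(LP(s))).
#'
#' @param fit a `supermodel_fit`.
#' @param subject named list of raw covariates (see [linear_predictor()]).
#' @param s landmark index.
#' @param horizon_weeks prediction horizon in weeks (>= 0).
#' @return probability in [0, 1].
#' @export
conditional_dropout_probability <- function(fit, subject, s,
                                            horizon_weeks = 1) {
  stopifnot(inherits(fit, "supermodel_fit"), horizon_weeks >= 0)
  W <- fit$duration_weeks
  if (!is.null(W) && 7 * (s + horizon_weeks) > 7 * W)
    stop("horizon extends beyond the end of training (week ", W, ")")
  if (horizon_weeks == 0) return(0)
  lp <- linear_predictor(fit, subject, s)
  dH <- cumhaz_at(fit$baseline_hazard, 7 * (s + horizon_weeks)) -
    cumhaz_at(fit$baseline_hazard, 7 * s)
  1 - exp(-dH * exp(lp))
}
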