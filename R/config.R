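# Predictor naming, in the fixed column order of the supermodel design:
# 9 baseline terms, 6 time-varying terms, 6 landmark-interaction terms.
.baseline_terms <- c("height", "body_mass", "age", "education1", "education2",
                     "body_fat", "cooper", "pushups10", "situps10")
.likert_items <- c("health", "motivated", "soreness", "sleep",
                   "mentalfit", "physical_fitness")
# Items entering the model by default (mentalfit is screened out on real-like
# data; it carries a zero true effect in the generator).
.model_items <- c("health", "motivated", "soreness", "sleep",
                  "physical_fitness", "pain")

#' Predictor term names of the landmark supermodel
#'
#' Returns the 21 design-column names in their canonical order: nine baseline
#' terms, six time-varying terms, and the six landmark-interaction terms
#' (suffix `"_lm"`).
#'
#' @param tv_items character vector of time-varying item names (default the
#'   six retained after screening: five Likert items plus the pain indicator).
#' @return character vector of column names.
#' @export
predictor_terms <- function(tv_items = .model_items) {
  c(.baseline_terms, tv_items, paste0(tv_items, "_lm"))
}

#' Published hazard ratios of the attrition supermodel
#'
#' The 21 multivariable hazard ratios of the development study, used as the
#' default true effects of the synthetic cohort generator. Baseline terms are
#' per natural unit (height in metres, push-ups and sit-ups per 10
#' repetitions); time-varying terms are per Likert point (pain per state
#' change), interactions per Likert point per landmark.
#'
#' @return named numeric vector of length 21.
#' @export
published_hazard_ratios <- function() {
  hr <- c(0.674, 0.957, 0.967, 0.913, 0.675, 1.034, 0.157, 0.984, 0.999,
          0.984, 0.655, 1.053, 1.048, 0.792, 0.673,
          0.992, 1.018, 0.998, 1.004, 1.007, 0.999)
  names(hr) <- predictor_terms()
  hr
}

#' Coefficient set for the landmark supermodel
#'
#' Bundles the three coefficient blocks of the stacked supermodel hazard
#' h(t | Z(s), s) = h0(t) exp(Z(s) (beta1 + beta2 code(s)) + X gamma):
#' `gamma` (9 baseline effects), `beta1` (6 time-varying main effects) and
#' `beta2` (6 landmark interactions).
#'
#' @param gamma named 9-vector of baseline log hazard ratios.
#' @param beta1 named 6-vector of time-varying main-effect log hazard ratios.
#' @param beta2 named 6-vector of landmark-interaction log hazard ratios.
#' @return object of class `coefficient_set`.
#' @export
coefficient_set <- function(gamma, beta1, beta2) {
  stopifnot(length(gamma) == 9L, length(beta1) == length(beta2))
  if (is.null(names(gamma))) names(gamma) <- .baseline_terms
  stopifnot(all(is.finite(c(gamma, beta1, beta2))))
  structure(list(gamma = gamma, beta1 = beta1, beta2 = beta2),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("Coefficient set:", length(x$gamma), "baseline,",
      length(x$beta1), "time-varying,", length(x$beta2), "interaction terms\n")
  print(round(as_vector.coefficient_set(x), 4))
  invisible(x)
}

as_vector.coefficient_set <- function(x) {
  v <- c(x$gamma, x$beta1, x$beta2)
  names(v) <- predictor_terms(names(x$beta1))
  v
}

#' Default true coefficients of the generator
#'
#' Log hazard ratios of [published_hazard_ratios()], arranged as a
#' [coefficient_set()]. These drive the synthetic dropout hazard.
#'
#' @return a `coefficient_set`.
#' @export
default_coefficients <- function() {
  lhr <- log(published_hazard_ratios())
  coefficient_set(gamma = lhr[1:9],
                  beta1 = stats::setNames(lhr[10:15], .model_items),
                  beta2 = stats::setNames(lhr[16:21], .model_items))
}

#' The reference subject
#'
#' The subject at which linear predictors are centred so that their score is
#' exactly zero at every landmark: a 23-year-old, 1.80 m, 80 kg recruit with
#' 14% body fat, 2.8 km Cooper distance, 55 push-ups and 55 sit-ups, unknown
#' education, all Likert responses neutral (5), and no reported pain.
#'
#' @return named list of raw covariate values.
#' @export
reference_subject <- function() {
  list(height = 1.80, body_mass = 80, age = 23, education = "unknown",
       body_fat = 14, cooper = 2.8, pushups = 55, situps = 55,
       health = 5, motivated = 5, soreness = 5, sleep = 5,
       mentalfit = 5, physical_fitness = 5, pain = 0)
}

# Baseline covariate targets: observed cohort mean/SD with the eligibility
# limits enforced at enlistment. Pre-truncation means are re-solved so the
# realised (truncated) means match the targets.
.baseline_spec <- function() {
  data.frame(
    covariate = c("height", "body_mass", "age", "body_fat",
                  "cooper", "pushups", "situps"),
    mean  = c(1.81, 77.9, 21, 13.6, 2.87, 54.2, 55.0),
    sd    = c(0.064, 7.9, 2.4, 3.1, 0.158, 11.5, 7.5),
    lower = c(1.65, 65, 17.5, 3, 2.7, 30, 30),
    upper = c(Inf, Inf, 27.9, Inf, Inf, Inf, Inf),
    stringsAsFactors = FALSE
  )
}

#' Missingness configuration
#'
#' Probabilities controlling how a complete simulated cohort is degraded to
#' the observed-data patterns: recruits with at least one missing baseline
#' field, left-truncated weekly series, week-1 dropouts without any status
#' observation, and the missing-not-at-random erasure of the mental-fitness
#' item (probability of erasure increases with `mnar_strength` times
#' (10 - latent value), with the intercept solved so the overall missing
#' fraction equals `p_mnar_mentalfit`).
#'
#' @param p_missing_baseline fraction of recruits with >= 1 missing baseline
#'   field (default 0.08).
#' @param p_left_truncated fraction of recruits whose first weeks of status
#'   are deleted (default 0.04).
#' @param p_week1_dropout_no_obs fraction of the cohort that are week-1
#'   dropouts with zero status rows (default 0.014).
#' @param p_mnar_mentalfit overall missing fraction of the mental-fitness
#'   item (default 0.61).
#' @param mnar_strength logistic slope linking low latent mental fitness to
#'   erasure (default 0.8 per Likert point).
#' @param p_missing_exit fraction of dropouts without an exit survey
#'   (default 0.06).
#' @return object of class `missingness_config`.
#' @export
missingness_config <- function(p_missing_baseline = 0.08,
                               p_left_truncated = 0.04,
                               p_week1_dropout_no_obs = 0.014,
                               p_mnar_mentalfit = 0.61,
                               mnar_strength = 0.8,
                               p_missing_exit = 0.06) {
  p <- c(p_missing_baseline, p_left_truncated, p_week1_dropout_no_obs,
         p_mnar_mentalfit, p_missing_exit)
  if (any(p < 0 | p > 1)) stop("missingness probabilities must lie in [0, 1]")
  if (mnar_strength < 0) stop("mnar_strength must be non-negative")
  structure(list(p_missing_baseline = p_missing_baseline,
                 p_left_truncated = p_left_truncated,
                 p_week1_dropout_no_obs = p_week1_dropout_no_obs,
                 p_mnar_mentalfit = p_mnar_mentalfit,
                 mnar_strength = mnar_strength,
                 p_missing_exit = p_missing_exit),
            class = "missingness_config")
}

#' Generator configuration
#'
#' Assembles every parameter of the synthetic cohort generator. Defaults
#' reproduce the development cohort's conditions: baseline marginals with
#' eligibility truncation, education mixture 25/17/58, stationary AR(1)
#' weekly Likert dynamics, the published log hazard ratios as true effects,
#' a calibrated geometric weekly base hazard hitting 54.8% total dropout
#' with 22% of dropouts in the first four weeks, the 137/240/27 dropout
#' reason mixture, and the observed missingness pattern.
#'
#' @param n_recruits number of recruits.
#' @param duration_weeks training length in weeks (default 24).
#' @param baseline_spec data frame of per-covariate mean/sd/lower/upper.
#' @param education_probs probabilities of education level 1, level 2 and
#'   unknown (reference); must sum to 1.
#' @param likert_item_means per-item population mean of the latent Likert
#'   trajectory (named, defaults 7 for every item).
#' @param likert_intercept_sd SD of the recruit-level item intercept.
#' @param likert_ar_coef AR(1) coefficient of the latent weekly dynamics,
#'   in (0, 1).
#' @param likert_noise_sd innovation SD of the latent dynamics (>= 0).
#' @param true_coefficients a [coefficient_set()] of true log hazard ratios.
#' @param weekly_base_hazard non-negative vector of length `duration_weeks`;
#'   default the calibrated geometric hazard ([default_base_hazard()]).
#' @param injury_weekly_prob weekly probability of a new pain report.
#' @param pain_reason_multiplier up-weighting of the injury dropout reason
#'   for recruits with a pain report by their dropout week.
#' @param reason_mixture probabilities of reasons injury / individual
#'   request / other; must sum to 1.
#' @param missingness a [missingness_config()].
#' @param landmark_coding `"s_minus_1"` (default) or `"s"`: the landmark
#'   index code entering the interaction terms.
#' @param seed integer master seed; all sub-generators draw from named
#'   streams derived from it.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_recruits,
                             duration_weeks = 24L,
                             baseline_spec = .baseline_spec(),
                             education_probs = c(level1 = 0.25, level2 = 0.17,
                                                 unknown = 0.58),
                             likert_item_means = stats::setNames(
                               rep(7, 6), .likert_items),
                             likert_intercept_sd = 1.0,
                             likert_ar_coef = 0.6,
                             likert_noise_sd = 0.8,
                             true_coefficients = default_coefficients(),
                             weekly_base_hazard = default_base_hazard(duration_weeks),
                             injury_weekly_prob = 0.01,
                             pain_reason_multiplier = 3,
                             reason_mixture = c(injury = 137, individual_request = 240,
                                                other = 27) / 404,
                             missingness = missingness_config(),
                             landmark_coding = c("s_minus_1", "s"),
                             seed = 1L) {
  landmark_coding <- match.arg(landmark_coding)
  if (n_recruits < 0) stop("n_recruits must be non-negative")
  if (duration_weeks < 2) stop("duration_weeks must be at least 2")
  if (abs(sum(education_probs) - 1) > 1e-12)
    stop("education_probs must sum to 1")
  if (abs(sum(reason_mixture) - 1) > 1e-12)
    stop("reason_mixture must sum to 1")
  if (likert_ar_coef <= 0 || likert_ar_coef >= 1)
    stop("likert_ar_coef must lie strictly in (0, 1)")
  if (likert_noise_sd < 0) stop("likert_noise_sd must be non-negative")
  if (length(weekly_base_hazard) != duration_weeks)
    stop("weekly_base_hazard must have length duration_weeks")
  if (any(weekly_base_hazard < 0)) stop("weekly_base_hazard must be non-negative")
  if (injury_weekly_prob < 0 || injury_weekly_prob > 1)
    stop("injury_weekly_prob must lie in [0, 1]")
  stopifnot(inherits(missingness, "missingness_config"),
            inherits(true_coefficients, "coefficient_set"))
  structure(list(n_recruits = as.integer(n_recruits),
                 duration_weeks = as.integer(duration_weeks),
                 baseline_spec = baseline_spec,
                 education_probs = education_probs,
                 likert_item_means = likert_item_means,
                 likert_intercept_sd = likert_intercept_sd,
                 likert_ar_coef = likert_ar_coef,
                 likert_noise_sd = likert_noise_sd,
                 true_coefficients = true_coefficients,
                 weekly_base_hazard = weekly_base_hazard,
                 injury_weekly_prob = injury_weekly_prob,
                 pain_reason_multiplier = pain_reason_multiplier,
                 reason_mixture = reason_mixture,
                 missingness = missingness,
                 landmark_coding = landmark_coding,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat("  recruits:", x$n_recruits, " duration:", x$duration_weeks, "weeks\n")
  cat("  landmark coding:", x$landmark_coding, " seed:", x$seed, "\n")
  invisible(x)
}
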