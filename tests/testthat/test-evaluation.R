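test_that("dynamic AUC matches the pairwise definition", {
  te <- toy_eval(case_lp = c(2, 3), control_lp = c(0, 1))
  expect_equal(dynamic_auc(te$lps, te$outcomes, 28), 1.0)
  te <- toy_eval(1, 1)
  expect_equal(dynamic_auc(te$lps, te$outcomes, 28), 0.5)
  te <- toy_eval(c(0.2, 0.8), c(0.5, 0.1, 0.9))
  expect_equal(dynamic_auc(te$lps, te$outcomes, 28), 0.5)  # 3 wins of 6 pairs

  set.seed(99)
  for (rep in 1:20) {
    cases <- round(rnorm(sample(1:8, 1)), 1)     # rounding forces ties
    controls <- round(rnorm(sample(1:8, 1)), 1)
    te <- toy_eval(cases, controls)
    expect_equal(dynamic_auc(te$lps, te$outcomes, 28),
                 oracle_auc(cases, controls))
  }
  # zero cases or controls -> missing, not an error
  te <- toy_eval(numeric(0), c(1, 2))
  expect_true(is.na(dynamic_auc(te$lps, te$outcomes, 28)))
})

test_that("dynamic ROC is internally consistent and finds the Youden optimum", {
  te <- toy_eval(c(2, 3), c(0, 1))
  roc <- dynamic_roc(te$lps, te$outcomes, 28)
  expect_equal(roc$optimal$sensitivity, 1)
  expect_equal(roc$optimal$specificity, 1)
  expect_true(roc$optimal$threshold > 1 && roc$optimal$threshold <= 2)

  te <- toy_eval(0.8, c(0.1, 0.9))
  roc <- dynamic_roc(te$lps, te$outcomes, 28)
  expect_equal(roc$optimal$threshold, 0.8)
  expect_equal(roc$optimal$sensitivity, 1.0)
  expect_equal(roc$optimal$specificity, 0.5)

  set.seed(100)
  for (rep in 1:10) {
    cases <- round(rnorm(sample(2:8, 1)), 1)
    controls <- round(rnorm(sample(2:8, 1)), 1)
    te <- toy_eval(cases, controls)
    roc <- dynamic_roc(te$lps, te$outcomes, 28)
    expect_equal(roc$auc, dynamic_auc(te$lps, te$outcomes, 28),
                 tolerance = 1e-12)
    expect_true(all(diff(roc$curve$sensitivity) >= 0))
    expect_true(all(diff(1 - roc$curve$specificity) >= 0))
    expect_equal(roc$curve$sensitivity[c(1, nrow(roc$curve))], c(0, 1))
    expect_equal(1 - roc$curve$specificity[c(1, nrow(roc$curve))], c(0, 1))
  }
})

test_that("AUC is invariant under strictly increasing transforms of the scores", {
  set.seed(101)
  cases <- rnorm(6); controls <- rnorm(9)
  te <- toy_eval(cases, controls)
  a0 <- dynamic_auc(te$lps, te$outcomes, 28)
  te$lps$lp <- 3 * te$lps$lp + 2
  expect_equal(dynamic_auc(te$lps, te$outcomes, 28), a0)
  te$lps$lp <- stats::plogis(te$lps$lp)
  expect_equal(dynamic_auc(te$lps, te$outcomes, 28), a0)
})

test_that("cases are scored at their pre-event landmark, controls at the evaluation day", {
  # the case is scored at its latest landmark before the event day, the
  # control at the latest landmark at or before the evaluation day
  lps <- data.frame(recruit_id = c(1, 1, 2, 2),
                    landmark = c(3, 4, 3, 4),
                    lp = c(5, -5, 0, 1))
  mk_out <- function(case_time)
    data.frame(recruit_id = 1:2, time = c(case_time, 168L),
               status = c(1L, 0L))
  # event day 25 -> case landmark 3 (lp 5) beats control landmark 4 (lp 1)
  expect_equal(dynamic_auc(lps, mk_out(25L), 28), 1)
  # event day 30 -> case landmark 4 (lp -5) loses to the same control
  expect_equal(dynamic_auc(lps, mk_out(30L), 28), 0)
})

test_that("repeated stratified CV is deterministic and partitions recruits", {
  s <- sim_clean(n = 250, seed = 32L)
  cv1 <- cross_validate(s$clean, k = 5, repeats = 2, seed = 13L,
                        eval_days = c(28, 84))
  cv2 <- cross_validate(s$clean, k = 5, repeats = 2, seed = 13L,
                        eval_days = c(28, 84))
  expect_identical(cv1$auc, cv2$auc)
  for (f in cv1$folds) {
    expect_setequal(f$recruit_id, s$clean$outcomes$recruit_id)
    expect_equal(sort(unique(f$fold)), 1:5)
    expect_equal(anyDuplicated(f$recruit_id), 0)
  }
  expect_true(all(cv1$auc >= 0 & cv1$auc <= 1, na.rm = TRUE))
})

test_that("baseline-only comparison ignores the weekly data", {
  s <- sim_clean(n = 250, seed = 33L)
  cmp <- compare_baseline_only(s$clean, eval_days = c(28, 84))
  cl2 <- s$clean
  idx <- sample(nrow(cl2$weekly))
  cl2$weekly[, cl2$tv_items] <- cl2$weekly[idx, cl2$tv_items]
  # permuting weekly columns breaks the stack (NA pattern) only for the
  # supermodel; the baseline model must be unchanged
  cmp2 <- try(compare_baseline_only(cl2, eval_days = c(28, 84)), silent = TRUE)
  if (!inherits(cmp2, "try-error")) {
    expect_equal(cmp2$baseline_coef, cmp$baseline_coef, tolerance = 1e-10)
    expect_equal(cmp2$auc$auc_baseline, cmp$auc$auc_baseline,
                 tolerance = 1e-10)
  }
  expect_true(all(cmp$auc$auc_supermodel >= 0 & cmp$auc$auc_supermodel <= 1))
})

test_that("dropout reasons and early exit statements are tabulated by the >=7 rule", {
  out <- data.frame(
    recruit_id = 1:4,
    time = c(10L, 20L, 25L, 100L),
    status = c(1L, 1L, 1L, 1L),
    reason = c("injury", "individual_request", "other", "injury"),
    exit_preparation = c(8, 7, NA, 9),
    exit_physical = c(2, 7, NA, 9),
    exit_mental = c(5, 1, NA, 9),
    exit_physician = c(5, 1, NA, 9),
    exit_injury = c(5, 1, NA, 9))
  r <- summarize_dropout_reasons(out)
  expect_equal(as.integer(r$reason_counts[c("injury", "individual_request",
                                            "other")]), c(2L, 1L, 1L))
  expect_equal(sum(r$reason_counts), r$n_dropouts)
  expect_equal(r$early$n, 3)                      # days 10, 20, 25
  expect_equal(unname(r$early$statement_counts["exit_preparation"]), 2L)
  expect_equal(unname(r$early$statement_counts["exit_physical"]), 1L)
  expect_equal(r$early$n_missing_survey, 1)
  r2 <- summarize_dropout_reasons(out, agree_threshold = 11)
  expect_true(all(r2$early$statement_counts == 0))
})
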