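test_that("baseline generator hits target means and respects eligibility limits", {
  cfg <- generator_config(n_recruits = 10000, seed = 11L)
  b <- generate_baseline(cfg)
  expect_equal(nrow(b), 10000)
  expect_lt(abs(mean(b$body_mass) - 77.9), 0.3)
  expect_lt(abs(mean(b$height) - 1.81), 0.005)
  expect_lt(abs(mean(b$cooper) - 2.87), 0.01)
  expect_gte(min(b$height), 1.65)
  expect_gte(min(b$body_mass), 65)
  expect_gte(min(b$cooper), 2.7)
  expect_gte(min(b$pushups), 30)
  expect_true(all(b$age >= 17.5 & b$age <= 27.9))
  p <- prop.table(table(b$education))
  expect_lt(max(abs(p[c("level1", "level2", "unknown")] -
                      c(0.25, 0.17, 0.58))), 0.03)
})

test_that("empty cohort and infeasible truncation are handled", {
  cfg <- generator_config(n_recruits = 0, seed = 1L)
  b <- generate_baseline(cfg)
  expect_equal(nrow(b), 0)
  spec <- generator_config(n_recruits = 5, seed = 1L)$baseline_spec
  spec$lower[spec$covariate == "body_mass"] <- 100   # target mean 77.9 below bound
  expect_error(generate_baseline(
    generator_config(n_recruits = 5, seed = 1L, baseline_spec = spec)),
    "infeasible")
})

test_that("noiseless trajectories are constant and Likert values stay in 1..10", {
  cfg <- generator_config(n_recruits = 20, seed = 3L,
                          likert_item_means = stats::setNames(rep(5, 6),
                            c("health", "motivated", "soreness", "sleep",
                              "mentalfit", "physical_fitness")),
                          likert_intercept_sd = 0, likert_noise_sd = 0)
  tr <- generate_trajectories(generate_baseline(cfg), cfg)
  expect_true(all(tr$observed == 5))
  cfg2 <- generator_config(n_recruits = 200, seed = 4L)
  tr2 <- generate_trajectories(generate_baseline(cfg2), cfg2)
  expect_true(all(tr2$observed >= 1 & tr2$observed <= 10))
  expect_error(generator_config(n_recruits = 5, likert_ar_coef = 1.2),
               "likert_ar_coef")
})

test_that("latent series have the configured lag-1 autocorrelation", {
  cfg <- generator_config(n_recruits = 2000, seed = 5L)
  tr <- generate_trajectories(generate_baseline(cfg), cfg)
  dev <- tr$latent[, , "motivated"] - tr$intercepts[, "motivated"]
  ac <- cor(as.vector(dev[, -24]), as.vector(dev[, -1]))
  expect_lt(abs(ac - cfg$likert_ar_coef), 0.03)
})

test_that("null hazard yields no dropouts; constant hazard matches closed-form survival", {
  zero <- coefficient_set(gamma = rep(0, 9),
                          beta1 = stats::setNames(rep(0, 6), recruitrisk:::.model_items),
                          beta2 = stats::setNames(rep(0, 6), recruitrisk:::.model_items))
  cfg0 <- generator_config(n_recruits = 50, seed = 6L,
                           weekly_base_hazard = rep(0, 24))
  co0 <- simulate_cohort(cfg0, degrade = FALSE)
  expect_true(all(co0$outcomes$status == 0))
  expect_true(all(co0$outcomes$time == 168))

  h <- 0.05
  cfg <- generator_config(n_recruits = 6000, seed = 7L,
                          true_coefficients = zero,
                          weekly_base_hazard = rep(h, 24))
  co <- simulate_cohort(cfg, degrade = FALSE)
  expect_true(all(abs(co$truth$lp) < 1e-12))
  for (w in c(4, 12, 24)) {
    surv_emp <- mean(co$outcomes$time > 7 * w |
                       (co$outcomes$status == 0 & w == 24))
    expect_lt(abs(surv_emp - exp(-h * w)), 0.02)
  }
  expect_true(all(co$outcomes$time[co$outcomes$status == 1] >= 1))
  expect_true(all(co$outcomes$time <= 168))
})

test_that("truth record replays through the supermodel linear predictor", {
  cfg <- generator_config(n_recruits = 40, seed = 8L)
  co <- simulate_cohort(cfg, degrade = FALSE)
  cs <- cfg$true_coefficients
  for (i in c(1, 17, 40)) {
    b <- co$baseline[i, ]
    for (w in c(1, 2, 9, 24)) {
      s_eff <- max(w - 1, 1)
      subject <- list(height = b$height, body_mass = b$body_mass, age = b$age,
                      education = as.character(b$education),
                      body_fat = b$body_fat, cooper = b$cooper,
                      pushups = b$pushups, situps = b$situps)
      wk <- co$truth   # observed items at week s_eff via the weekly table
      row <- co$weekly[co$weekly$recruit_id == b$recruit_id &
                         co$weekly$week == s_eff, ]
      if (nrow(row) == 0) next  # dropped out before week s_eff survey
      for (it in c("health", "motivated", "soreness", "sleep",
                   "physical_fitness"))
        subject[[it]] <- row[[it]]
      subject$pain <- co$truth$ever_pain[i, s_eff]
      lp <- linear_predictor(cs, subject, s_eff,
                             coding = cfg$landmark_coding)
      expect_equal(lp, co$truth$lp[i, w], tolerance = 1e-10)
      expect_equal(co$truth$prob[i, w], 1 - exp(-co$truth$hazard[i, w]),
                   tolerance = 1e-12)
    }
  }
})

test_that("missingness degrades to the configured patterns and is MNAR for mental fitness", {
  cfg <- generator_config(n_recruits = 4000, seed = 9L)
  co <- simulate_cohort(cfg)                       # degraded
  n <- nrow(co$baseline)
  num <- c("height", "body_mass", "age", "body_fat", "cooper",
           "pushups", "situps")
  frac_base <- mean(rowSums(is.na(co$baseline[, num])) > 0)
  expect_lt(abs(frac_base - 0.08), 0.02)
  expect_lt(abs(mean(is.na(co$weekly$mentalfit)) - 0.61), 0.03)

  lat <- co$truth$latent[cbind(co$weekly$recruit_id, co$weekly$week,
                               5L)]                # mentalfit latent
  expect_lt(mean(lat[is.na(co$weekly$mentalfit)]),
            mean(lat[!is.na(co$weekly$mentalfit)]))

  ent <- determine_entry(co$weekly, co$outcomes)
  expect_lt(abs(nrow(ent$exclusions) / n - 0.014), 0.008)
  expect_lt(abs(mean(ent$entry$entry_week > 1) - 0.04), 0.02)
})

test_that("zero missingness is the identity and streams are independent", {
  cfg <- generator_config(n_recruits = 120, seed = 10L,
                          missingness = missingness_config(0, 0, 0, 0, 0, 0))
  co <- simulate_cohort(cfg, degrade = FALSE)
  expect_identical(apply_missingness(co, cfg), co)

  cfg_a <- generator_config(n_recruits = 120, seed = 10L)
  co_a <- simulate_cohort(cfg_a)
  keep <- c("recruit_id", "time", "status", "dropout_week", "reason")
  expect_identical(co_a$outcomes[keep], co$outcomes[keep])  # streams separate
  co_b <- simulate_cohort(generator_config(n_recruits = 120, seed = 10L))
  expect_identical(co_a, co_b)                      # byte-identical under a seed
})

test_that("cohort planning arithmetic matches the design rules", {
  expect_identical(required_cohorts(10, 90, 0.5, 22), 5L)
  expect_identical(required_cohorts(10, 220, 1.0, 22), 1L)
  expect_identical(required_cohorts(10, 89, 0.5, 22), 5L)
  expect_error(required_cohorts(10, 90, 0, 22), "dropout_rate")
  expect_identical(events_per_predictor(744, 0.5, 22), 17L)
})
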