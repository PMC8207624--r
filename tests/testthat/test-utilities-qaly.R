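test_that("score-to-utility mapping applies link, clamp and errors", {
  const <- mapping_spec(0.5, numeric(0))
  expect_equal(map_scores_to_utility(c(global_health = 10), const), 0.5)
  boundary <- mapping_spec(0, c(global_health = 0.01))
  expect_equal(map_scores_to_utility(c(global_health = 100), boundary), 1)
  expect_equal(map_scores_to_utility(c(global_health = 150), boundary), 1)
  # inverse-logit of 0.2 + 0.01*60 - 0.005*40 = 0.6, hand-computed
  spec <- mapping_spec(0.2, c(global_health = 0.01, pain = -0.005),
                       link = "logit-inverse")
  expect_equal(
    map_scores_to_utility(c(global_health = 60, pain = 40), spec),
    0.64565631, tolerance = 1e-7)
  expect_error(map_scores_to_utility(c(global_health = 60), spec),
               "pain")
  df <- data.frame(global_health = c(60, 60), pain = c(40, 40))
  expect_equal(map_scores_to_utility(df, spec),
               rep(0.64565631, 2), tolerance = 1e-7)
})

test_that("dropout utilities follow the before/after-radiotherapy rule", {
  traj <- utility_traj(utility = c(0.8, NA, NA, NA),
                       dropout_reason = "hospitalization",
                       dropout_month = 1)
  out <- assign_dropout_utility(traj, end_of_rt_month = 2)
  expect_equal(out$utility, c(0.8, 0.35, 0.30, 0.30))

  dead <- utility_traj(utility = c(0.8, 0.6, NA, NA),
                       dropout_reason = "death", dropout_month = 3)
  out <- assign_dropout_utility(dead)
  expect_equal(out$utility, c(0.8, 0.6, 0, 0))
  # QALY accrues only before death: the last contribution is the ramp
  # down to zero on [2, 3], nothing afterwards
  expect_equal(qaly_auc(out$visit_month, out$utility),
               (1.4 + 0.3 + 0) / 12)

  complete <- utility_traj()
  expect_identical(assign_dropout_utility(complete)$utility,
                   complete$utility)
  # dropout after the final visit is a no-op
  late <- utility_traj(dropout_reason = "hospitalization",
                       dropout_month = 6)
  expect_identical(assign_dropout_utility(late)$utility, late$utility)
  # observed values are never overwritten; LTFU stays missing
  lost <- utility_traj(utility = c(0.8, 0.6, NA, NA),
                       dropout_reason = "lost", dropout_month = 3)
  expect_identical(assign_dropout_utility(lost)$utility,
                   lost$utility)
  # alternative literature utilities are parameters, not constants
  out <- assign_dropout_utility(traj, utility_before = 0.5,
                                utility_after = 0.4)
  expect_equal(out$utility, c(0.8, 0.5, 0.4, 0.4))
})

test_that("qaly_auc computes the interpolated area under the curve", {
  expect_equal(qaly_auc(c(0, 2, 3, 5), rep(1, 4)), 5 / 12)
  expect_equal(qaly_auc(c(0, 2, 3, 5), rep(0, 4)), 0)
  expect_equal(qaly_auc(c(0, 2, 3, 5), c(0.8, 0.6, 0.6, 0.8)),
               (1.4 + 0.6 + 1.4) / 12)
  expect_error(qaly_auc(c(0, 2, 3, 5), c(0.8, NA, 0.6, 0.8)),
               "impute")
  expect_error(qaly_auc(c(0, 2, 2, 5), rep(0.5, 4)), "increasing")
})

test_that("qaly_auc is monotone, linear, and interpolation-invariant", {
  set.seed(11)
  for (r in 1:20) {
    times <- sort(c(0, runif(3, 0.5, 5)))
    u <- runif(4)
    base <- qaly_auc(times, u)
    # raising any utility never decreases the QALY
    j <- sample(4, 1)
    up <- u
    up[j] <- min(1, up[j] + 0.1)
    expect_gte(qaly_auc(times, up), base)
    # linearity in utilities
    expect_equal(qaly_auc(times, u / 2), base / 2)
    # inserting a point interpolated on an existing segment changes nothing
    k <- sample(3, 1)
    tm <- (times[k] + times[k + 1]) / 2
    um <- (u[k] + u[k + 1]) / 2
    expect_equal(qaly_auc(sort(c(times, tm)), append(u, um, after = k)),
                 base)
  }
})

test_that("chained imputation is identity on complete data and errors early", {
  cfg <- noise_free_config(n = 6)
  tr <- generate_trial(cfg)
  imp <- impute_chained(tr$utilities, m = 3, seed = 1)
  expect_length(imp$datasets, 3)
  for (d in imp$datasets) expect_equal(d$utility, imp$datasets[[1]]$utility)
  expect_equal(sort(imp$datasets[[1]]$utility),
               sort(tr$utilities$utility))
  expect_error(impute_chained(tr$utilities, m = 1), "at least 2")
  broken <- tr$utilities
  broken$utility[broken$visit_month == 3] <- NA
  expect_error(impute_chained(broken, m = 2), "unidentifiable")
})

test_that("imputation preserves observed values and stays in [0, 1]", {
  cfg <- small_config(n = 40, seed = 12)
  tr <- generate_trial(cfg)
  u <- assign_dropout_utility(tr$utilities)
  imp <- impute_chained(u, m = 4, seed = 8)
  obs <- !is.na(u$utility)
  for (d in imp$datasets) {
    expect_false(anyNA(d$utility))
    expect_identical(d$utility[obs], u$utility[obs])
    expect_true(all(d$utility >= 0 & d$utility <= 1))
  }
  # deterministic given seed
  imp2 <- impute_chained(u, m = 4, seed = 8)
  expect_identical(lapply(imp$datasets, `[[`, "utility"),
                   lapply(imp2$datasets, `[[`, "utility"))
})

test_that("MCAR imputation recovers per-visit means within 3 SE", {
  cfg <- no_dropout_config(n = 150, seed = 21)
  tr <- generate_trial(cfg)
  complete <- tr$utilities
  holed <- complete
  set.seed(31)
  drop_idx <- which(runif(nrow(holed)) < 0.2 & holed$visit_month > 0)
  holed$utility[drop_idx] <- NA
  imp <- impute_chained(holed, m = 10, seed = 7)
  pooled <- Reduce(`+`, lapply(imp$datasets, `[[`, "utility")) / imp$m
  for (v in unique(complete$visit_month)) {
    sel <- complete$visit_month == v
    se <- sd(complete$utility[sel]) / sqrt(sum(sel))
    expect_lt(abs(mean(pooled[sel]) - mean(complete$utility[sel])),
              3 * se)
  }
})

test_that("per-patient QALYs pool as plain averages across imputations", {
  cfg <- small_config(n = 20, seed = 3)
  tr <- generate_trial(cfg)
  u <- assign_dropout_utility(tr$utilities)
  imp <- impute_chained(u, m = 3, seed = 2)
  q <- qaly_from_imputations(imp)
  per <- sapply(imp$datasets, function(d) qaly_by_patient(d)$qaly)
  expect_equal(q$qaly, rowMeans(per))
  expect_true(all(q$n_imputations == 3))
  # Rubin's rules: pooled estimate is the mean of per-dataset estimates
  est <- colMeans(per)
  pr <- pool_rubin(est, rep(0.001, 3))
  expect_equal(pr$estimate, mean(est))
  expect_equal(pr$variance, 0.001 + (1 + 1 / 3) * var(est))
})

test_that("noise-free LMM recovers the arm difference exactly", {
  d <- simulate_lmm_data(n_per_arm = 8, mean_t = c(0.8, 0.7, 0.7, 0.75),
                         mean_c = c(0.7, 0.6, 0.6, 0.65),
                         sd_b = 0, sd_e = 0)
  fit <- fit_random_intercept_lmm(d)
  expect_equal(unname(fit$fixed[["armtreatment"]]), 0.1, tolerance = 1e-8)
  expect_equal(unname(fit$varcomp[["intercept_var"]]), 0,
               tolerance = 1e-10)
  expect_error(fit_random_intercept_lmm(
    d[d$arm == "treatment", ]), "both arms")
})

test_that("LMM recovers variance components on simulated data", {
  set.seed(99)
  reps <- 10
  iv <- rv <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- simulate_lmm_data(n_per_arm = 100, sd_b = 0.1, sd_e = 0.05)
    fit <- fit_random_intercept_lmm(d)
    iv[r] <- fit$varcomp[["intercept_var"]]
    rv[r] <- fit$varcomp[["residual_var"]]
  }
  expect_lt(abs(mean(iv) - 0.01), 3 * sd(iv) / sqrt(reps))
  expect_lt(abs(mean(rv) - 0.0025), 3 * sd(rv) / sqrt(reps))
})

test_that("interaction LRT holds its level under the null", {
  set.seed(123)
  reps <- 150
  p <- vapply(seq_len(reps), function(r) {
    d <- simulate_lmm_data(n_per_arm = 60, sd_b = 0.08, sd_e = 0.05)
    fit_random_intercept_lmm(d)$lrt$p_value
  }, numeric(1))
  rej <- mean(p < 0.05)
  band <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gt(rej, 0.05 - max(band, 0.035) - 1e-9)
  expect_lt(rej, 0.05 + max(band, 0.035) + 1e-9)
})

test_that("mixed-model likelihood dominates the zero-variance OLS fit", {
  set.seed(7)
  d <- simulate_lmm_data(n_per_arm = 25, sd_b = 0.1, sd_e = 0.05)
  fit <- fit_random_intercept_lmm(d)
  ols <- lm(utility ~ arm * factor(visit_month), data = d)
  expect_gte(fit$loglik_ml, as.numeric(logLik(ols)) - 1e-6)
})
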