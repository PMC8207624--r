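test_that("trial_config validates fields and names the offender", {
  expect_error(trial_config(n_treatment = 0), "n_treatment")
  expect_error(trial_config(visit_months = c(1, 2, 3, 5)), "visit_months")
  expect_error(trial_config(visit_months = c(0, 3, 2, 5)), "visit_months")
  expect_error(trial_config(mcar_rate = 1.2), "mcar_rate")
  bad_um <- default_utility_model()
  bad_um$sd_residual <- -1
  expect_error(trial_config(utility_model = bad_um), "utility_model")
  bad_sm <- default_survival_model()
  bad_sm$hazard_late[1] <- -0.1
  expect_error(trial_config(survival_model = bad_sm), "survival_model")
})

test_that("generation is deterministic given the seed", {
  cfg <- small_config(n = 15)
  a <- generate_trial(cfg)
  b <- generate_trial(cfg)
  expect_identical(a$utilities, b$utilities)
  expect_identical(a$resources, b$resources)
  expect_identical(a$survival, b$survival)
  c <- generate_trial(cfg, seed = cfg$seed + 1)
  expect_false(identical(a$survival, c$survival))
})

test_that("noise-free configuration yields arm means at every visit", {
  cfg <- noise_free_config(n = 10)
  tr <- generate_trial(cfg)
  expect_false(anyNA(tr$utilities$utility))
  for (a in c("treatment", "control")) {
    mu <- if (a == "treatment") cfg$utility_model$mean_treatment else
      cfg$utility_model$mean_control
    for (v in seq_along(cfg$visit_months)) {
      got <- tr$utilities$utility[tr$utilities$arm == a &
                        tr$utilities$visit_month == cfg$visit_months[v]]
      expect_equal(got, rep(mu[v], 10))
    }
  }
  expect_true(all(tr$utilities$dropout_reason == "none"))
})

test_that("patient records respect structural invariants", {
  cfg <- small_config(n = 40, seed = 77)
  tr <- generate_trial(cfg)
  u <- tr$utilities
  expect_true(all(u$visit_month %in% cfg$visit_months))
  expect_true(all(u$utility >= 0 & u$utility <= 1, na.rm = TRUE))
  expect_false(anyNA(u[c("age", "gender", "malnourished", "tumor_site",
                         "tumor_stage", "handgrip", "phase_angle")]))
  s <- tr$survival
  expect_true(all(s$time_days >= 0))
  cens <- s$event == 0
  expect_equal(s$time_days[cens],
               round(as.numeric(cfg$admin_censor_date -
                                  s$accrual_date[cens])))
  expect_true(all(as.matrix(tr$resources[-(1:2)]) >= 0))
})

test_that("on-trial death counts match the configured early hazard", {
  cfg <- trial_config()  # default study-sized arms
  p_death <- 1 - exp(-cfg$survival_model$hazard_early[["treatment"]] *
                       5 * 30.4375)
  reps <- 200
  set.seed(1)
  deaths <- vapply(seq_len(reps), function(r) {
    tr <- generate_trial(cfg, seed = 1000 + r)
    sum(tr$survival$event == 1 &
          tr$survival$time_days <= 5 * 30.4375)
  }, numeric(1))
  n_tot <- reps * (cfg$n_treatment + cfg$n_control)
  expect_gt(sum(deaths), n_tot * p_death - 3 * sqrt(n_tot * p_death *
                                                      (1 - p_death)))
  expect_lt(sum(deaths), n_tot * p_death + 3 * sqrt(n_tot * p_death *
                                                      (1 - p_death)))
})

test_that("true_values symmetry: identical arms give zero increments", {
  cfg <- trial_config()
  cfg$utility_model$mean_control <- cfg$utility_model$mean_treatment
  cfg$cost_model$control <- cfg$cost_model$treatment
  cfg$survival_model$hazard_late["control"] <-
    cfg$survival_model$hazard_late[["treatment"]]
  tv <- true_values(cfg)
  expect_equal(tv$incremental$delta_cost, 0)
  expect_equal(tv$incremental$delta_qaly, 0)
  expect_equal(unname(tv$incremental$delta_rmst), rep(0, 6))
})

test_that("piecewise-exponential RMST matches closed form and quadrature", {
  # constant hazard: (1 - exp(-h tau)) / h
  h <- 0.002
  tau <- 800
  expect_equal(trialcea:::pexp_rmst(h, h, 365, tau),
               (1 - exp(-h * tau)) / h)
  # changepoint inside the horizon: numerical integration oracle
  h1 <- 0.002; h2 <- 0.0005; cp <- 300; tau <- 1000
  oracle <- integrate(function(t) trialcea:::pexp_surv(t, h1, h2, cp),
                      0, tau, rel.tol = 1e-10)$value
  expect_equal(trialcea:::pexp_rmst(h1, h2, cp, tau), oracle,
               tolerance = 1e-8)
  # zero-hazard degenerate case: RMST equals the horizon
  expect_equal(trialcea:::pexp_rmst(0, 0, 365, tau), tau)
})

test_that("empirical means converge to true_values at large n", {
  cfg <- no_dropout_config(n = 5000, seed = 314)
  tv <- true_values(cfg)
  tr <- generate_trial(cfg)
  costs <- suppressMessages(cost_breakdowns(tr$resources))
  q <- qaly_by_patient(tr$utilities)
  for (a in c("treatment", "control")) {
    ct <- costs$total[costs$arm == a]
    expect_lt(abs(mean(ct) - tv[[a]]$mean_cost),
              3 * sd(ct) / sqrt(length(ct)))
    qa <- q$qaly[q$arm == a]
    expect_lt(abs(mean(qa) - tv[[a]]$mean_qaly),
              3 * sd(qa) / sqrt(length(qa)))
  }
})

test_that("KM estimate tracks the configured survival function", {
  cfg <- trial_config(n_treatment = 6000, n_control = 10, seed = 2718)
  tr <- generate_trial(cfg)
  s <- tr$survival[tr$survival$arm == "treatment", ]
  curve <- km_fit(s$time_days, s$event)
  sm <- cfg$survival_model
  grid <- seq(0, 1300, by = 10)  # within every patient's follow-up
  est <- trialcea:::km_surv_at(curve, grid)
  truth <- trialcea:::pexp_surv(grid, sm$hazard_early[["treatment"]],
                                sm$hazard_late[["treatment"]],
                                sm$changepoint_days)
  expect_lt(max(abs(est - truth)), 0.02)
})

test_that("trial CSV round trip preserves the data", {
  cfg <- small_config(n = 8)
  tr <- generate_trial(cfg)
  dir <- withr::local_tempdir()
  write_trial_csv(tr, dir)
  back <- read_trial_csv(dir)
  expect_equal(back$survival$time_days, tr$survival$time_days)
  expect_equal(back$utilities$utility, tr$utilities$utility)
  expect_equal(back$resources[-(1:2)], tr$resources[-(1:2)],
               tolerance = 1e-12)
  expect_error(read_trial_csv(file.path(dir, "nope")), "missing input")
})
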