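# Independent check of the product-limit estimate by brute force.
brute_km <- function(time, event, t) {
  ev_times <- sort(unique(time[event == 1]))
  prod(vapply(ev_times[ev_times <= t], function(s) {
    n <- sum(time >= s)
    d <- sum(time == s & event == 1)
    1 - d / n
  }, numeric(1)))
}

test_that("km_fit reproduces hand product-limit arithmetic", {
  cv <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(cv$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(cv$n_risk, c(3, 2, 1))
  none <- km_fit(c(5, 8, 9), c(0, 0, 0))
  expect_length(none$time, 0)
  expect_equal(trialcea:::km_surv_at(none, c(0, 100)), c(1, 1))
  expect_error(km_fit(numeric(0), numeric(0)), "empty")
  # censoring at an event time stays in the risk set (events first)
  tie <- km_fit(c(2, 2, 3), c(1, 0, 1))
  expect_equal(tie$surv, c(2 / 3, 0))
})

test_that("km_fit equals brute force and the survival package", {
  set.seed(41)
  for (r in 1:20) {
    d <- random_survival_data(n = sample(5:20, 1))
    cv <- km_fit(d$time, d$event)
    for (t in unique(d$time)) {
      expect_equal(trialcea:::km_surv_at(cv, t),
                   brute_km(d$time, d$event, t))
    }
    sf <- summary(survival::survfit(
      survival::Surv(d$time, d$event) ~ 1))
    keep <- sf$n.event > 0
    expect_equal(cv$time, sf$time[keep])
    expect_equal(cv$surv, sf$surv[keep])
    # survfit reports NaN standard errors once the curve reaches zero
    fin <- is.finite(sf$std.err[keep])
    expect_equal(sqrt(cv$var)[fin], sf$std.err[keep][fin],
                 tolerance = 1e-8)
  }
})

test_that("reverse KM median follows the follow-up distribution", {
  # everyone administratively censored at day 2200
  flat <- reverse_km_median(rep(2200, 25), rep(0, 25))
  expect_true(flat$defined)
  expect_equal(flat$median, 2200)
  expect_equal(flat$ci, c(2200, 2200))
  # no censoring at all: the reverse curve never drops
  dead <- reverse_km_median(c(10, 20, 30), c(1, 1, 1))
  expect_false(dead$defined)
  expect_true(is.na(dead$median))
  # staggered accrual: median potential follow-up within calendar bounds
  cfg <- trial_config()
  tr <- generate_trial(cfg)
  s <- tr$survival
  rkm <- reverse_km_median(s$time_days, s$event)
  lo <- as.numeric(cfg$admin_censor_date - cfg$accrual_end)
  hi <- as.numeric(cfg$admin_censor_date - cfg$accrual_start)
  expect_true(rkm$defined)
  expect_gte(rkm$median, lo)
  expect_lte(rkm$median, hi)
  expect_true(rkm$ci[1] <= rkm$median && rkm$median <= rkm$ci[2])
})

test_that("rmst integrates the step function and hits the closed form", {
  # flat curve: RMST equals the horizon
  flat <- km_fit(rep(400, 10), rep(0, 10))
  expect_equal(rmst(flat, 365.25)$rmst, 1)
  # hand-computed two-step curve: S=1 on [0,100), 0.5 on [100,365)
  two <- km_fit(c(100, 365), c(1, 0))
  expect_equal(rmst(two, 365)$rmst, (100 + 0.5 * 265) / 365.25)
  expect_error(rmst(two, 1000), "exceeds")
  expect_error(rmst(two, 1000, arm = "control"), "control")
  # closed-form exponential oracle at n = 2000
  set.seed(43)
  h <- 1 / 500
  tm <- round(rexp(2000, h))
  cv <- km_fit(tm, rep(1, 2000))
  tau <- 730.5
  est <- rmst(cv, tau)
  truth <- (1 - exp(-h * tau)) / h / 365.25
  expect_lt(abs(est$rmst - truth), 3 * est$se)
  # monotone in tau and bounded by tau
  taus <- c(100, 300, 600, 730)
  vals <- vapply(taus, function(t) rmst(cv, t)$rmst, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals <= taus / 365.25 + 1e-12))
})

test_that("rmst difference is symmetric and its z-test behaves", {
  set.seed(44)
  a <- km_fit(round(rexp(300, 1 / 400)), rep(1, 300))
  b <- km_fit(round(rexp(300, 1 / 600)), rep(1, 300))
  d_ab <- rmst_difference(a, b, 365)
  d_ba <- rmst_difference(b, a, 365)
  expect_equal(d_ab$difference, -d_ba$difference)
  expect_equal(d_ab$p_value, d_ba$p_value)
  same <- rmst_difference(a, a, 365)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
})

test_that("weighted log-rank reduces to the classical log-rank", {
  set.seed(45)
  for (r in 1:25) {
    d <- random_survival_data(n = sample(12:40, 1))
    w <- weighted_logrank(d$time, d$event, d$arm, p = 0, q = 0)
    sd_fit <- survival::survdiff(
      survival::Surv(time, event) ~ arm, data = d, rho = 0)
    expect_equal(w$z^2, sd_fit$chisq, tolerance = 1e-9)
    # statistic sign: observed minus expected in the treatment arm
    grp <- which(sort(unique(d$arm)) == "treatment")
    expect_equal(w$statistic,
                 unname(sd_fit$obs[grp] - sd_fit$exp[grp]),
                 tolerance = 1e-9)
  }
})

test_that("weighted log-rank on mirrored arms is exactly zero", {
  d <- data.frame(time = c(3, 5, 8, 11, 3, 5, 8, 11),
                  event = c(1, 0, 1, 1, 1, 0, 1, 1),
                  arm = rep(c("treatment", "control"), each = 4))
  for (pq in list(c(0, 0), c(1, 0), c(0, 2))) {
    w <- weighted_logrank(d$time, d$event, d$arm, pq[1], pq[2])
    expect_equal(w$statistic, 0)
    expect_equal(w$p_value, 1)
  }
  expect_error(weighted_logrank(d$time, d$event, rep("a", 8)),
               "two arms")
})

test_that("late-emphasis weighting gains power under late separation", {
  cfg <- trial_config(n_treatment = 80, n_control = 80)
  reps <- 120
  p00 <- p02 <- numeric(reps)
  for (r in seq_len(reps)) {
    tr <- generate_trial(cfg, seed = 5000 + r)
    s <- tr$survival
    p00[r] <- weighted_logrank(s$time_days, s$event, s$arm, 0, 0)$p_value
    p02[r] <- weighted_logrank(s$time_days, s$event, s$arm, 0, 2)$p_value
  }
  expect_gt(mean(p02 < 0.05), mean(p00 < 0.05))
})

test_that("max-combo statistic, reduction and null behaviour", {
  set.seed(46)
  d <- random_survival_data(n = 40)
  mc <- maxcombo(d$time, d$event, d$arm, n_perm = 2000, seed = 3)
  # statistic is exactly the max of the component |z| values
  zs <- vapply(list(c(0, 0), c(1, 0), c(0, 2)), function(pq)
    weighted_logrank(d$time, d$event, d$arm, pq[1], pq[2])$z,
    numeric(1))
  expect_equal(mc$statistic, max(abs(zs)))
  expect_equal(unname(mc$z), zs)
  expect_true(mc$p_value >= 0 && mc$p_value <= 1)
  expect_gt(mc$mc_se, 0)
  # single-combo max-combo is a permutation log-rank test
  solo <- maxcombo(d$time, d$event, d$arm, combos = list(c(0, 0)),
                   n_perm = 2000, seed = 3)
  expect_equal(solo$statistic,
               abs(weighted_logrank(d$time, d$event, d$arm, 0, 0)$z))
  # mirrored arms: observed statistic is never exceeded... by chance only
  mirror <- data.frame(time = rep(c(2, 4, 6, 9), 2),
                       event = rep(c(1, 1, 0, 1), 2),
                       arm = rep(c("treatment", "control"), each = 4))
  mc0 <- maxcombo(mirror$time, mirror$event, mirror$arm,
                  n_perm = 1000, seed = 1)
  expect_equal(mc0$statistic, 0)
  expect_gt(mc0$p_value, 0.9)
  expect_warning(maxcombo(d$time, d$event, d$arm, n_perm = 500,
                          seed = 1), "n_perm")
  # determinism
  mc2 <- maxcombo(d$time, d$event, d$arm, n_perm = 2000, seed = 3)
  expect_identical(mc$p_value, mc2$p_value)
})

test_that("discounted LYG table reproduces its own arithmetic", {
  set.seed(47)
  tmA <- round(rexp(150, 1 / 900))
  tmB <- round(rexp(150, 1 / 700))
  cvA <- km_fit(pmin(tmA, 2200), as.integer(tmA <= 2200))
  cvB <- km_fit(pmin(tmB, 2200), as.integer(tmB <= 2200))
  tab <- discounted_lyg_icer(cvA, cvB, delta_cost = -8.96,
                             taus_years = 1:5, discount = 0.035)
  # undiscounted first year: ICER = delta_cost / RMST difference
  expect_equal(tab$lyg_discounted[1], tab$difference[1])
  expect_equal(tab$icer[1], -8.96 / tab$difference[1])
  # discounted cumulative LYG by direct recomputation
  r_t <- vapply(1:5, function(y) rmst(cvA, y * 365.25)$rmst, numeric(1))
  r_c <- vapply(1:5, function(y) rmst(cvB, y * 365.25)$rmst, numeric(1))
  lyg <- cumsum((diff(c(0, r_t)) - diff(c(0, r_c))) / 1.035^(0:4))
  expect_equal(tab$lyg_discounted, lyg)
  # quadrature oracle on the synthetic generator's known hazards
  cfg <- trial_config(n_treatment = 3000, n_control = 3000, seed = 48)
  tr <- generate_trial(cfg)
  s <- tr$survival
  cvT <- km_fit(s$time_days[s$arm == "treatment"],
                s$event[s$arm == "treatment"])
  cvC <- km_fit(s$time_days[s$arm == "control"],
                s$event[s$arm == "control"])
  tab6 <- discounted_lyg_icer(cvT, cvC, delta_cost = -8.96,
                              taus_years = 1:6)
  sm <- cfg$survival_model
  delta_surv <- function(t) {
    trialcea:::pexp_surv(t, sm$hazard_early[["treatment"]],
                         sm$hazard_late[["treatment"]],
                         sm$changepoint_days) -
      trialcea:::pexp_surv(t, sm$hazard_early[["control"]],
                           sm$hazard_late[["control"]],
                           sm$changepoint_days)
  }
  oracle <- sum(vapply(1:6, function(y) {
    integrate(delta_surv, (y - 1) * 365.25, y * 365.25,
              rel.tol = 1e-9)$value / 365.25 / 1.035^(y - 1)
  }, numeric(1)))
  expect_lt(abs(tab6$lyg_discounted[6] - oracle), 0.05)
  # zero survival difference flags every ICER as undefined
  same <- discounted_lyg_icer(cvA, cvA, delta_cost = 100,
                              taus_years = 1:3)
  expect_true(all(is.na(same$icer)))
  expect_true(all(same$label == "undefined"))
})
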