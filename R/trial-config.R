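#' Default per-arm resource-use model for the synthetic trial
#'
#' Each resource category is drawn as a zero-inflated Gamma count:
#' with probability `p_any` the patient uses the category at all, and the
#' quantity used is then Gamma with the given `shape` and mean
#' `mean_given_any`. Category names match [default_unit_costs()], so the
#' configured mean euro cost per arm is `sum(p_any * mean_given_any *
#' unit_cost)`. The defaults are calibrated so that the per-category mean
#' costs reproduce the cost structure of a nutritional-counselling +/- oral
#' nutritional supplements (ONS) trial in head-and-neck cancer: ONS and its
#' delivery service dominate the treatment arm (~673 euro) while sparse,
#' large parenteral-nutrition and hospitalization episodes dominate the
#' control arm, giving near-equal totals (~988 vs ~996 euro) with a much
#' heavier right tail in control.
#'
#' @return A list with elements `treatment` and `control`; each is a named
#'   list of categories with fields `p_any`, `mean_given_any`, `shape`.
#' @export
default_cost_model <- function() {
  cat <- function(p_any, mean_given_any, shape) {
    list(p_any = p_any, mean_given_any = mean_given_any, shape = shape)
  }
  list(
    treatment = list(
      ons_treatment_bottle      = cat(1.00, 131.5, 8),
      ons_treatment_service_day = cat(1.00, 110.0, 8),
      ons_control_bottle        = cat(0.00, 0, 1),
      first_visit               = cat(0.15, 1.00, 50),
      followup_visit            = cat(0.15, 1.03, 5),
      en_service_day            = cat(0.20, 36.6, 2),
      en_compound_day           = cat(0.20, 36.6, 2),
      pn_day                    = cat(0.12, 20.2, 1),
      hospitalization_episode   = cat(0.17, 1.09, 3),
      mucositis_episode         = cat(0.28, 1.06, 10)
    ),
    control = list(
      ons_treatment_bottle      = cat(0.00, 0, 1),
      ons_treatment_service_day = cat(0.00, 0, 1),
      ons_control_bottle        = cat(0.10, 354.0, 2),
      first_visit               = cat(0.20, 1.00, 50),
      followup_visit            = cat(0.20, 1.21, 5),
      en_service_day            = cat(0.20, 41.9, 1.5),
      en_compound_day           = cat(0.20, 41.9, 1.5),
      pn_day                    = cat(0.15, 54.2, 0.8),
      hospitalization_episode   = cat(0.25, 3.16, 0.5),
      mucositis_episode         = cat(0.30, 1.18, 10)
    )
  )
}

default_utility_model <- function() {
  list(
    # per-visit mean utility at months 0, 2, 3, 5 (dip at end of RT,
    # partial recovery afterwards); calibrated so the all-visit trapezoid
    # gives mean QALYs near 0.291 (treatment) and 0.288 (control)
    mean_treatment = c(0.76, 0.66, 0.68, 0.73),
    mean_control   = c(0.753, 0.653, 0.673, 0.723),
    sd_intercept = 0.18,  # between-patient random intercept SD
    sd_residual  = 0.07   # within-patient residual SD
  )
}

default_dropout_model <- function() {
  # monthly hazards over the 5-month trial window; death is governed by
  # survival_model so that on-trial deaths and long-term survival agree
  list(
    treatment = c(hospitalization = 0.010, artificial_nutrition = 0.008,
                  lost = 0.005),
    control   = c(hospitalization = 0.014, artificial_nutrition = 0.012,
                  lost = 0.005)
  )
}

default_survival_model <- function() {
  # piecewise-exponential daily hazards with one changepoint: arms share
  # the first-year hazard, the treatment hazard is roughly halved
  # afterwards (late separation), giving medians near 1949 vs 1085 days
  list(
    hazard_early = c(treatment = 6.4e-4, control = 6.4e-4),
    hazard_late  = c(treatment = 2.9e-4, control = 6.4e-4),
    changepoint_days = 365
  )
}

#' Configuration of a synthetic two-arm nutrition-support trial
#'
#' Bundles every generative assumption of the synthetic trial: arm sizes,
#' the visit schedule, the longitudinal utility model (per-visit arm means
#' plus a patient-level random intercept and residual noise, clamped to
#' \[0, 1\]), dropout hazards, the resource-use/cost model, a
#' piecewise-exponential survival model with late separation, and the
#' accrual/censoring calendar. [true_values()] returns the analytic
#' estimands implied by a configuration; [generate_trial()] samples from it.
#'
#' @param n_treatment,n_control Arm sizes (defaults 78 and 81).
#' @param visit_months Utility assessment times in months since
#'   randomization; must be strictly increasing and start at 0.
#' @param end_of_rt_month Month at which radiotherapy ends (visit 2 by
#'   default); drives the before/after split of rule-based dropout
#'   utilities.
#' @param utility_model List with `mean_treatment`, `mean_control`
#'   (per-visit mean utilities), `sd_intercept`, `sd_residual`.
#' @param dropout_model Per-arm named monthly hazards for
#'   `hospitalization`, `artificial_nutrition` and `lost` over the trial
#'   window. Death is derived from `survival_model`.
#' @param cost_model Per-arm resource model, see [default_cost_model()].
#' @param survival_model List with per-arm `hazard_early`, `hazard_late`
#'   (per day) and `changepoint_days`.
#' @param accrual_start,accrual_end Calendar accrual window.
#' @param admin_censor_date Administrative censoring date for survival.
#' @param mcar_rate Probability that an otherwise observed utility value is
#'   missing completely at random (emulates sporadic single missing
#'   questionnaires).
#' @param seed Default integer seed used by [generate_trial()].
#' @return An object of class `trial_config`.
#' @seealso [generate_trial()], [true_values()]
#' @export
#' @examples
#' cfg <- trial_config(n_treatment = 20, n_control = 20)
#' cfg
trial_config <- function(n_treatment = 78,
                         n_control = 81,
                         visit_months = c(0, 2, 3, 5),
                         end_of_rt_month = 2,
                         utility_model = default_utility_model(),
                         dropout_model = default_dropout_model(),
                         cost_model = default_cost_model(),
                         survival_model = default_survival_model(),
                         accrual_start = as.Date("2012-07-01"),
                         accrual_end = as.Date("2016-04-30"),
                         admin_censor_date = as.Date("2020-01-02"),
                         mcar_rate = 0.015,
                         seed = 121003L) {
  cfg_stop <- function(field, msg) {
    stop(sprintf("invalid trial_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(n_treatment) || length(n_treatment) != 1L ||
      n_treatment < 1 || n_treatment != floor(n_treatment)) {
    cfg_stop("n_treatment", "must be a positive integer")
  }
  if (!is.numeric(n_control) || length(n_control) != 1L ||
      n_control < 1 || n_control != floor(n_control)) {
    cfg_stop("n_control", "must be a positive integer")
  }
  if (length(visit_months) < 2L || any(diff(visit_months) <= 0) ||
      visit_months[1] != 0) {
    cfg_stop("visit_months", "must be strictly increasing and start at 0")
  }
  um <- utility_model
  for (f in c("mean_treatment", "mean_control")) {
    if (length(um[[f]]) != length(visit_months)) {
      cfg_stop("utility_model", sprintf(
        "%s must have one mean per visit (%d)", f, length(visit_months)))
    }
    if (any(um[[f]] < 0 | um[[f]] > 1)) {
      cfg_stop("utility_model", paste(f, "must lie in [0, 1]"))
    }
  }
  if (um$sd_intercept < 0 || um$sd_residual < 0) {
    cfg_stop("utility_model", "SDs must be non-negative")
  }
  for (a in c("treatment", "control")) {
    dm <- dropout_model[[a]]
    if (is.null(dm) || !all(c("hospitalization", "artificial_nutrition",
                              "lost") %in% names(dm))) {
      cfg_stop("dropout_model", paste("missing hazards for arm", a))
    }
    if (any(dm < 0)) cfg_stop("dropout_model", "hazards must be >= 0")
    if (is.null(cost_model[[a]])) {
      cfg_stop("cost_model", paste("missing arm", a))
    }
    for (nm in names(cost_model[[a]])) {
      cc <- cost_model[[a]][[nm]]
      if (cc$p_any < 0 || cc$p_any > 1 || cc$mean_given_any < 0 ||
          cc$shape <= 0) {
        cfg_stop("cost_model", sprintf("bad parameters for '%s' (%s)", nm, a))
      }
    }
  }
  sm <- survival_model
  if (any(sm$hazard_early < 0) || any(sm$hazard_late < 0) ||
      sm$changepoint_days <= 0) {
    cfg_stop("survival_model", "hazards must be >= 0, changepoint > 0")
  }
  accrual_start <- as.Date(accrual_start)
  accrual_end <- as.Date(accrual_end)
  admin_censor_date <- as.Date(admin_censor_date)
  if (accrual_start > accrual_end) {
    cfg_stop("accrual_start", "accrual window is empty")
  }
  if (admin_censor_date <= accrual_end) {
    cfg_stop("admin_censor_date", "must fall after the accrual window")
  }
  if (mcar_rate < 0 || mcar_rate >= 1) cfg_stop("mcar_rate", "must be in [0, 1)")
  structure(list(
    n_treatment = as.integer(n_treatment),
    n_control = as.integer(n_control),
    visit_months = visit_months,
    end_of_rt_month = end_of_rt_month,
    utility_model = um,
    dropout_model = dropout_model,
    cost_model = cost_model,
    survival_model = sm,
    accrual_start = accrual_start,
    accrual_end = accrual_end,
    admin_censor_date = admin_censor_date,
    mcar_rate = mcar_rate,
    seed = as.integer(seed)
  ), class = "trial_config")
}

#' @export
print.trial_config <- function(x, ...) {
  cat("Synthetic trial configuration\n")
  cat(sprintf("  arms: treatment n=%d, control n=%d\n",
              x$n_treatment, x$n_control))
  cat(sprintf("  utility visits at months: %s\n",
              paste(x$visit_months, collapse = ", ")))
  cat(sprintf("  accrual %s .. %s, administrative censoring %s\n",
              format(x$accrual_start), format(x$accrual_end),
              format(x$admin_censor_date)))
  cat(sprintf("  survival hazards/day: early %s, late %s (changepoint %d d)\n",
              paste(signif(x$survival_model$hazard_early, 3), collapse = "/"),
              paste(signif(x$survival_model$hazard_late, 3), collapse = "/"),
              x$survival_model$changepoint_days))
  invisible(x)
}
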