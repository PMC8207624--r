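# Restricted mean of a piecewise-exponential survival time (in the same
# time unit as the hazards), hazard h1 up to the changepoint, h2 after.
pexp_rmst <- function(h1, h2, changepoint, tau) {
  t1 <- min(tau, changepoint)
  seg1 <- if (h1 > 0) (1 - exp(-h1 * t1)) / h1 else t1
  if (tau <= changepoint) return(seg1)
  s_cp <- exp(-h1 * changepoint)
  seg2 <- if (h2 > 0) {
    s_cp * (1 - exp(-h2 * (tau - changepoint))) / h2
  } else {
    s_cp * (tau - changepoint)
  }
  seg1 + seg2
}

pexp_surv <- function(t, h1, h2, changepoint) {
  ifelse(t <= changepoint, exp(-h1 * t),
         exp(-h1 * changepoint - h2 * (t - changepoint)))
}

#' Ground-truth estimands of a synthetic trial configuration
#'
#' Computes, analytically, the estimands a perfect analysis of infinitely
#' many patients generated from `config` would recover:
#' \itemize{
#'   \item per-arm mean utility at each visit, accounting for the clamping
#'     of the normal utility model to \[0, 1\] (censored-normal mean with
#'     total SD `sqrt(sd_intercept^2 + sd_residual^2)`);
#'   \item per-arm mean QALY over the trial horizon, the trapezoid of the
#'     mean utility curve divided by 12 (months per year), absent dropout;
#'   \item per-arm mean cost, summing `p_any * mean_given_any * unit_cost`
#'     over resource categories;
#'   \item per-arm restricted mean survival time (years) at horizons
#'     `tau_years`, the closed-form integral of the piecewise-exponential
#'     survival function;
#'   \item the incremental (treatment minus control) versions of each.
#' }
#'
#' @param config A [trial_config()].
#' @param unit_costs Unit-cost table used to price the configured resource
#'   use; defaults to [default_unit_costs()] with no inflation (amounts
#'   are treated as target-year euros).
#' @param tau_years Horizons (years) for the true RMST.
#' @return A list with components `treatment`, `control` (each holding
#'   `mean_utility`, `mean_qaly`, `mean_cost`, `rmst`) and `incremental`
#'   (`delta_cost`, `delta_qaly`, `delta_rmst`).
#' @export
#' @examples
#' tv <- true_values(trial_config())
#' tv$incremental$delta_qaly
true_values <- function(config, unit_costs = default_unit_costs(),
                        tau_years = 1:6) {
  stopifnot(inherits(config, "trial_config"))
  um <- config$utility_model
  sd_tot <- sqrt(um$sd_intercept^2 + um$sd_residual^2)
  visits <- config$visit_months
  uc <- stats::setNames(unit_costs$unit_cost, unit_costs$category)
  arm_truth <- function(arm) {
    mu <- if (arm == "treatment") um$mean_treatment else um$mean_control
    mean_u <- censored_normal_mean(mu, sd_tot)
    mean_qaly <- trapz(visits, mean_u) / 12
    cm <- config$cost_model[[arm]]
    missing_uc <- setdiff(names(cm), names(uc))
    if (length(missing_uc)) {
      stop("no unit cost for resource category: ",
           paste(missing_uc, collapse = ", "), call. = FALSE)
    }
    mean_cost <- sum(vapply(names(cm), function(nm) {
      cm[[nm]]$p_any * cm[[nm]]$mean_given_any * uc[[nm]]
    }, numeric(1)))
    sm <- config$survival_model
    rmst <- vapply(tau_years, function(tau) {
      pexp_rmst(sm$hazard_early[[arm]], sm$hazard_late[[arm]],
                sm$changepoint_days, tau * DAYS_PER_YEAR) / DAYS_PER_YEAR
    }, numeric(1))
    names(rmst) <- paste0("year_", tau_years)
    list(mean_utility = mean_u, mean_qaly = mean_qaly,
         mean_cost = mean_cost, rmst = rmst)
  }
  tr <- arm_truth("treatment")
  ct <- arm_truth("control")
  list(treatment = tr, control = ct,
       incremental = list(
         delta_cost = tr$mean_cost - ct$mean_cost,
         delta_qaly = tr$mean_qaly - ct$mean_qaly,
         delta_rmst = tr$rmst - ct$rmst
       ))
}
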