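#' Kaplan-Meier product-limit estimate
#'
#' Hand-rolled product-limit estimator exposing the internals the rest of
#' the survival analysis needs (at-risk counts, event counts and Greenwood
#' variance increments at every event time). Ties are handled in the
#' standard way: subjects censored at an event time are counted in the
#' risk set at that time (events before censorings).
#'
#' @param time Follow-up times (days), non-negative.
#' @param event Event indicators (1 = death, 0 = censored).
#' @return An object of class `km_curve`: `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv`, `var` (Greenwood), `n` and `max_time`
#'   (largest follow-up, where the curve stops being defined).
#' @export
#' @examples
#' km_fit(c(1, 2, 3), c(1, 1, 1))$surv  # 2/3, 1/3, 0
km_fit <- function(time, event) {
  if (length(time) == 0) stop("empty survival input", call. = FALSE)
  if (length(event) != length(time)) {
    stop("time and event must have equal length", call. = FALSE)
  }
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  event <- as.integer(event != 0)
  ut <- sort(unique(time[event == 1]))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw_inc <- ifelse(n_risk > n_event,
                   n_event / (n_risk * (n_risk - n_event)), 0)
  gw <- cumsum(gw_inc)
  structure(list(time = ut, n_risk = n_risk, n_event = n_event,
                 surv = surv, var = surv^2 * gw, greenwood_cum = gw,
                 n = length(time), max_time = max(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times, follow-up to %g\n",
              x$n, length(x$time), x$max_time))
  if (length(x$time)) {
    med <- km_quantile_time(x, 0.5)
    cat(sprintf("  median survival: %s\n",
                if (is.na(med)) "not reached" else format(med)))
  }
  invisible(x)
}

# right-continuous step evaluation S(t)
km_surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1L]
}

# first time the curve drops to or below probability p (NA if never)
km_quantile_time <- function(curve, p = 0.5) {
  hit <- which(curve$surv <= p)
  if (!length(hit)) NA_real_ else curve$time[hit[1]]
}

#' Median follow-up by the reverse Kaplan-Meier estimator
#'
#' Runs the product-limit estimator with the roles of death and censoring
#' swapped, so the "survival" curve estimates the follow-up distribution.
#' The median is the first time the curve reaches 0.5; its confidence
#' interval inverts pointwise log(-log) confidence bands
#' (Brookmeyer-Crowley style).
#'
#' @param time Follow-up times (days).
#' @param event Original event indicators (1 = death); censorings become
#'   the events of the reversed analysis.
#' @param conf Confidence level (default 0.95).
#' @return List with `median` (days), `ci`, `defined` (FALSE when the
#'   reverse curve never reaches 0.5, e.g. with no censored subject) and
#'   the reverse `curve`.
#' @export
reverse_km_median <- function(time, event, conf = 0.95) {
  event <- as.integer(event != 0)
  curve <- km_fit(time, 1L - event)
  med <- km_quantile_time(curve, 0.5)
  if (is.na(med)) {
    return(list(median = NA_real_, ci = c(NA_real_, NA_real_),
                defined = FALSE, curve = curve))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  s <- curve$surv
  se_cll <- ifelse(s > 0 & s < 1,
                   sqrt(curve$var) / (s * abs(log(s))), NA_real_)
  s_low <- ifelse(s == 0, 0, ifelse(s == 1, 1, s^exp(z * se_cll)))
  s_upp <- ifelse(s == 0, 0, ifelse(s == 1, 1, s^exp(-z * se_cll)))
  first_at_or_below <- function(vals) {
    hit <- which(!is.na(vals) & vals <= 0.5)
    if (!length(hit)) NA_real_ else curve$time[hit[1]]
  }
  list(median = med,
       ci = c(first_at_or_below(s_low), first_at_or_below(s_upp)),
       defined = TRUE, curve = curve)
}

#' Export a Kaplan-Meier curve as a step-function data frame
#'
#' @param curve A `km_curve`.
#' @return Data frame `time`, `n_risk`, `n_event`, `surv`, `std_err`.
#' @export
km_as_data_frame <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  data.frame(time = curve$time, n_risk = curve$n_risk,
             n_event = curve$n_event, surv = curve$surv,
             std_err = sqrt(curve$var))
}
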