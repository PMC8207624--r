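`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' All stochastic stages of the package draw their own seed from a single
#' master seed plus a stage label, so that (i) a whole run is reproducible
#' from one integer and (ii) the stream used by one stage does not depend on
#' how many random numbers an earlier stage consumed.
#'
#' @param seed Integer master seed.
#' @param stage Character label of the stage (e.g. `"bootstrap"`).
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' substream_seed(1, "bootstrap")
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * (seq_along(codes) + 7))
  as.integer((abs(as.numeric(seed)) * 48271 + 7919 * h) %% 2147483629)
}

# trapezoid rule on irregular grid
trapz <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# Mean of a normal variate censored (clamped) to [lower, upper].
# Vectorised over mu; sigma scalar.
censored_normal_mean <- function(mu, sigma, lower = 0, upper = 1) {
  if (sigma <= 0) return(pmin(pmax(mu, lower), upper))
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  lower * stats::pnorm(a) + upper * stats::pnorm(b, lower.tail = FALSE) +
    mu * (stats::pnorm(b) - stats::pnorm(a)) -
    sigma * (stats::dnorm(b) - stats::dnorm(a))
}

DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25
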