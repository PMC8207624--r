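PSA_FAMILIES <- c(normal = "norm", gamma = "gamma", weibull = "weibull",
                  lognormal = "lnorm")

n_params <- function(family) 2L  # all candidate families have 2 parameters

#' Fit candidate parametric families and select by AIC
#'
#' Maximum-likelihood fits of the candidate families (normal, Gamma,
#' Weibull, log-normal) to a sample of non-negative values, selecting the
#' family with the lowest AIC; ties are broken by fewer parameters and
#' then by family name. Samples containing exact zeros (e.g. patients with
#' no cost at all) are handled as a mixture of a point mass at zero and a
#' positive continuous part: the continuous family is fitted to the
#' positive values and the zero probability enters the likelihood (and
#' the AIC parameter count) as one extra parameter, applied uniformly to
#' every candidate so the AICs stay comparable.
#'
#' @param values Numeric sample, all `>= 0`, at least 10 values, not
#'   constant.
#' @param candidates Subset of `c("normal", "gamma", "weibull",
#'   "lognormal")`.
#' @return An object of class `dist_fit_set`: `best` (a `dist_fit`) and
#'   `fits` (all successful `dist_fit`s). Each `dist_fit` holds `family`,
#'   `parameters`, `p_zero`, `log_likelihood`, `aic`, `n`.
#' @seealso [sample_psa()]
#' @export
fit_best_distribution <- function(values,
                                  candidates = c("normal", "gamma",
                                                 "weibull", "lognormal")) {
  candidates <- match.arg(candidates, names(PSA_FAMILIES),
                          several.ok = TRUE)
  if (length(values) < 10) {
    stop("at least 10 values are required to fit a distribution",
         call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("values must be finite and non-negative", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("degenerate (constant) sample: no distribution can be fitted",
         call. = FALSE)
  }
  n <- length(values)
  n0 <- sum(values == 0)
  pos <- values[values > 0]
  p_zero <- n0 / n
  if (length(pos) < 10) {
    stop("fewer than 10 positive values after removing zeros",
         call. = FALSE)
  }
  mix_ll <- if (n0 > 0) n0 * log(p_zero) + (n - n0) * log(1 - p_zero) else 0
  extra_par <- as.integer(n0 > 0)
  # fit on mean-scaled data for numerical stability; a common scale
  # factor shifts every family's log-likelihood by -n*log(s), so the AIC
  # ranking is unchanged and parameters/log-likelihoods map back exactly
  s <- mean(pos)
  scaled <- pos / s
  unscale <- function(fam, est) {
    switch(fam,
           normal = c(mean = est[["mean"]] * s, sd = est[["sd"]] * s),
           gamma = c(shape = est[["shape"]], rate = est[["rate"]] / s),
           weibull = c(shape = est[["shape"]],
                       scale = est[["scale"]] * s),
           lognormal = c(meanlog = est[["meanlog"]] + log(s),
                         sdlog = est[["sdlog"]]))
  }
  fits <- list()
  for (fam in candidates) {
    fd <- tryCatch(
      suppressWarnings(fitdistrplus::fitdist(scaled, PSA_FAMILIES[[fam]])),
      error = function(e) NULL)
    if (is.null(fd) || anyNA(fd$estimate)) next
    ll <- fd$loglik - length(pos) * log(s) + mix_ll
    k <- n_params(fam) + extra_par
    fits[[fam]] <- structure(list(
      family = fam, parameters = unscale(fam, fd$estimate),
      p_zero = p_zero,
      log_likelihood = ll, aic = 2 * k - 2 * ll, n = n,
      n_parameters = k), class = "dist_fit")
  }
  if (!length(fits)) {
    stop("no candidate family could be fitted", call. = FALSE)
  }
  ord <- order(vapply(fits, `[[`, numeric(1), "aic"),
               vapply(fits, `[[`, integer(1), "n_parameters"),
               names(fits))
  structure(list(best = fits[[ord[1]]], fits = fits),
            class = "dist_fit_set")
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d%s): %s; logLik %.2f, AIC %.2f\n",
              x$family, x$n,
              if (x$p_zero > 0) sprintf(", P(zero) = %.3f", x$p_zero) else "",
              paste(sprintf("%s = %.4g", names(x$parameters),
                            x$parameters), collapse = ", "),
              x$log_likelihood, x$aic))
  invisible(x)
}

#' @export
print.dist_fit_set <- function(x, ...) {
  cat("Candidate distribution fits (AIC-ranked):\n")
  for (f in x$fits[order(vapply(x$fits, `[[`, numeric(1), "aic"))]) {
    cat("  ")
    print(f)
  }
  cat("selected:", x$best$family, "\n")
  invisible(x)
}

#' Complement transform for QALYs ahead of distribution fitting
#'
#' Trial QALY distributions over a short horizon are bounded above and
#' heavily left-skewed; fitting right-skewed positive families works on
#' the complement to the maximum attainable QALY (`max_q`, 5/12 for four
#' visits over 5 months). Exact-zero complements (patients at the
#' theoretical maximum) are shifted by half the smallest positive
#' complement so positive-support likelihoods remain finite.
#'
#' @param qalys QALY values in `[0, max_q]`.
#' @param max_q Maximum attainable QALY (default `5/12`).
#' @return Positive complements, with attribute `max_q`.
#' @seealso [back_transform_qaly()]
#' @export
transform_qaly_complement <- function(qalys, max_q = 5 / 12) {
  if (any(qalys < 0)) stop("QALYs must be non-negative", call. = FALSE)
  if (any(qalys > max_q + 1e-12)) {
    stop("QALY exceeds the maximum attainable value max_q = ",
         signif(max_q, 4), call. = FALSE)
  }
  comp <- pmax(max_q - qalys, 0)
  if (any(comp == 0)) {
    pos <- comp[comp > 0]
    if (!length(pos)) {
      stop("all QALYs equal max_q; complement distribution degenerate",
           call. = FALSE)
    }
    comp[comp == 0] <- min(pos) / 2
  }
  attr(comp, "max_q") <- max_q
  comp
}

#' Back-transform complement samples to the QALY scale
#'
#' @param samples Draws on the complement scale.
#' @param max_q Maximum attainable QALY.
#' @return `max_q - samples`, clamped to `[0, max_q]`.
#' @export
back_transform_qaly <- function(samples, max_q = 5 / 12) {
  pmin(pmax(max_q - samples, 0), max_q)
}

# random draws from a fitted (possibly zero-inflated) family
rdist_fit <- function(fit, n) {
  stopifnot(inherits(fit, "dist_fit"))
  rfun <- get(paste0("r", PSA_FAMILIES[[fit$family]]),
              envir = asNamespace("stats"))
  draws <- do.call(rfun, c(list(n), as.list(fit$parameters)))
  if (fit$p_zero > 0) {
    draws[stats::runif(n) < fit$p_zero] <- 0
  }
  draws
}

#' Sample a cost-effectiveness distribution from parametric fits
#'
#' Draws `n` independent samples per arm from the fitted cost
#' distributions and the fitted QALY-complement distributions (the latter
#' back-transformed and clamped to `[0, max_q]`), and assembles the
#' treatment-minus-control incremental pairs. Costs and effects are
#' sampled independently within arm. Normal-family cost draws are
#' truncated at zero.
#'
#' @param fits List with elements `treatment` and `control`, each a list
#'   with `cost` and `qaly` entries of class `dist_fit` (the `qaly` fits
#'   are on the complement scale).
#' @param n Number of draws (default 1000).
#' @param seed Integer seed.
#' @param max_q Maximum attainable QALY used in the complement transform.
#' @param point_estimate Optional original-sample `c(delta_cost,
#'   delta_effect)` carried through for reporting.
#' @return A [ce_distribution()] with `source = "psa"`.
#' @export
sample_psa <- function(fits, n = 1000, seed = 1, max_q = 5 / 12,
                       point_estimate = NULL) {
  for (a in c("treatment", "control")) {
    if (!inherits(fits[[a]]$cost, "dist_fit") ||
        !inherits(fits[[a]]$qaly, "dist_fit")) {
      stop("fits$", a, " must contain dist_fit entries 'cost' and 'qaly'",
           call. = FALSE)
    }
  }
  set.seed(substream_seed(seed, "psa-sampling"))
  draw_arm <- function(a) {
    cost <- pmax(rdist_fit(fits[[a]]$cost, n), 0)
    qaly <- back_transform_qaly(rdist_fit(fits[[a]]$qaly, n), max_q)
    list(cost = cost, qaly = qaly)
  }
  tr <- draw_arm("treatment")
  ct <- draw_arm("control")
  ce_distribution(tr$cost - ct$cost, tr$qaly - ct$qaly, source = "psa",
                  point_estimate = point_estimate, seed = seed)
}

#' Tabulate fitted distributions for reporting
#'
#' @param fits Nested list of `dist_fit_set` or `dist_fit` objects, e.g.
#'   `list(treatment = list(cost = ..., qaly = ...), ...)`.
#' @return Data frame with `arm`, `quantity`, `family`, `parameters`
#'   (formatted), `p_zero`, `aic`.
#' @export
psa_fit_table <- function(fits) {
  rows <- list()
  for (a in names(fits)) {
    for (q in names(fits[[a]])) {
      f <- fits[[a]][[q]]
      if (inherits(f, "dist_fit_set")) f <- f$best
      rows[[length(rows) + 1L]] <- data.frame(
        arm = a, quantity = q, family = f$family,
        parameters = paste(sprintf("%s=%.5g", names(f$parameters),
                                   f$parameters), collapse = "; "),
        p_zero = f$p_zero, aic = f$aic, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
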