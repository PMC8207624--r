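#' Construct a cost-effectiveness distribution
#'
#' The common substrate of all decision-analytic outputs: a cloud of
#' incremental cost / incremental effect pairs, from the nonparametric
#' bootstrap ([bootstrap_pairs()]) or the parametric sensitivity analysis
#' ([sample_psa()]).
#'
#' @param delta_cost,delta_effect Equal-length numeric vectors of
#'   incremental costs (euro) and effects (QALYs or life years).
#' @param source `"bootstrap"` or `"psa"`.
#' @param point_estimate Length-2 numeric `c(delta_cost, delta_effect)`
#'   from the original sample (optional).
#' @param seed Seed used to generate the pairs, for provenance.
#' @return An object of class `ce_distribution`.
#' @export
ce_distribution <- function(delta_cost, delta_effect,
                            source = c("bootstrap", "psa"),
                            point_estimate = NULL, seed = NA_integer_) {
  source <- match.arg(source)
  if (length(delta_cost) < 1L || length(delta_cost) != length(delta_effect)) {
    stop("delta_cost and delta_effect must be non-empty and equal length",
         call. = FALSE)
  }
  if (!all(is.finite(delta_cost)) || !all(is.finite(delta_effect))) {
    stop("incremental pairs must be finite", call. = FALSE)
  }
  structure(list(delta_cost = delta_cost, delta_effect = delta_effect,
                 B = length(delta_cost), source = source,
                 point_estimate = point_estimate, seed = seed),
            class = "ce_distribution")
}

#' @export
print.ce_distribution <- function(x, ...) {
  cat(sprintf("Cost-effectiveness distribution (%s, B = %d)\n",
              x$source, x$B))
  cat(sprintf("  mean delta cost %.2f euro, mean delta effect %.5f\n",
              mean(x$delta_cost), mean(x$delta_effect)))
  if (!is.null(x$point_estimate)) {
    cat(sprintf("  point estimate: delta cost %.2f, delta effect %.5f\n",
                x$point_estimate[1], x$point_estimate[2]))
  }
  invisible(x)
}

#' Stratified nonparametric bootstrap of incremental cost and effect
#'
#' Resamples patients with replacement within each arm, recomputes arm
#' means of cost and effect, and stores the treatment-minus-control
#' differences; the arm sizes of every replicate equal the observed ones.
#'
#' @param data Data frame with columns `id`, `arm` (`"treatment"` /
#'   `"control"`), `qaly` and `cost`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A [ce_distribution()] with `source = "bootstrap"` and the
#'   original-sample point estimate attached.
#' @export
bootstrap_pairs <- function(data, B = 1000, seed = 1) {
  absent <- setdiff(c("arm", "qaly", "cost"), names(data))
  if (length(absent)) {
    stop("data is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  t_arm <- data[data$arm == "treatment", ]
  c_arm <- data[data$arm == "control", ]
  if (nrow(t_arm) == 0 || nrow(c_arm) == 0) {
    stop("both arms must be non-empty", call. = FALSE)
  }
  stopifnot(B >= 1)
  point <- c(delta_cost = mean(t_arm$cost) - mean(c_arm$cost),
             delta_effect = mean(t_arm$qaly) - mean(c_arm$qaly))
  set.seed(substream_seed(seed, "bootstrap-pairs"))
  arm_means <- function(d) {
    n <- nrow(d)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    list(cost = rowMeans(matrix(d$cost[idx], nrow = B)),
         qaly = rowMeans(matrix(d$qaly[idx], nrow = B)))
  }
  mt <- arm_means(t_arm)
  mc <- arm_means(c_arm)
  ce_distribution(mt$cost - mc$cost, mt$qaly - mc$qaly,
                  source = "bootstrap", point_estimate = point,
                  seed = seed)
}

#' Incremental cost-effectiveness ratio with dominance labelling
#'
#' @param delta_cost Incremental cost (euro).
#' @param delta_effect Incremental effect (QALYs or life years).
#' @return List with `ratio` (`delta_cost / delta_effect`, `NA` when the
#'   effect difference is zero), `defined`, and a cost-effectiveness-plane
#'   `label`: `"dominant"` (cheaper, more effective), `"dominated"`
#'   (costlier, less effective), `"more costly, more effective"`,
#'   `"less costly, less effective"`, or `"undefined"`.
#' @export
#' @examples
#' icer(-8.96, -0.022)  # 407.27 euro per unit of effect forgone
icer <- function(delta_cost, delta_effect) {
  if (!is.finite(delta_cost) || !is.finite(delta_effect)) {
    stop("delta_cost and delta_effect must be finite", call. = FALSE)
  }
  if (delta_effect == 0) {
    return(list(ratio = NA_real_, defined = FALSE, label = "undefined",
                delta_cost = delta_cost, delta_effect = delta_effect))
  }
  label <- if (delta_cost <= 0 && delta_effect > 0) {
    "dominant"
  } else if (delta_cost >= 0 && delta_effect < 0) {
    "dominated"
  } else if (delta_effect > 0) {
    "more costly, more effective"
  } else {
    "less costly, less effective"
  }
  list(ratio = delta_cost / delta_effect, defined = TRUE, label = label,
       delta_cost = delta_cost, delta_effect = delta_effect)
}

check_wtp_grid <- function(wtp) {
  if (any(wtp < 0) || any(diff(wtp) <= 0)) {
    stop("willingness-to-pay grid must be non-negative and strictly ",
         "increasing", call. = FALSE)
  }
  wtp
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold `k`, the fraction of pairs with
#' positive incremental net benefit `k * delta_effect - delta_cost`. At
#' `k = 0` this is the probability that the intervention is cost saving.
#'
#' @param dist A [ce_distribution()].
#' @param wtp Threshold grid (euro per QALY), default 0 to 50,000 in
#'   steps of 100.
#' @return Data frame with `wtp` and `probability`.
#' @export
ceac <- function(dist, wtp = seq(0, 50000, by = 100)) {
  stopifnot(inherits(dist, "ce_distribution"))
  check_wtp_grid(wtp)
  prob <- vapply(wtp, function(k) {
    mean(k * dist$delta_effect - dist$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp, probability = prob)
}

#' Expected incremental benefit at a willingness-to-pay threshold
#'
#' `EIB(k) = k * mean(delta_effect) - mean(delta_cost)`, with a percentile
#' confidence interval from the per-pair net benefits.
#'
#' @param dist A [ce_distribution()].
#' @param k Threshold (euro per QALY).
#' @param conf Confidence level for the percentile interval.
#' @return List with `eib`, `ci` (percentile bounds) and `k`.
#' @export
eib <- function(dist, k = 30000, conf = 0.95) {
  stopifnot(inherits(dist, "ce_distribution"))
  nb <- k * dist$delta_effect - dist$delta_cost
  a <- (1 - conf) / 2
  list(eib = mean(nb),
       ci = unname(stats::quantile(nb, c(a, 1 - a))), k = k)
}

#' Per-patient expected value of perfect information
#'
#' The expected opportunity loss of deciding under current uncertainty:
#' with per-pair incremental net benefit `INB_i = k * delta_effect_i -
#' delta_cost_i`, `EVPI = mean(pmax(0, INB)) - max(0, mean(INB))`. For two
#' strategies this equals the expected gain of always picking the ex-post
#' best arm; it is zero exactly when every pair favours the same decision.
#'
#' @param dist A [ce_distribution()].
#' @param k Threshold (euro per QALY).
#' @return EVPI in euro per patient (always non-negative).
#' @export
evpi <- function(dist, k = 30000) {
  stopifnot(inherits(dist, "ce_distribution"))
  inb <- k * dist$delta_effect - dist$delta_cost
  mean(pmax(0, inb)) - max(0, mean(inb))
}

#' Population expected value of perfect information
#'
#' Scales a per-patient EVPI by the yearly number of patients affected by
#' the information over a decision horizon, discounting each year:
#' `sum over t = 1..horizon of incidence * evpi_pp / (1 + discount)^t`
#' (every year discounted; there is no undiscounted year 0).
#'
#' @param evpi_pp Per-patient EVPI (euro).
#' @param incidence Patients affected per year.
#' @param horizon Years the information remains useful.
#' @param discount Annual discount rate (default 0.035).
#' @return Population EVPI in euro.
#' @export
#' @examples
#' population_evpi(184.39, 5580, 10, 0.035) / 1e6  # about 8.6 million
population_evpi <- function(evpi_pp, incidence, horizon,
                            discount = 0.035) {
  if (evpi_pp < 0 || incidence < 0 || horizon < 0 || discount < 0) {
    stop("all inputs must be non-negative", call. = FALSE)
  }
  if (horizon == 0) return(0)
  sum(incidence * evpi_pp / (1 + discount)^(seq_len(horizon)))
}

#' CEAC, EIB and EVPI over a threshold grid
#'
#' @param dist A [ce_distribution()].
#' @param wtp Threshold grid.
#' @return Data frame with `wtp`, `ceac`, `eib`, `eib_lower`, `eib_upper`,
#'   `evpi`.
#' @export
value_of_information_table <- function(dist, wtp = seq(0, 50000, by = 100)) {
  stopifnot(inherits(dist, "ce_distribution"))
  check_wtp_grid(wtp)
  rows <- lapply(wtp, function(k) {
    nb <- k * dist$delta_effect - dist$delta_cost
    ci <- stats::quantile(nb, c(0.025, 0.975))
    data.frame(wtp = k, ceac = mean(nb > 0), eib = mean(nb),
               eib_lower = unname(ci[1]), eib_upper = unname(ci[2]),
               evpi = mean(pmax(0, nb)) - max(0, mean(nb)))
  })
  do.call(rbind, rows)
}
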