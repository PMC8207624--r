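#' Specification of a quality-of-life-to-utility mapping
#'
#' Describes a published mapping from EORTC QLQ-C30 scale scores to EQ-5D
#' utilities as a linear predictor plus link. The package ships no
#' coefficients of its own (such mappings are estimated on external
#' datasets); users supply the intercept and named scale weights.
#'
#' @param intercept Numeric intercept of the linear predictor.
#' @param coefficients Named numeric vector of weights; names are the
#'   QLQ-C30 scale names (e.g. `global_health`, `physical_functioning`).
#' @param link `"identity"` (linear predictor clamped to \[0, 1\]) or
#'   `"logit-inverse"` (inverse-logit of the linear predictor).
#' @return An object of class `mapping_spec`.
#' @seealso [map_scores_to_utility()]
#' @export
mapping_spec <- function(intercept, coefficients,
                         link = c("identity", "logit-inverse")) {
  link <- match.arg(link)
  if (length(coefficients) && is.null(names(coefficients))) {
    stop("coefficients must be named after the predictor scales",
         call. = FALSE)
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 link = link),
            class = "mapping_spec")
}

#' Map quality-of-life scale scores to a utility weight
#'
#' Applies a [mapping_spec()] to one set (named vector) or several sets
#' (data frame) of scale scores: utility = link(intercept + sum of
#' coefficient * score), clamped to \[0, 1\].
#'
#' @param scores Named numeric vector, or data frame with one column per
#'   predictor scale.
#' @param spec A [mapping_spec()].
#' @return Numeric utility value(s) in \[0, 1\].
#' @export
#' @examples
#' spec <- mapping_spec(0, c(global_health = 0.01))
#' map_scores_to_utility(c(global_health = 50), spec)
map_scores_to_utility <- function(scores, spec) {
  stopifnot(inherits(spec, "mapping_spec"))
  need <- names(spec$coefficients)
  if (is.data.frame(scores)) {
    absent <- setdiff(need, names(scores))
    if (length(absent)) {
      stop("missing predictor scale(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    lp <- spec$intercept +
      as.matrix(scores[need]) %*% spec$coefficients[need]
    lp <- drop(lp)
  } else {
    absent <- setdiff(need, names(scores))
    if (length(absent)) {
      stop("missing predictor scale(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    lp <- spec$intercept + sum(spec$coefficients[need] * scores[need])
  }
  u <- if (spec$link == "logit-inverse") stats::plogis(lp) else lp
  unname(pmin(pmax(u, 0), 1))
}

#' Fill in rule-based utilities for informative dropout
#'
#' Patients who drop out for hospitalization or artificial nutrition get
#' literature-based utilities at their unobserved visits: `utility_before`
#' at visits up to the end of radiotherapy and `utility_after` at later
#' visits. Patients who die get utility 0 at every visit from the death
#' time to the end of the horizon (the standard QALY convention for
#' decedents). Observed values are never overwritten, other dropout
#' reasons (loss to follow-up, withdrawal) are left missing for
#' [impute_chained()], and dropouts after the last visit are a no-op.
#'
#' @param utilities Long-format utility data frame with columns `id`,
#'   `visit_month`, `utility`, `dropout_reason`, `dropout_month`.
#' @param end_of_rt_month End of radiotherapy, in months (default 2).
#' @param utility_before,utility_after Utilities assigned before/after the
#'   end of radiotherapy (defaults 0.35 and 0.30); these are parameters,
#'   not constants, so other literature values can be substituted.
#' @return The data frame with rule-based utilities filled in.
#' @export
assign_dropout_utility <- function(utilities, end_of_rt_month = 2,
                                   utility_before = 0.35,
                                   utility_after = 0.30) {
  need <- c("id", "visit_month", "utility", "dropout_reason",
            "dropout_month")
  absent <- setdiff(need, names(utilities))
  if (length(absent)) {
    stop("utilities is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  u <- utilities
  care <- u$dropout_reason %in% c("hospitalization", "artificial_nutrition") &
    is.na(u$utility) & !is.na(u$dropout_month) &
    u$visit_month >= u$dropout_month
  u$utility[care] <- ifelse(u$visit_month[care] <= end_of_rt_month,
                            utility_before, utility_after)
  dead <- u$dropout_reason == "death" & is.na(u$utility) &
    !is.na(u$dropout_month) & u$visit_month >= u$dropout_month
  u$utility[dead] <- 0
  u
}

#' QALY as the interpolated area under a utility trajectory
#'
#' Trapezoidal area of utility versus time in months, divided by 12 to
#' yield years. Over a 5-month horizon with utility 1 throughout the
#' maximum attainable value is 5/12 (about 0.417).
#'
#' @param times Visit times in months, strictly increasing.
#' @param utilities Utility values in \[0, 1\], no missing values.
#' @return QALY in years.
#' @export
#' @examples
#' qaly_auc(c(0, 2, 3, 5), c(1, 1, 1, 1))  # 5/12
qaly_auc <- function(times, utilities) {
  if (length(times) != length(utilities) || length(times) < 2L) {
    stop("times and utilities must have equal length >= 2", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (anyNA(utilities)) {
    stop("utility trajectory contains missing values; apply ",
         "assign_dropout_utility() and impute_chained() first",
         call. = FALSE)
  }
  if (any(utilities < 0 | utilities > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  trapz(times, utilities) / 12
}

#' Per-patient QALYs from a completed long-format utility table
#'
#' @param utilities Long-format data frame with columns `id`, `arm`,
#'   `visit_month`, `utility` (complete).
#' @return Data frame with one row per patient: `id`, `arm`, `qaly`.
#' @export
qaly_by_patient <- function(utilities) {
  split_idx <- split(seq_len(nrow(utilities)), utilities$id)
  rows <- lapply(split_idx, function(ix) {
    ix <- ix[order(utilities$visit_month[ix])]
    data.frame(id = utilities$id[ix[1]], arm = utilities$arm[ix[1]],
               qaly = qaly_auc(utilities$visit_month[ix],
                               utilities$utility[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
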