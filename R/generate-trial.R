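#' Generate a complete synthetic trial
#'
#' Samples one realisation of a two-arm trial from a [trial_config()]:
#' baseline covariates, staggered accrual dates, piecewise-exponential
#' survival with administrative censoring, competing on-trial dropout
#' (death from the survival model; hospitalization, artificial nutrition
#' and loss to follow-up from exponential hazards), longitudinal utilities
#' (arm-specific visit means + patient random intercept + residual noise,
#' clamped to \[0, 1\], set missing from dropout onwards and thinned by an
#' MCAR rate), and zero-inflated Gamma resource use per cost category.
#'
#' Each generation stage uses its own sub-seed derived with
#' [substream_seed()], so the values produced by one stage do not depend on
#' how many draws another stage consumed.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `trial_data`: a list with data frames
#'   `utilities` (long format: one row per patient-visit, with dropout
#'   annotations and baseline covariates), `resources` (wide, one column
#'   per resource category), `survival` (`id`, `arm`, `time_days`, `event`,
#'   `accrual_date`), plus the `config` and `seed` used.
#' @seealso [true_values()], [write_trial_csv()]
#' @export
#' @examples
#' trial <- generate_trial(trial_config(n_treatment = 10, n_control = 10))
#' head(trial$survival)
generate_trial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "trial_config"))
  n_t <- config$n_treatment
  n_c <- config$n_control
  n <- n_t + n_c
  arm <- rep(c("treatment", "control"), c(n_t, n_c))
  id <- sprintf("P%04d", seq_len(n))
  visits <- config$visit_months
  last_visit <- visits[length(visits)]

  ## baseline covariates (imputation predictors; always complete)
  set.seed(substream_seed(seed, "covariates"))
  age <- round(pmin(pmax(stats::rnorm(n, 64, 10), 18), 90))
  gender <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.75, 0.25))
  malnourished <- stats::runif(n) < 0.30
  tumor_site <- sample(c("oral_cavity", "oropharynx", "hypopharynx",
                         "larynx", "nasopharynx"),
                       n, replace = TRUE, prob = c(.2, .3, .1, .3, .1))
  tumor_stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                        prob = c(.1, .2, .3, .4))
  handgrip <- round(pmax(stats::rnorm(n, 30, 8), 5), 1)
  phase_angle <- round(pmax(stats::rnorm(n, 5, 0.8), 2), 2)
  accrual_span <- as.numeric(config$accrual_end - config$accrual_start)
  accrual_date <- config$accrual_start +
    floor(stats::runif(n) * (accrual_span + 1))

  ## survival: piecewise-exponential death times, administrative censoring
  set.seed(substream_seed(seed, "survival"))
  sm <- config$survival_model
  h1 <- unname(sm$hazard_early[arm])
  h2 <- unname(sm$hazard_late[arm])
  cp <- sm$changepoint_days
  u <- stats::runif(n)
  s_cp <- exp(-h1 * cp)
  death_days <- ifelse(u >= s_cp, -log(u) / h1,
                       cp + (-log(u) - h1 * cp) / h2)
  censor_days <- as.numeric(config$admin_censor_date - accrual_date)
  event <- death_days <= censor_days
  time_days <- round(pmin(death_days, censor_days))

  ## on-trial dropout: earliest of death / hosp / AN / lost within window
  set.seed(substream_seed(seed, "dropout"))
  rexp_haz <- function(rate) {
    out <- rep(Inf, n)
    pos <- rate > 0
    if (any(pos)) out[pos] <- stats::rexp(sum(pos), rate[pos])
    out
  }
  haz_of <- function(cause) {
    vapply(arm, function(a) config$dropout_model[[a]][[cause]], numeric(1))
  }
  t_hosp <- rexp_haz(haz_of("hospitalization"))
  t_an <- rexp_haz(haz_of("artificial_nutrition"))
  t_lost <- rexp_haz(haz_of("lost"))
  death_month <- ifelse(event, time_days / DAYS_PER_MONTH, Inf)
  cand <- cbind(death = death_month, hospitalization = t_hosp,
                artificial_nutrition = t_an, lost = t_lost)
  first <- apply(cand, 1L, which.min)
  t_first <- cand[cbind(seq_len(n), first)]
  dropped <- is.finite(t_first) & t_first <= last_visit
  dropout_reason <- ifelse(dropped, colnames(cand)[first], "none")
  dropout_month <- ifelse(dropped, round(t_first, 3), NA_real_)

  ## longitudinal utilities
  set.seed(substream_seed(seed, "utilities"))
  um <- config$utility_model
  mu <- rbind(treatment = um$mean_treatment, control = um$mean_control)
  b <- stats::rnorm(n, 0, um$sd_intercept)
  util <- matrix(NA_real_, n, length(visits))
  for (v in seq_along(visits)) {
    raw <- mu[arm, v] + b + stats::rnorm(n, 0, um$sd_residual)
    util[, v] <- pmin(pmax(raw, 0), 1)
  }
  # missing from dropout onwards
  for (v in seq_along(visits)) {
    gone <- dropped & visits[v] >= dropout_month
    util[gone, v] <- NA_real_
  }
  # sporadic MCAR missingness on the remaining observed values
  if (config$mcar_rate > 0) {
    mcar <- matrix(stats::runif(n * length(visits)) < config$mcar_rate,
                   n, length(visits))
    util[mcar & !is.na(util)] <- NA_real_
  }

  ## resource use: zero-inflated Gamma per category
  set.seed(substream_seed(seed, "resources"))
  categories <- names(config$cost_model$treatment)
  res <- matrix(0, n, length(categories),
                dimnames = list(NULL, categories))
  for (j in seq_along(categories)) {
    p_any <- vapply(arm, function(a)
      config$cost_model[[a]][[categories[j]]]$p_any, numeric(1))
    mn <- vapply(arm, function(a)
      config$cost_model[[a]][[categories[j]]]$mean_given_any, numeric(1))
    sh <- vapply(arm, function(a)
      config$cost_model[[a]][[categories[j]]]$shape, numeric(1))
    any_use <- stats::runif(n) < p_any
    draw <- any_use & mn > 0
    if (any(draw)) {
      res[draw, j] <- stats::rgamma(sum(draw), shape = sh[draw],
                                    rate = sh[draw] / mn[draw])
    }
  }

  utilities <- data.frame(
    id = rep(id, each = length(visits)),
    arm = rep(arm, each = length(visits)),
    visit_month = rep(visits, n),
    utility = as.vector(t(util)),
    dropout_reason = rep(dropout_reason, each = length(visits)),
    dropout_month = rep(dropout_month, each = length(visits)),
    age = rep(age, each = length(visits)),
    gender = rep(gender, each = length(visits)),
    malnourished = rep(malnourished, each = length(visits)),
    tumor_site = rep(tumor_site, each = length(visits)),
    tumor_stage = rep(tumor_stage, each = length(visits)),
    handgrip = rep(handgrip, each = length(visits)),
    phase_angle = rep(phase_angle, each = length(visits)),
    stringsAsFactors = FALSE
  )
  resources <- data.frame(id = id, arm = arm, res,
                          stringsAsFactors = FALSE)
  survival <- data.frame(id = id, arm = arm, time_days = time_days,
                         event = as.integer(event),
                         accrual_date = accrual_date,
                         stringsAsFactors = FALSE)
  structure(list(utilities = utilities, resources = resources,
                 survival = survival, config = config, seed = seed),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  n <- nrow(x$survival)
  cat(sprintf("Synthetic trial data: %d patients (%d treatment / %d control)\n",
              n, sum(x$survival$arm == "treatment"),
              sum(x$survival$arm == "control")))
  cat(sprintf("  utility rows: %d (%.1f%% missing before rules/imputation)\n",
              nrow(x$utilities),
              100 * mean(is.na(x$utilities$utility))))
  cat(sprintf("  on-trial deaths: %d treatment, %d control\n",
              sum(x$utilities$dropout_reason == "death" &
                    x$utilities$arm == "treatment" &
                    x$utilities$visit_month == 0),
              sum(x$utilities$dropout_reason == "death" &
                    x$utilities$arm == "control" &
                    x$utilities$visit_month == 0)))
  invisible(x)
}

#' Write a synthetic trial to CSV (plus ground truth JSON)
#'
#' Writes `utilities.csv` (long format), `resources.csv`, `survival.csv`
#' and `truth.json` (the [true_values()] of the generating configuration)
#' into `dir`, using the same dialect the pipeline reads back (UTF-8,
#' header row, ISO dates).
#'
#' @param trial A `trial_data` object from [generate_trial()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_trial_csv <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("utilities.csv", "resources.csv",
                            "survival.csv", "truth.json"))
  utils::write.csv(trial$utilities, paths[1], row.names = FALSE)
  utils::write.csv(trial$resources, paths[2], row.names = FALSE)
  utils::write.csv(trial$survival, paths[3], row.names = FALSE)
  jsonlite::write_json(true_values(trial$config), paths[4],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read trial CSV inputs written by [write_trial_csv()]
#'
#' @param dir Directory containing `utilities.csv`, `resources.csv` and
#'   `survival.csv`.
#' @return A list with data frames `utilities`, `resources`, `survival`.
#' @export
read_trial_csv <- function(dir) {
  need <- file.path(dir, c("utilities.csv", "resources.csv", "survival.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utilities <- utils::read.csv(need[1], stringsAsFactors = FALSE)
  resources <- utils::read.csv(need[2], stringsAsFactors = FALSE)
  survival <- utils::read.csv(need[3], stringsAsFactors = FALSE)
  survival$accrual_date <- as.Date(survival$accrual_date)
  structure(list(utilities = utilities, resources = resources,
                 survival = survival, config = NULL, seed = NA_integer_),
            class = "trial_data")
}
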