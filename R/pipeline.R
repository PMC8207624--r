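#' Configuration of an end-to-end cost-effectiveness pipeline run
#'
#' @param trial A [trial_config()] for simulation mode, or `NULL` when
#'   reading CSV inputs.
#' @param input_dir Directory with `utilities.csv`, `resources.csv`,
#'   `survival.csv` (see [read_trial_csv()]); exactly one of `trial` /
#'   `input_dir` must be given.
#' @param unit_costs Unit-cost table ([default_unit_costs()]).
#' @param index Optional inflation index (named numeric, year -> index).
#' @param target_year Price year of the analysis (default 2017).
#' @param wtp_grid Willingness-to-pay grid (euro/QALY).
#' @param wtp_reference Reference threshold for EIB/EVPI (default 30000).
#' @param B Bootstrap replicates (default 1000).
#' @param psa_n Probabilistic-sensitivity-analysis draws (default 1000).
#' @param m Number of multiple imputations (default 20).
#' @param n_perm Max-combo permutations (default 10000).
#' @param discount Annual discount rate for life years and the population
#'   EVPI (default 0.035).
#' @param incidence Patients affected by the information per year; the
#'   default takes 60% of a national yearly incidence of 9300 head-and-
#'   neck cancer diagnoses as radiotherapy candidates.
#' @param horizon_years Lifetime of the information (default 10).
#' @param end_of_rt_month,dropout_utility Parameters of
#'   [assign_dropout_utility()].
#' @param taus_years Survival horizons for the life-years analysis.
#' @param seed Master seed; every stochastic stage derives its own
#'   substream from it.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param verbose Log stage progress (default TRUE).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(trial = NULL, input_dir = NULL,
                            unit_costs = default_unit_costs(),
                            index = NULL, target_year = 2017,
                            wtp_grid = seq(0, 50000, by = 100),
                            wtp_reference = 30000,
                            B = 1000, psa_n = 1000, m = 20,
                            n_perm = 10000, discount = 0.035,
                            incidence = round(0.60 * 9300),
                            horizon_years = 10,
                            end_of_rt_month = 2,
                            dropout_utility = c(before = 0.35,
                                                after = 0.30),
                            taus_years = 1:6, seed = 1,
                            out_dir = NULL, verbose = TRUE) {
  if (is.null(trial) == is.null(input_dir)) {
    stop("exactly one of 'trial' (simulation) or 'input_dir' (CSV inputs) ",
         "must be supplied", call. = FALSE)
  }
  if (!is.null(trial)) stopifnot(inherits(trial, "trial_config"))
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  counts <- c(B = B, psa_n = psa_n, m = m, n_perm = n_perm,
              horizon_years = horizon_years)
  if (any(counts < 1)) {
    stop("counts must be positive: ",
         paste(names(counts)[counts < 1], collapse = ", "), call. = FALSE)
  }
  check_wtp_grid(wtp_grid)
  structure(list(trial = trial, input_dir = input_dir,
                 unit_costs = unit_costs, index = index,
                 target_year = target_year, wtp_grid = wtp_grid,
                 wtp_reference = wtp_reference, B = B, psa_n = psa_n,
                 m = m, n_perm = n_perm, discount = discount,
                 incidence = incidence, horizon_years = horizon_years,
                 end_of_rt_month = end_of_rt_month,
                 dropout_utility = dropout_utility,
                 taus_years = taus_years, seed = as.integer(seed),
                 out_dir = out_dir, verbose = verbose),
            class = "pipeline_config")
}

config_hash <- function(config) {
  stable <- config[setdiff(names(config), c("out_dir", "verbose"))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(
    jsonlite::serializeJSON(stable, digits = 15), tmp, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full cost-effectiveness pipeline
#'
#' Orchestrates every analysis stage in order: data acquisition
#' (simulation from a [trial_config()] or CSV inputs), rule-based dropout
#' utilities, chained multiple imputation and per-patient QALYs, costing
#' and the arm-wise cost table, the stratified bootstrap with cost-
#' effectiveness plane / CEAC / EIB / EVPI / population EVPI, the
#' parametric sensitivity analysis (AIC-selected distributions, sampled
#' into the same decision-analytic outputs), and the long-term survival
#' analysis (Kaplan-Meier, reverse-KM follow-up, weighted log-rank and
#' max-combo tests, discounted cost-per-life-year table). A rerun with an
#' identical configuration is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `cea_pipeline`: a list with elements
#'   `data`, `qaly`, `lmm`, `costs`, `cost_table`, `ce_data`,
#'   `bootstrap` (distribution, icer, ceac, voi, eib, evpi,
#'   population_evpi), `psa` (fits, fit table, distribution, icer, ceac,
#'   eib, evpi), `survival` (curves, median follow-up, tests, lyg_table)
#'   and `manifest`. When `config$out_dir` is set all tables are also
#'   written as CSV/JSON.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(trial = trial_config(n_treatment = 30,
#'                                             n_control = 30),
#'                        B = 200, psa_n = 200, m = 3, n_perm = 1000,
#'                        seed = 7, verbose = FALSE)
#' res <- run_pipeline(cfg)
#' res$bootstrap$icer$ratio
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(stage, ...) {
    if (config$verbose) {
      message(sprintf("[%s +%.1fs] %s", stage,
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      sprintf(...)))
    }
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seed <- config$seed

  ## 1. data
  data <- run_stage("data", {
    if (!is.null(config$trial)) {
      generate_trial(config$trial, seed = substream_seed(seed, "trial"))
    } else {
      read_trial_csv(config$input_dir)
    }
  })
  say("data", "%d patients, %d utility rows", nrow(data$survival),
      nrow(data$utilities))

  ## 2. dropout rules + imputation -> QALYs
  qaly_df <- NULL
  imputed <- NULL
  utilities <- run_stage("dropout-utilities", {
    assign_dropout_utility(data$utilities,
                           end_of_rt_month = config$end_of_rt_month,
                           utility_before = config$dropout_utility[["before"]],
                           utility_after = config$dropout_utility[["after"]])
  })
  run_stage("imputation", {
    if (anyNA(utilities$utility)) {
      imputed <- impute_chained(utilities, m = config$m,
                                seed = substream_seed(seed, "imputation"))
      qaly_df <- qaly_from_imputations(imputed)
    } else {
      qaly_df <- qaly_by_patient(utilities)
      qaly_df$n_imputations <- 0L
    }
  })
  say("qaly", "mean QALY %.4f (treatment) / %.4f (control)",
      mean(qaly_df$qaly[qaly_df$arm == "treatment"]),
      mean(qaly_df$qaly[qaly_df$arm == "control"]))

  ## 2b. utility-profile mixed model on the first completed dataset
  lmm <- run_stage("lmm", {
    lmm_data <- if (!is.null(imputed)) imputed$datasets[[1]] else utilities
    fit_random_intercept_lmm(lmm_data)
  })

  ## 3. costing
  costs <- run_stage("costing", {
    suppressMessages(cost_breakdowns(data$resources,
                                     unit_costs = config$unit_costs,
                                     target_year = config$target_year,
                                     index = config$index))
  })
  cost_tab <- run_stage("cost-table", {
    cost_table(costs, b_boot = config$B,
               seed = substream_seed(seed, "cost-table"))
  })
  say("costs", "mean total %.2f (treatment) / %.2f (control)",
      mean(costs$total[costs$arm == "treatment"]),
      mean(costs$total[costs$arm == "control"]))

  ## 4. bootstrap decision analysis
  ce_data <- merge(qaly_df[c("id", "arm", "qaly")],
                   costs[c("id", "total")], by = "id")
  names(ce_data)[names(ce_data) == "total"] <- "cost"
  boot <- run_stage("bootstrap", {
    dist <- bootstrap_pairs(ce_data, B = config$B,
                            seed = substream_seed(seed, "bootstrap"))
    k <- config$wtp_reference
    evpi_pp <- evpi(dist, k)
    list(distribution = dist,
         icer = icer(dist$point_estimate[["delta_cost"]],
                     dist$point_estimate[["delta_effect"]]),
         ceac = ceac(dist, config$wtp_grid),
         voi = value_of_information_table(dist, config$wtp_grid),
         eib = eib(dist, k),
         evpi = evpi_pp,
         population_evpi = population_evpi(evpi_pp, config$incidence,
                                           config$horizon_years,
                                           config$discount))
  })
  say("bootstrap", "ICER %.0f (%s); CEAC(%d) = %.3f",
      boot$icer$ratio %||% NA, boot$icer$label, config$wtp_reference,
      boot$ceac$probability[boot$ceac$wtp == config$wtp_reference])

  ## 5. parametric sensitivity analysis
  psa <- run_stage("psa", {
    vm <- unique(utilities$visit_month)
    max_q <- (max(vm) - min(vm)) / 12  # QALY ceiling over the horizon
    fit_arm <- function(a) {
      arm_cost <- costs$total[costs$arm == a]
      arm_qaly <- qaly_df$qaly[qaly_df$arm == a]
      list(cost = fit_best_distribution(arm_cost),
           qaly = fit_best_distribution(
             as.numeric(transform_qaly_complement(arm_qaly, max_q))))
    }
    fit_sets <- list(treatment = fit_arm("treatment"),
                     control = fit_arm("control"))
    best <- lapply(fit_sets, function(fs)
      list(cost = fs$cost$best, qaly = fs$qaly$best))
    dist <- sample_psa(best, n = config$psa_n,
                       seed = substream_seed(seed, "psa"),
                       max_q = max_q,
                       point_estimate = boot$distribution$point_estimate)
    k <- config$wtp_reference
    list(fits = fit_sets, fit_table = psa_fit_table(fit_sets),
         distribution = dist,
         icer = icer(mean(dist$delta_cost), mean(dist$delta_effect)),
         ceac = ceac(dist, config$wtp_grid),
         eib = eib(dist, k), evpi = evpi(dist, k),
         max_q = max_q)
  })
  say("psa", "cost families: %s / %s",
      psa$fits$treatment$cost$best$family,
      psa$fits$control$cost$best$family)

  ## 6. long-term survival
  surv <- run_stage("survival", {
    sd <- data$survival
    curves <- list(
      treatment = km_fit(sd$time_days[sd$arm == "treatment"],
                         sd$event[sd$arm == "treatment"]),
      control = km_fit(sd$time_days[sd$arm == "control"],
                       sd$event[sd$arm == "control"]))
    followup <- reverse_km_median(sd$time_days, sd$event)
    wlr <- lapply(list(c(0, 0), c(1, 0), c(0, 2)), function(pq)
      weighted_logrank(sd$time_days, sd$event, sd$arm, pq[1], pq[2]))
    names(wlr) <- c("logrank", "early", "late")
    mc <- maxcombo(sd$time_days, sd$event, sd$arm,
                   n_perm = config$n_perm,
                   seed = substream_seed(seed, "maxcombo"))
    lyg <- discounted_lyg_icer(
      curves$treatment, curves$control,
      delta_cost = boot$distribution$point_estimate[["delta_cost"]],
      taus_years = config$taus_years, discount = config$discount)
    list(curves = curves, median_followup = followup,
         weighted_logrank = wlr, maxcombo = mc, lyg_table = lyg)
  })
  say("survival", "median follow-up %s d; max-combo P = %.4f",
      format(surv$median_followup$median), surv$maxcombo$p_value)

  manifest <- list(
    package_version = as.character(utils::packageVersion("trialcea")),
    config_hash = config_hash(config),
    master_seed = seed,
    stage_seeds = vapply(c("trial", "imputation", "cost-table",
                           "bootstrap", "psa", "maxcombo"),
                         function(s) substream_seed(seed, s), integer(1)),
    n_patients = nrow(data$survival),
    n_utility_rows = nrow(data$utilities),
    mode = if (!is.null(config$trial)) "simulate" else "csv")

  result <- structure(list(data = data, utilities = utilities,
                           imputed = imputed, qaly = qaly_df, lmm = lmm,
                           costs = costs, cost_table = cost_tab,
                           ce_data = ce_data, bootstrap = boot, psa = psa,
                           survival = surv, config = config,
                           manifest = manifest),
                      class = "cea_pipeline")
  if (!is.null(config$out_dir)) {
    run_stage("write-outputs", write_pipeline_outputs(result,
                                                      config$out_dir))
    say("write-outputs", "artifacts in %s", config$out_dir)
  }
  result
}

#' Write pipeline artifacts as CSV/JSON
#'
#' @param result A `cea_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "cea_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  boot <- result$bootstrap
  psa <- result$psa
  surv <- result$survival
  files <- c(
    wcsv(result$qaly, "qaly.csv"),
    wcsv(result$cost_table, "cost_table.csv"),
    wcsv(data.frame(delta_cost = boot$distribution$delta_cost,
                    delta_qaly = boot$distribution$delta_effect),
         "cep_pairs.csv"),
    wcsv(boot$ceac, "ceac.csv"),
    wcsv(boot$voi, "value_of_information.csv"),
    wcsv(psa$fit_table, "psa_fit_table.csv"),
    wcsv(data.frame(delta_cost = psa$distribution$delta_cost,
                    delta_qaly = psa$distribution$delta_effect),
         "psa_cep_pairs.csv"),
    wcsv(psa$ceac, "psa_ceac.csv"),
    wcsv(km_as_data_frame(surv$curves$treatment), "km_treatment.csv"),
    wcsv(km_as_data_frame(surv$curves$control), "km_control.csv"),
    wcsv(surv$lyg_table, "lyg_icer.csv"))
  decision <- list(
    point_icer = boot$icer,
    eib = boot$eib, evpi_per_patient = boot$evpi,
    population_evpi = boot$population_evpi,
    psa_icer = psa$icer, psa_eib = psa$eib,
    psa_evpi_per_patient = psa$evpi,
    median_followup_days = surv$median_followup$median,
    median_followup_ci = surv$median_followup$ci,
    weighted_logrank_p = lapply(surv$weighted_logrank, `[[`, "p_value"),
    maxcombo = surv$maxcombo[c("statistic", "p_value", "mc_se",
                               "n_perm")])
  jp <- file.path(dir, "decision_metrics.json")
  jsonlite::write_json(decision, jp, auto_unbox = TRUE, digits = NA,
                       na = "null")
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(result$manifest, mp, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(files, jp, mp))
}

#' @export
print.cea_pipeline <- function(x, ...) {
  b <- x$bootstrap
  cat("Trial-based cost-effectiveness analysis\n")
  cat(sprintf("  n = %d patients; delta cost %.2f euro, delta QALY %.5f\n",
              nrow(x$data$survival),
              b$distribution$point_estimate[["delta_cost"]],
              b$distribution$point_estimate[["delta_effect"]]))
  cat(sprintf("  point ICER: %s (%s)\n",
              if (b$icer$defined) sprintf("%.0f euro/QALY", b$icer$ratio)
              else "undefined", b$icer$label))
  k <- x$config$wtp_reference
  cat(sprintf("  at WTP %d: CEAC %.3f, EIB %.2f, EVPI %.2f/patient, ",
              k, b$ceac$probability[b$ceac$wtp == k], b$eib$eib, b$evpi))
  cat(sprintf("population EVPI %.2f M\n", b$population_evpi / 1e6))
  cat(sprintf("  max-combo permutation P = %.4f\n",
              x$survival$maxcombo$p_value))
  invisible(x)
}
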