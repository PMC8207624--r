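# Shared fixtures and independent oracles used across test files.

# A small, fast trial configuration (default models, smaller arms).
small_config <- function(n = 30, seed = 42, ...) {
  trial_config(n_treatment = n, n_control = n, seed = seed, ...)
}

# Noise-free configuration: no dropout, no deaths in the trial window,
# no residual/intercept variance, no MCAR missingness.
noise_free_config <- function(n = 12, seed = 5) {
  trial_config(
    n_treatment = n, n_control = n,
    utility_model = list(mean_treatment = c(0.8, 0.7, 0.7, 0.75),
                         mean_control = c(0.78, 0.68, 0.68, 0.73),
                         sd_intercept = 0, sd_residual = 0),
    dropout_model = list(
      treatment = c(hospitalization = 0, artificial_nutrition = 0,
                    lost = 0),
      control = c(hospitalization = 0, artificial_nutrition = 0,
                  lost = 0)),
    survival_model = list(hazard_early = c(treatment = 0, control = 0),
                          hazard_late = c(treatment = 2.9e-4,
                                          control = 6.4e-4),
                          changepoint_days = 365),
    mcar_rate = 0, seed = seed)
}

# Zero-dropout configuration with utility noise kept: every utility is
# observed, so empirical QALY means are comparable to true_values.
no_dropout_config <- function(n = 30, seed = 9) {
  cfg <- noise_free_config(n, seed)
  cfg$utility_model <- default_utility_model()
  cfg
}

# Random small survival dataset with ties and censoring, for oracles.
random_survival_data <- function(n = 30) {
  time <- sample(1:25, n, replace = TRUE)  # many ties
  event <- rbinom(n, 1, 0.7)
  arm <- sample(c("treatment", "control"), n, replace = TRUE)
  # make sure both arms appear and at least one event exists
  arm[1:2] <- c("treatment", "control")
  event[1] <- 1
  data.frame(time = time, event = event, arm = arm)
}

# Long-format utility table built directly (unit-level fixture).
utility_traj <- function(id = "P1", arm = "treatment",
                         months = c(0, 2, 3, 5),
                         utility = c(0.8, 0.6, 0.6, 0.8),
                         dropout_reason = "none",
                         dropout_month = NA_real_) {
  data.frame(id = id, arm = arm, visit_month = months, utility = utility,
             dropout_reason = dropout_reason,
             dropout_month = dropout_month, stringsAsFactors = FALSE)
}

# Simulated long-format utility data with known LMM structure.
simulate_lmm_data <- function(n_per_arm = 30, visits = c(0, 2, 3, 5),
                              mean_t = c(0.8, 0.7, 0.7, 0.75),
                              mean_c = c(0.8, 0.7, 0.7, 0.75),
                              sd_b = 0.1, sd_e = 0.05) {
  n <- 2 * n_per_arm
  arm <- rep(c("treatment", "control"), each = n_per_arm)
  b <- rnorm(n, 0, sd_b)
  rows <- lapply(seq_len(n), function(i) {
    mu <- if (arm[i] == "treatment") mean_t else mean_c
    data.frame(id = sprintf("S%03d", i), arm = arm[i],
               visit_month = visits,
               utility = mu + b[i] + rnorm(length(visits), 0, sd_e),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
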