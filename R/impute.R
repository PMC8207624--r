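IMPUTE_PREDICTORS <- c("age", "gender", "malnourished", "tumor_site",
                       "tumor_stage", "handgrip", "phase_angle")

# One Bayesian predictive-mean-matching draw for a single variable.
# y: full response vector; X: full design matrix; mis: logical missing
# mask (current working values in y[mis] are ignored); donors: donor pool.
pmm_draw <- function(y, X, mis, donors) {
  obs <- which(!mis)
  mis_i <- which(mis)
  qrX <- qr(X[obs, , drop = FALSE])
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xo <- X[obs, keep, drop = FALSE]
  Xm <- X[mis_i, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, y[obs])
  beta <- fit$coefficients
  df_res <- length(obs) - length(keep)
  if (df_res < 1) {
    stop("too few observed values to fit the imputation model",
         call. = FALSE)
  }
  rss <- sum(fit$residuals^2)
  sigma2_star <- rss / stats::rchisq(1, df_res)
  xtx_inv <- tryCatch(chol2inv(chol(crossprod(Xo))),
                      error = function(e)
                        chol2inv(chol(crossprod(Xo) +
                                        diag(1e-8, ncol(Xo)))))
  beta_star <- beta + sqrt(sigma2_star) *
    drop(t(chol(xtx_inv + diag(1e-12, ncol(Xo)))) %*%
           stats::rnorm(length(keep)))
  yhat_obs <- drop(Xo %*% beta)
  yhat_mis <- drop(Xm %*% beta_star)
  vapply(yhat_mis, function(p) {
    pool <- order(abs(yhat_obs - p))[seq_len(min(donors, length(obs)))]
    y[obs][pool[sample.int(length(pool), 1L)]]
  }, numeric(1))
}

#' Chained multiple imputation of missing utilities
#'
#' Imputes the utilities still missing after [assign_dropout_utility()] by
#' iterated conditional draws: each visit with missing values is regressed
#' on the baseline covariates (age, gender, malnutrition at inclusion,
#' tumor site and stage, handgrip strength, phase angle) plus the current
#' completed utilities at the other visits, and missing entries are filled
#' by predictive mean matching (a Bayesian parameter draw followed by
#' sampling one of the `donors` observed values with closest predicted
#' mean). Because donors are observed utilities, imputed values always lie
#' in \[0, 1\] and observed values are never altered.
#'
#' @param utilities Long-format utility data frame (as produced by
#'   [generate_trial()] and [assign_dropout_utility()]) containing the
#'   baseline covariate columns.
#' @param m Number of imputed datasets (must be at least 2; default 20).
#' @param seed Integer seed; each imputation uses its own substream.
#' @param maxit Chained iterations per imputation (default 10).
#' @param donors Predictive-mean-matching donor pool size (default 5).
#' @return An object of class `imputed_utilities`: a list with `datasets`
#'   (a list of `m` completed long-format data frames), `m`, `seed`, and
#'   the visit schedule.
#' @seealso [qaly_from_imputations()]
#' @export
impute_chained <- function(utilities, m = 20, seed = 1, maxit = 10,
                           donors = 5) {
  if (m < 2) stop("m must be at least 2", call. = FALSE)
  absent <- setdiff(c("id", "arm", "visit_month", "utility",
                      IMPUTE_PREDICTORS), names(utilities))
  if (length(absent)) {
    stop("utilities is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  visits <- sort(unique(utilities$visit_month))
  u <- utilities[order(utilities$id, utilities$visit_month), ]
  ids <- unique(u$id)
  n <- length(ids)
  U <- matrix(u$utility, nrow = n, ncol = length(visits), byrow = TRUE)
  miss <- is.na(U)
  all_missing <- colSums(!miss) == 0
  if (any(all_missing)) {
    stop("utility at month ", paste(visits[all_missing], collapse = ", "),
         " is missing for every patient; imputation model unidentifiable",
         call. = FALSE)
  }
  base <- u[u$visit_month == visits[1], c("id", IMPUTE_PREDICTORS)]
  if (anyNA(base[IMPUTE_PREDICTORS])) {
    bad <- IMPUTE_PREDICTORS[vapply(base[IMPUTE_PREDICTORS], anyNA,
                                    logical(1))]
    stop("baseline predictor(s) with missing values: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (v in IMPUTE_PREDICTORS) {
    if (is.character(base[[v]])) base[[v]] <- factor(base[[v]])
  }
  X0 <- stats::model.matrix(
    stats::reformulate(IMPUTE_PREDICTORS), data = base)
  target_cols <- which(colSums(miss) > 0)

  datasets <- vector("list", m)
  for (imp in seq_len(m)) {
    set.seed(substream_seed(seed, paste0("imputation-", imp)))
    U_cur <- U
    for (j in target_cols) {
      U_cur[miss[, j], j] <- sample(U[!miss[, j], j],
                                    sum(miss[, j]), replace = TRUE)
    }
    if (length(target_cols)) {
      for (it in seq_len(maxit)) {
        for (j in target_cols) {
          X <- cbind(X0, U_cur[, -j, drop = FALSE])
          U_cur[miss[, j], j] <- pmm_draw(U_cur[, j], X, miss[, j], donors)
        }
      }
    }
    filled <- u
    filled$utility <- as.vector(t(U_cur))
    datasets[[imp]] <- filled
  }
  structure(list(datasets = datasets, m = m, seed = seed,
                 visit_months = visits),
            class = "imputed_utilities")
}

#' @export
print.imputed_utilities <- function(x, ...) {
  cat(sprintf("%d imputed utility datasets (%d patients x %d visits)\n",
              x$m, nrow(x$datasets[[1]]) / length(x$visit_months),
              length(x$visit_months)))
  invisible(x)
}

#' Per-patient QALYs averaged across imputations
#'
#' Computes [qaly_by_patient()] within every completed dataset and averages
#' per patient, the per-patient summary the downstream bootstrap operates
#' on.
#'
#' @param imputed An `imputed_utilities` object.
#' @return Data frame `id`, `arm`, `qaly`, `n_imputations`.
#' @export
qaly_from_imputations <- function(imputed) {
  stopifnot(inherits(imputed, "imputed_utilities"))
  per <- lapply(imputed$datasets, qaly_by_patient)
  out <- per[[1]]
  qmat <- vapply(per, function(d) d$qaly, numeric(nrow(out)))
  out$qaly <- rowMeans(qmat)
  out$n_imputations <- imputed$m
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' @param estimates Per-imputation point estimates.
#' @param variances Per-imputation squared standard errors.
#' @return List with the pooled `estimate`, total variance `variance`
#'   (within + (1 + 1/m) between), and the between/within components.
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  stopifnot(m >= 2, length(variances) == m)
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  list(estimate = qbar, variance = w + (1 + 1 / m) * b,
       within = w, between = b, m = m)
}
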