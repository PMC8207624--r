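#' Default unit-cost table
#'
#' Unit costs for the resource categories of a nutritional-support trial
#' under an Italian NHS perspective: oral nutritional supplement (ONS)
#' bottles and their delivery service, medical visits, enteral (EN) and
#' parenteral (PN) nutrition days, severe mucositis episodes and hospital
#' admissions. Each row carries its price year; categories priced in
#' earlier years (mucositis 2008, hospitalization 2004) should be brought
#' to the target year with an inflation `index` (see [inflate()]); with no
#' index supplied amounts are treated as target-year euros.
#'
#' The `group` column aggregates unit-level categories into the reporting
#' categories used by [cost_table()].
#'
#' @return Data frame with columns `category`, `unit_cost` (euro), `unit`,
#'   `price_year`, `group`.
#' @export
default_unit_costs <- function() {
  data.frame(
    category = c("ons_treatment_bottle", "ons_treatment_service_day",
                 "ons_control_bottle", "first_visit", "followup_visit",
                 "en_service_day", "en_compound_day", "pn_day",
                 "mucositis_episode", "hospitalization_episode"),
    unit_cost = c(3.23, 2.26, 1.43, 28.50, 17.90, 6.18, 4.20, 43.40,
                  45.00, 608.00),
    unit = c("bottle", "day", "bottle", "visit", "visit", "day", "day",
             "day", "episode", "episode"),
    price_year = c(2017, 2017, 2017, 2017, 2017, 2017, 2017, 2017,
                   2008, 2004),
    group = c("ons", "ons", "ons", "medical_visit", "medical_visit",
              "enteral_nutrition", "enteral_nutrition",
              "parenteral_nutrition", "mucositis", "hospitalization"),
    stringsAsFactors = FALSE
  )
}

#' Adjust an amount for inflation between two price years
#'
#' @param amount Euro amount(s).
#' @param from_year,to_year Price years.
#' @param index Named numeric vector mapping years (as names) to index
#'   values (e.g. a consumer price index series).
#' @return `amount * index[to_year] / index[from_year]`.
#' @export
#' @examples
#' inflate(50, 2004, 2017, c(`2004` = 100, `2017` = 110))
inflate <- function(amount, from_year, to_year, index) {
  for (y in c(from_year, to_year)) {
    if (!as.character(y) %in% names(index)) {
      stop("inflation index has no entry for year ", y, call. = FALSE)
    }
  }
  amount * index[[as.character(to_year)]] / index[[as.character(from_year)]]
}

inflation_factors <- function(unit_costs, target_year, index = NULL) {
  if (is.null(index)) {
    return(rep(1, nrow(unit_costs)))
  }
  vapply(unit_costs$price_year, function(y) {
    inflate(1, y, target_year, index)
  }, numeric(1))
}

#' Cost a single patient's resource use
#'
#' Multiplies each resource count by its unit cost (inflated from the
#' category's price year to `target_year` when an `index` is supplied) and
#' aggregates into reporting groups. With `index = NULL` a notice is
#' logged once per session scope and unit costs are used as-is.
#'
#' @param resources Named numeric vector of counts/days per category.
#' @param unit_costs Unit-cost table, see [default_unit_costs()].
#' @param target_year Price year of the output (default 2017).
#' @param index Optional inflation index (named numeric, year -> index).
#' @param quiet Suppress the no-index notice.
#' @return An object of class `cost_breakdown`: per-category amounts,
#'   per-group amounts and the total (euro).
#' @export
#' @examples
#' patient_cost(c(ons_treatment_bottle = 60, ons_treatment_service_day = 60),
#'              default_unit_costs())
patient_cost <- function(resources, unit_costs = default_unit_costs(),
                         target_year = 2017, index = NULL, quiet = FALSE) {
  if (is.null(names(resources)) || any(!nzchar(names(resources)))) {
    stop("resources must be a named vector of category counts",
         call. = FALSE)
  }
  unknown <- setdiff(names(resources), unit_costs$category)
  if (length(unknown)) {
    stop("unknown resource category: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(resources < 0)) {
    stop("negative resource count for: ",
         paste(names(resources)[resources < 0], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(index) && !quiet) {
    message("no inflation index supplied; unit costs used as ",
            target_year, " euros")
  }
  fac <- inflation_factors(unit_costs, target_year, index)
  uc <- stats::setNames(unit_costs$unit_cost * fac, unit_costs$category)
  grp <- stats::setNames(unit_costs$group, unit_costs$category)
  amounts <- resources * uc[names(resources)]
  by_group <- tapply(amounts, grp[names(resources)], sum)
  groups <- unique(unit_costs$group)
  full <- stats::setNames(numeric(length(groups)), groups)
  full[names(by_group)] <- by_group
  structure(list(amounts = amounts, by_group = full,
                 total = sum(amounts), target_year = target_year),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("Patient cost breakdown (euro):\n")
  df <- data.frame(group = names(x$by_group),
                   euro = round(unname(x$by_group), 2))
  print(df, row.names = FALSE)
  cat(sprintf("  total: %.2f euro\n", x$total))
  invisible(x)
}

#' Cost every patient in a resource-use table
#'
#' @param resources Data frame with `id`, `arm` and one column per
#'   resource category.
#' @param unit_costs,target_year,index As in [patient_cost()].
#' @return Data frame with `id`, `arm`, one column per reporting group,
#'   and `total` (euro).
#' @export
cost_breakdowns <- function(resources, unit_costs = default_unit_costs(),
                            target_year = 2017, index = NULL) {
  cats <- setdiff(names(resources), c("id", "arm"))
  unknown <- setdiff(cats, unit_costs$category)
  if (length(unknown)) {
    stop("unknown resource category: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(as.matrix(resources[cats]) < 0)) {
    stop("negative resource counts present", call. = FALSE)
  }
  if (is.null(index)) {
    message("no inflation index supplied; unit costs used as ",
            target_year, " euros")
  }
  fac <- inflation_factors(unit_costs, target_year, index)
  uc <- stats::setNames(unit_costs$unit_cost * fac, unit_costs$category)
  grp <- stats::setNames(unit_costs$group, unit_costs$category)
  amounts <- as.matrix(resources[cats]) %*% diag(uc[cats])
  colnames(amounts) <- cats
  groups <- unique(unit_costs$group)
  out <- data.frame(id = resources$id, arm = resources$arm,
                    stringsAsFactors = FALSE)
  for (g in groups) {
    gc <- cats[grp[cats] == g]
    out[[g]] <- if (length(gc)) rowSums(amounts[, gc, drop = FALSE]) else 0
  }
  out$total <- rowSums(out[groups])
  out
}

#' Per-category cost comparison between arms
#'
#' Reproduces the classical trial costing table: per-arm mean euro cost
#' for each reporting group and for the total, a Welch t-test p-value per
#' row, and for the total additionally a stratified bootstrap percentile
#' p-value, `2 * min(P(delta* <= 0), P(delta* >= 0))`, which is robust to
#' the heavy right tails typical of hospitalization and parenteral
#' nutrition costs.
#'
#' @param costs Output of [cost_breakdowns()].
#' @param b_boot Bootstrap replicates for the total-cost p-value
#'   (default 1000; values below 100 trigger a warning).
#' @param seed Integer seed for the bootstrap.
#' @return Data frame with `category`, `mean_treatment`, `mean_control`,
#'   `p_ttest` and `p_bootstrap` (non-missing for the total row only).
#' @export
cost_table <- function(costs, b_boot = 1000, seed = 1) {
  arms <- unique(costs$arm)
  if (!all(c("treatment", "control") %in% arms)) {
    stop("both a treatment and a control arm are required", call. = FALSE)
  }
  if (b_boot < 100) {
    warning("b_boot < 100 gives a very coarse bootstrap p-value")
  }
  groups <- setdiff(names(costs), c("id", "arm", "total"))
  t_arm <- costs[costs$arm == "treatment", ]
  c_arm <- costs[costs$arm == "control", ]
  welch_p <- function(x, y) {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
  }
  rows <- lapply(c(groups, "total"), function(g) {
    data.frame(category = g,
               mean_treatment = mean(t_arm[[g]]),
               mean_control = mean(c_arm[[g]]),
               p_ttest = welch_p(t_arm[[g]], c_arm[[g]]),
               p_bootstrap = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  set.seed(substream_seed(seed, "cost-bootstrap"))
  nt <- nrow(t_arm)
  nc <- nrow(c_arm)
  mt <- matrix(t_arm$total[sample.int(nt, nt * b_boot, replace = TRUE)],
               nrow = b_boot)
  mc <- matrix(c_arm$total[sample.int(nc, nc * b_boot, replace = TRUE)],
               nrow = b_boot)
  delta <- rowMeans(mt) - rowMeans(mc)
  p_boot <- min(1, 2 * min(mean(delta <= 0), mean(delta >= 0)))
  out$p_bootstrap[out$category == "total"] <- p_boot
  out
}
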