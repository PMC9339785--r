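#' Per-cycle discount factor
#'
#' `(1 + r)^(-cycle * cycle_length / 365.25)`; cycle 0 has factor 1.
#'
#' @param rate Annual discount rate, `>= 0`.
#' @param cycle Non-negative cycle index (vectorized).
#' @param cycle_length Cycle length in days.
#' @return Discount factors in `(0, 1]`.
#' @examples
#' discount_factor(0.05, 365.25 / 28, 28)  # one year: 1/1.05
#' @export
discount_factor <- function(rate, cycle, cycle_length) {
  if (rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  if (any(cycle < 0)) stop("cycle must be >= 0", call. = FALSE)
  (1 + rate)^(-cycle * cycle_length / 365.25)
}

#' Mean drug price
#'
#' Arithmetic mean of component prices (e.g. originator and generics),
#' rounded to 2 decimals for reporting.
#'
#' @param prices Non-empty numeric vector of prices in yuan.
#' @return The mean price rounded to 2 decimal places.
#' @examples
#' mean_price(c(1599.40, 1295.90, 1272.58))  # 1389.29
#' @export
mean_price <- function(prices) {
  if (length(prices) == 0L) stop("empty price vector", call. = FALSE)
  round(mean(prices), 2)
}

# expected AE cost per event-category (mix over itemized rows)
ae_category_cost <- function(params, category) {
  mix <- params$ae$mix[[category]]
  sum(vapply(names(mix), function(nm) mix[[nm]] * params$ae$costs[[nm]], numeric(1)))
}

# expected AE decrement per event-category
ae_category_disutility <- function(params, category) {
  mix <- params$ae$disutility_mix[[category]]
  sum(vapply(names(mix), function(nm) mix[[nm]] * params$ae$disutility[[nm]], numeric(1)))
}

# expected per-cycle AE cost and QALY decrement for each state of one arm
ae_state_expectation <- function(params, arm) {
  inc <- params$ae$incidence[[arm]]
  cats <- names(inc)
  exp_cost <- sum(vapply(cats, function(cg) inc[[cg]] * ae_category_cost(params, cg), numeric(1)))
  exp_disu <- sum(vapply(cats, function(cg) inc[[cg]] * ae_category_disutility(params, cg), numeric(1)))
  cost <- stats::setNames(rep(0, 9), cea_states)
  disu <- stats::setNames(rep(0, 9), cea_states)
  cost[params$ae$states] <- exp_cost
  disu[params$ae$states] <- exp_disu
  list(cost = cost, disutility = disu)
}

# administration (resource-use) cost per state per cycle
admin_state_cost <- function(params) {
  out <- stats::setNames(rep(0, 9), cea_states)
  for (s in names(params$admin_freq)) {
    fr <- params$admin_freq[[s]]
    out[s] <- sum(vapply(names(fr), function(item) fr[[item]] * params$costs[[item]],
                         numeric(1)))
  }
  out
}

# drug + management cost per state for a given cycle (first cycle differs)
state_cycle_cost <- function(params, arm, cycle) {
  cl <- params$settings$cycle_length_days
  pr <- params$prices
  cost <- stats::setNames(rep(0, 9), cea_states)
  cost["first_line"] <- if (arm == "degarelix") {
    if (cycle == 0) pr$degarelix_first_cycle else pr$degarelix_maintenance
  } else {
    pr$leuprorelin_per_cycle + if (cycle == 0) pr$flare_cover_daily * cl else 0
  }
  cost["aa_addition"] <- pr$flare_cover_daily * cl
  cost["docetaxel"] <- (pr$docetaxel_daily + pr$dexamethasone_daily) * cl
  cost["abiraterone"] <- (pr$abiraterone_daily + pr$dexamethasone_daily) * cl
  cost["post_abiraterone"] <- params$costs$post_abiraterone_cycle
  cost["supportive_care"] <- params$costs$supportive_care_cycle
  cost["palliative_care"] <- params$costs$palliative_care_cycle
  cost
}

#' Accumulate discounted costs and QALYs from a cohort trace
#'
#' Each of the `n` model cycles accrues, for every state, occupancy times
#' (state cost + expected adverse-event cost) discounted at the cost rate,
#' and occupancy times (utility + expected adverse-event decrement) times
#' `cycle_length / 365.25` discounted at the effect rate. Occupancy at the
#' start of each cycle is used; with `settings$half_cycle_correction = TRUE`
#' the mean of start- and end-of-cycle occupancy is used instead.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param params A `cea_parameters` object.
#' @param arm Arm label; defaults to the trace's arm.
#' @return A list with class `arm_totals`: `arm`, `cost` (yuan), `qalys`,
#'   `life_years` (undiscounted expected years alive).
#' @export
accumulate <- function(trace, params, arm = trace$arm) {
  stopifnot(inherits(trace, "cohort_trace"))
  arm <- match.arg(arm, cea_arms)
  missing_u <- setdiff(setdiff(cea_states, "death"), names(params$utilities))
  if (length(missing_u)) {
    stop("missing utilities for state(s): ", paste(missing_u, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(trace$occupancy) - 1L
  cl <- trace$cycle_length_days
  occ <- trace$occupancy[1:n, , drop = FALSE]
  if (isTRUE(params$settings$half_cycle_correction)) {
    occ <- (occ + trace$occupancy[2:(n + 1), , drop = FALSE]) / 2
  }
  df_c <- discount_factor(params$settings$discount_cost, 0:(n - 1), cl)
  df_e <- discount_factor(params$settings$discount_effect, 0:(n - 1), cl)

  util <- stats::setNames(rep(0, 9), cea_states)
  for (s in names(params$utilities)) util[s] <- params$utilities[[s]]
  ae <- ae_state_expectation(params, arm)
  admin <- admin_state_cost(params)

  # constant-per-cycle components (everything except the cycle-0 drug dose)
  base_cost <- state_cycle_cost(params, arm, cycle = 1) + admin + ae$cost
  cost_per_cycle <- as.numeric(occ %*% base_cost)
  # cycle-0 drug adjustment
  delta0 <- state_cycle_cost(params, arm, cycle = 0) - state_cycle_cost(params, arm, cycle = 1)
  cost_per_cycle[1] <- cost_per_cycle[1] + sum(occ[1, ] * delta0)

  qaly_w <- util + ae$disutility
  qaly_per_cycle <- as.numeric(occ %*% qaly_w) * cl / 365.25
  alive <- 1 - occ[, "death"]

  structure(
    list(
      arm = arm,
      cost = sum(cost_per_cycle * df_c),
      qalys = sum(qaly_per_cycle * df_e),
      life_years = sum(alive * cl / 365.25)
    ),
    class = "arm_totals"
  )
}

#' @export
print.arm_totals <- function(x, ...) {
  cat(sprintf("%s: cost %.0f yuan, %.3f QALYs (%.2f undiscounted life-years)\n",
              x$arm, x$cost, x$qalys, x$life_years))
  invisible(x)
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes `delta_cost`, `delta_qalys`, the ICER `delta_cost / delta_qalys`,
#' the incremental net benefit `INB = wtp * delta_qalys - delta_cost`, and
#' the ICER as a multiple of GDP per capita. Degenerate cases are labelled,
#' not raised: `delta_qalys = 0` flags the ICER undefined; a cheaper and more
#' effective intervention is labelled `"dominant"`, a costlier and less
#' effective one `"dominated"`.
#'
#' @param a `arm_totals` of the intervention arm.
#' @param b `arm_totals` of the reference arm.
#' @param wtp Willingness-to-pay threshold in yuan/QALY.
#' @param gdp_per_capita GDP per capita in yuan (for the GDP multiple);
#'   optional.
#' @return An `economic_result` list: per-arm totals, `delta_cost`,
#'   `delta_qalys`, `icer`, `icer_label` (`"defined"`, `"undefined"`,
#'   `"dominant"`, `"dominated"`), `wtp`, `inb`, `gdp_multiple`.
#' @examples
#' a <- structure(list(arm = "degarelix", cost = 566226, qalys = 5.190), class = "arm_totals")
#' b <- structure(list(arm = "leuprorelin", cost = 489693, qalys = 4.510), class = "arm_totals")
#' incremental(a, b, wtp = 242928, gdp_per_capita = 80976)$icer
#' @export
incremental <- function(a, b, wtp, gdp_per_capita = NA_real_) {
  dc <- a$cost - b$cost
  de <- a$qalys - b$qalys
  if (de == 0) {
    icer <- NA_real_
    label <- "undefined"
  } else {
    icer <- dc / de
    label <- if (dc < 0 && de > 0) "dominant" else if (dc > 0 && de < 0) "dominated" else "defined"
  }
  structure(
    list(
      arm_a = a, arm_b = b,
      delta_cost = dc, delta_qalys = de,
      icer = icer, icer_label = label,
      wtp = wtp, inb = wtp * de - dc,
      gdp_per_capita = gdp_per_capita,
      gdp_multiple = if (is.finite(gdp_per_capita)) icer / gdp_per_capita else NA_real_
    ),
    class = "economic_result"
  )
}

#' @export
print.economic_result <- function(x, ...) {
  cat("Incremental cost-utility result\n")
  cat(sprintf("  %-12s cost %9.0f yuan, %6.3f QALYs\n", x$arm_a$arm, x$arm_a$cost, x$arm_a$qalys))
  cat(sprintf("  %-12s cost %9.0f yuan, %6.3f QALYs\n", x$arm_b$arm, x$arm_b$cost, x$arm_b$qalys))
  cat(sprintf("  delta cost %.0f yuan, delta QALYs %.3f\n", x$delta_cost, x$delta_qalys))
  icer_str <- switch(x$icer_label,
    dominant = "Dominant", dominated = "Dominated",
    undefined = "undefined (delta QALYs = 0)",
    sprintf("%.0f yuan/QALY", x$icer))
  cat("  ICER:", icer_str, "\n")
  if (is.finite(x$gdp_multiple)) {
    cat(sprintf("  = %.2f times GDP per capita\n", x$gdp_multiple))
  }
  cat(sprintf("  INB at WTP %.0f: %.0f yuan\n", x$wtp, x$inb))
  invisible(x)
}

#' One-row summary table of an economic result
#'
#' Mirrors the layout of a base-case results table: one row per arm with
#' total cost (0 d.p.), QALYs (3 d.p.), and the incremental columns on the
#' intervention row.
#'
#' @param result An `economic_result`.
#' @return A data.frame with columns `treatment`, `total_cost`, `qalys`,
#'   `incremental_qalys`, `icer`, `inb`.
#' @export
result_table <- function(result) {
  icer_str <- switch(result$icer_label,
    dominant = "Dominant", dominated = "Dominated", undefined = "NA",
    sprintf("%.0f", result$icer))
  data.frame(
    treatment = c(result$arm_a$arm, result$arm_b$arm),
    total_cost = round(c(result$arm_a$cost, result$arm_b$cost)),
    qalys = round(c(result$arm_a$qalys, result$arm_b$qalys), 3),
    incremental_qalys = c(round(result$delta_qalys, 3), NA),
    icer = c(icer_str, NA),
    inb = c(round(result$inb), NA)
  )
}

#' Run the full cost-utility comparison for a parameter set
#'
#' Convenience wrapper: runs both cohort arms, accumulates discounted totals,
#' and returns the incremental comparison at the configured willingness to
#' pay (`wtp_multiple * gdp_per_capita`).
#'
#' @param params A `cea_parameters` object.
#' @param wtp Willingness to pay; default from the parameter set.
#' @return An `economic_result` (with the two `cohort_trace`s attached as
#'   attribute `"traces"`).
#' @export
run_cea <- function(params, wtp = NULL) {
  if (is.null(wtp)) {
    wtp <- params$economics$wtp_multiple * params$economics$gdp_per_capita
  }
  tr_a <- run_cohort(params, "degarelix")
  tr_b <- run_cohort(params, "leuprorelin")
  res <- incremental(
    accumulate(tr_a, params),
    accumulate(tr_b, params),
    wtp = wtp,
    gdp_per_capita = params$economics$gdp_per_capita
  )
  attr(res, "traces") <- list(degarelix = tr_a, leuprorelin = tr_b)
  res
}
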