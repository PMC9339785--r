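#' Default one-way perturbation set
#'
#' Builds the standard one-way sensitivity ranges: cost-class parameters
#' (prices, per-cycle and per-event costs) varied by +/-20%, efficacy-class
#' parameters (the PSA-recurrence hazard ratio and the per-cycle second-line
#' response rates) by +/-10%, state utilities by +/-10% (capped at 1), and
#' the cost discount rate over 0 to 8%.
#'
#' @param params A `cea_parameters` object.
#' @return A data.frame with columns `path`, `low`, `high`, `class`.
#' @export
default_perturbations <- function(params) {
  rows <- list()
  add <- function(path, low, high, class) {
    rows[[length(rows) + 1L]] <<- data.frame(path = path, low = low,
                                             high = high, class = class)
  }
  cost_paths <- c(
    "prices.degarelix_first_cycle", "prices.degarelix_maintenance",
    "prices.leuprorelin_per_cycle", "prices.flare_cover_daily",
    "prices.docetaxel_daily", "prices.abiraterone_daily",
    "costs.post_abiraterone_cycle", "costs.supportive_care_cycle",
    "costs.palliative_care_cycle"
  )
  for (p in cost_paths) {
    v <- param_get(params, p)
    add(p, 0.8 * v, 1.2 * v, "cost")
  }
  eff_paths <- c(
    "survival.hr_psa_recurrence",
    "transitions.response_aa_addition", "transitions.response_aa_withdrawal",
    "transitions.response_docetaxel", "transitions.response_abiraterone"
  )
  for (p in eff_paths) {
    v <- param_get(params, p)
    add(p, 0.9 * v, min(1.1 * v, if (startsWith(p, "transitions.")) 1 else Inf), "efficacy")
  }
  for (p in paste0("utilities.", setdiff(cea_states, "death"))) {
    v <- param_get(params, p)
    add(p, 0.9 * v, min(1.1 * v, 1), "utility")
  }
  add("settings.discount_cost", 0, 0.08, "rate")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the full model twice per parameter (at its low and high
#' value, all other parameters at base) and tabulates the ICER range, sorted
#' by descending range with a stable sort. A perturbation the model never
#' reads yields a zero range; a path listed twice yields two identical rows.
#'
#' @param params Base `cea_parameters`.
#' @param perturbations Data.frame with columns `path`, `low`, `high`
#'   (optionally `class`); default [default_perturbations()].
#' @return A `tornado` data.frame with columns `path`, `class`, `low_input`,
#'   `high_input`, `icer_low`, `icer_high`, `range`, plus attribute
#'   `"base_icer"`.
#' @export
one_way <- function(params, perturbations = default_perturbations(params)) {
  stopifnot(all(c("path", "low", "high") %in% names(perturbations)))
  base_icer <- run_cea(params)$icer
  eval_at <- function(path, value) run_cea(param_set(params, path, value))$icer
  icer_low <- numeric(nrow(perturbations))
  icer_high <- numeric(nrow(perturbations))
  for (i in seq_len(nrow(perturbations))) {
    icer_low[i] <- eval_at(perturbations$path[i], perturbations$low[i])
    icer_high[i] <- eval_at(perturbations$path[i], perturbations$high[i])
  }
  out <- data.frame(
    path = perturbations$path,
    class = if ("class" %in% names(perturbations)) perturbations$class else NA,
    low_input = perturbations$low,
    high_input = perturbations$high,
    icer_low = icer_low,
    icer_high = icer_high,
    range = abs(icer_high - icer_low)
  )
  out <- out[order(-out$range), , drop = FALSE]  # order() is a stable sort
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  class(out) <- c("tornado", "data.frame")
  out
}

#' Scenario analysis: run the model under a set of parameter edits
#'
#' Applies dot-path edits to a copy of the base parameter set and returns the
#' incremental result; the base object is never modified (pure function).
#'
#' @param params Base `cea_parameters`.
#' @param edits Named list mapping dot-paths to replacement values (empty
#'   list reproduces the base result).
#' @return An `economic_result`.
#' @examples
#' p <- default_parameters()
#' ten_year <- scenario_run(p, list(settings.horizon_years = 10))
#' @export
scenario_run <- function(params, edits = list()) {
  for (path in names(edits)) {
    params <- param_set(params, path, edits[[path]])
  }
  run_cea(params)
}

#' Threshold-price search by bisection
#'
#' Finds the price at which the model's ICER equals a target willingness-
#' to-pay (e.g. 1x GDP per capita), assuming the ICER is monotone in the
#' addressed price over the bracket. Stops when the ICER is within
#' `tol_icer` of the target or the bracket is narrower than `tol_price`.
#'
#' @param params Base `cea_parameters`.
#' @param price_path Dot-path of the price to vary.
#' @param target_icer Target ICER in yuan/QALY.
#' @param lower,upper Search bracket; defaults to `(0, 4x base price)`.
#' @param tol_icer ICER tolerance, default 1 yuan/QALY.
#' @param tol_price Bracket-width tolerance, default 0.01 yuan.
#' @return A list: `price`, `pct_change` from the base price, `icer` at the
#'   solution, `iterations`.
#' @export
threshold_price <- function(params, price_path, target_icer,
                            lower = NULL, upper = NULL,
                            tol_icer = 1, tol_price = 0.01) {
  base_price <- param_get(params, price_path)
  if (is.null(lower)) lower <- 0
  if (is.null(upper)) upper <- 4 * base_price
  icer_at <- function(price) run_cea(param_set(params, price_path, price))$icer
  f_lo <- icer_at(lower) - target_icer
  f_hi <- icer_at(upper) - target_icer
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0) {
    stop("target ICER not bracketed by [", lower, ", ", upper, "]", call. = FALSE)
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mid <- (lower + upper) / 2
    f_mid <- icer_at(mid) - target_icer
    if (abs(f_mid) <= tol_icer || (upper - lower) / 2 < tol_price || iter >= 200L) {
      return(list(price = mid,
                  pct_change = 100 * (mid - base_price) / base_price,
                  icer = f_mid + target_icer,
                  iterations = iter))
    }
    if (f_lo * f_mid <= 0) {
      upper <- mid
      f_hi <- f_mid
    } else {
      lower <- mid
      f_lo <- f_mid
    }
  }
}

# ---- probabilistic sensitivity analysis ------------------------------------

#' Default PSA distribution assignments
#'
#' Assigns standard cost-effectiveness sampling distributions to the
#' uncertain parameters: gamma for costs and prices, beta for utilities and
#' per-cycle probabilities, log-normal for hazard ratios. Hyper-parameters
#' are derived by moment matching from the base value and a relative
#' standard error (default 20%).
#'
#' @param params A `cea_parameters` object.
#' @param rse Relative standard error applied to every parameter.
#' @return A data.frame with columns `path`, `family`, `rse`.
#' @export
default_psa_distributions <- function(params, rse = 0.2) {
  gamma_paths <- c(
    "prices.degarelix_first_cycle", "prices.degarelix_maintenance",
    "prices.leuprorelin_per_cycle", "prices.flare_cover_daily",
    "prices.docetaxel_daily", "prices.abiraterone_daily",
    "costs.post_abiraterone_cycle", "costs.supportive_care_cycle",
    "costs.palliative_care_cycle", "costs.gp_visit", "costs.bone_scan",
    "costs.ct_scan", "costs.mri", "costs.blood_test"
  )
  beta_paths <- c(
    paste0("utilities.", setdiff(cea_states, "death")),
    "transitions.response_aa_addition", "transitions.response_aa_withdrawal",
    "transitions.response_docetaxel", "transitions.response_abiraterone",
    "transitions.response_post_abiraterone", "transitions.response_supportive_care",
    "transitions.chemo_skip_fraction"
  )
  lnorm_paths <- c("survival.hr_psa_recurrence", "mortality.hr_post_progression")
  data.frame(
    path = c(gamma_paths, beta_paths, lnorm_paths),
    family = c(rep("gamma", length(gamma_paths)),
               rep("beta", length(beta_paths)),
               rep("lognormal", length(lnorm_paths))),
    rse = rse
  )
}

# moment-matched draws for one parameter; rse = 0 degenerates to the base
psa_draw <- function(family, base, rse, n) {
  if (rse == 0 || base == 0) return(rep(base, n))
  s <- rse * base
  switch(family,
    gamma = {
      shape <- 1 / rse^2
      stats::rgamma(n, shape = shape, rate = shape / base)
    },
    beta = {
      s <- min(s, 0.95 * sqrt(base * (1 - base)))
      nu <- base * (1 - base) / s^2 - 1
      stats::rbeta(n, base * nu, (1 - base) * nu)
    },
    lognormal = {
      sdlog <- sqrt(log1p(rse^2))
      stats::rlnorm(n, meanlog = log(base) - sdlog^2 / 2, sdlog = sdlog)
    },
    stop("unknown PSA distribution family: ", family, call. = FALSE)
  )
}

psa_domain <- function(family) {
  switch(family,
    beta = c(0, 1),
    gamma = c(0, Inf),
    lognormal = c(0, Inf)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo samples every listed parameter independently from its assigned
#' distribution, re-runs the full two-arm model per iteration, and summarizes
#' the incremental cost-effectiveness plane and the cost-effectiveness
#' acceptability curve `CEAC(wtp) = mean(INB > 0)`.
#'
#' Draws are parameter-major under one root seed: each parameter's vector of
#' `n_iter` draws is generated in the listed order, so appending a new
#' parameter leaves all earlier draws unchanged. Draws falling outside a
#' parameter's domain are rejected and redrawn (capped at 1000 rounds).
#'
#' @param params Base `cea_parameters`.
#' @param dists Distribution table from [default_psa_distributions()] (columns
#'   `path`, `family`, `rse`).
#' @param n_iter Number of Monte-Carlo iterations, default 5000.
#' @param seed Integer root seed.
#' @param wtp_grid Willingness-to-pay grid for the CEAC; default 0 to
#'   300,000 yuan in steps of 1,000.
#' @return A `psa_result` list: `samples` (data.frame `iteration`,
#'   `delta_cost`, `delta_qaly`, `icer`), `ceac` (data.frame `wtp`,
#'   `probability`), `n_iter`, `seed`.
#' @export
psa <- function(params, dists = default_psa_distributions(params),
                n_iter = 5000, seed = 1,
                wtp_grid = seq(0, 300000, by = 1000)) {
  stopifnot(n_iter >= 1)
  set.seed(seed)
  draws <- vector("list", nrow(dists))
  for (i in seq_len(nrow(dists))) {
    base <- param_get(params, dists$path[i])
    dom <- psa_domain(dists$family[i])
    d <- psa_draw(dists$family[i], base, dists$rse[i], n_iter)
    rounds <- 0L
    while (any(bad <- !(d >= dom[1] & d <= dom[2]))) {
      rounds <- rounds + 1L
      if (rounds > 1000L) {
        stop("PSA draws persistently outside domain for `", dists$path[i], "`",
             call. = FALSE)
      }
      d[bad] <- psa_draw(dists$family[i], base, dists$rse[i], sum(bad))
    }
    draws[[i]] <- d
  }
  dc <- numeric(n_iter)
  de <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    p <- params
    for (i in seq_len(nrow(dists))) {
      p <- param_set(p, dists$path[i], draws[[i]][it])
    }
    res <- run_cea(p)
    dc[it] <- res$delta_cost
    de[it] <- res$delta_qalys
  }
  samples <- data.frame(iteration = seq_len(n_iter), delta_cost = dc,
                        delta_qaly = de,
                        icer = ifelse(de == 0, NA_real_, dc / de))
  ceac <- data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(w) mean(w * de - dc > 0), numeric(1))
  )
  structure(list(samples = samples, ceac = ceac, n_iter = n_iter, seed = seed),
            class = "psa_result")
}

#' Probability cost-effective at given willingness-to-pay values
#' @param psa_result A `psa_result` from [psa()].
#' @param wtp Numeric vector of willingness-to-pay thresholds.
#' @return Probabilities (fractions of iterations with positive INB).
#' @export
ceac_at <- function(psa_result, wtp) {
  s <- psa_result$samples
  vapply(wtp, function(w) mean(w * s$delta_qaly - s$delta_cost > 0), numeric(1))
}

#' Quadrant counts of the incremental cost-effectiveness plane
#' @param psa_result A `psa_result`.
#' @return Named integer vector over the four quadrants (NE: costlier and
#'   more effective; SE: cheaper and more effective; SW; NW). Points on an
#'   axis count toward the adjacent positive side.
#' @export
ce_plane_quadrants <- function(psa_result) {
  s <- psa_result$samples
  c(NE = sum(s$delta_cost >= 0 & s$delta_qaly > 0),
    SE = sum(s$delta_cost < 0 & s$delta_qaly > 0),
    SW = sum(s$delta_cost < 0 & s$delta_qaly <= 0),
    NW = sum(s$delta_cost >= 0 & s$delta_qaly <= 0))
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %d)\n",
              x$n_iter, x$seed))
  q <- ce_plane_quadrants(x)
  cat("  CE-plane quadrants:", paste(names(q), q, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
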