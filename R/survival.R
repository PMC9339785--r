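#' Right-censored survival dataset
#'
#' Bundles event-or-censoring times (days) with event indicators into a
#' validated container used by the parametric fitting routines.
#'
#' @param times Numeric vector of strictly positive times in days.
#' @param events Integer/numeric vector of indicators, 1 = progression
#'   observed, 0 = right-censored. Must be the same length as `times`.
#' @return An object of class `survival_dataset` (a data.frame with columns
#'   `time_days` and `event`).
#' @examples
#' d <- survival_dataset(c(30, 120, 365), c(1, 1, 0))
#' nrow(d)
#' @export
survival_dataset <- function(times, events) {
  times <- as.numeric(times)
  events <- as.numeric(events)
  if (length(times) != length(events)) {
    stop("`times` and `events` must have equal length", call. = FALSE)
  }
  if (length(times) == 0L) stop("empty survival dataset", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all times must be finite and strictly positive", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) {
    stop("event indicators must be 0 or 1", call. = FALSE)
  }
  structure(
    data.frame(time_days = times, event = events),
    class = c("survival_dataset", "data.frame")
  )
}

#' Read a survival dataset from a delimited file
#'
#' Expects a headered table with columns `time_days` and `event`.
#'
#' @param path File path.
#' @param sep Field separator, default tab.
#' @return A [survival_dataset()].
#' @export
read_survival_data <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#")
  if (!all(c("time_days", "event") %in% names(tab))) {
    stop("survival file must have columns `time_days` and `event`", call. = FALSE)
  }
  survival_dataset(tab$time_days, tab$event)
}

surv_families <- c("exponential", "weibull", "loglogistic", "lognormal", "gompertz")

# Parameterizations (t in days):
#   exponential  S = exp(-lambda t)
#   weibull      S = exp(-lambda t^gamma)
#   loglogistic  S = 1 / (1 + lambda t^gamma)
#   lognormal    S = 1 - Phi((log t - mu) / sigma)   (shape slot = sigma, scale slot = mu)
#   gompertz     S = exp(-(lambda/gamma)(exp(gamma t) - 1)); gamma may be
#                negative, in which case S plateaus at exp(-lambda/|gamma|).
surv_n_params <- c(exponential = 1L, weibull = 2L, loglogistic = 2L,
                   lognormal = 2L, gompertz = 2L)

new_survival_fit <- function(family, shape, scale, log_likelihood, n) {
  n_params <- surv_n_params[[family]]
  structure(
    list(
      family = family,
      shape = shape,
      scale = scale,
      log_likelihood = log_likelihood,
      n_params = n_params,
      aic = 2 * n_params - 2 * log_likelihood,
      n = n
    ),
    class = "survival_fit"
  )
}

#' Construct a parametric survival model from known parameters
#'
#' Used to build survival functions directly from configuration (e.g. a
#' log-logistic curve with given shape and scale) without fitting.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`, `"gompertz"`.
#' @param shape Shape parameter (gamma; sigma for lognormal; ignored for
#'   exponential, where it is fixed at 1).
#' @param scale Scale parameter (lambda; mu for lognormal).
#' @return A `survival_fit` object with `log_likelihood = NA`.
#' @examples
#' f <- survival_model("loglogistic", shape = 1.3, scale = 1e-4)
#' survival_at(f, 365)
#' @export
survival_model <- function(family, shape = 1, scale) {
  family <- match.arg(family, surv_families)
  check_surv_params(family, shape, scale)
  new_survival_fit(family, shape, scale, NA_real_, NA_integer_)
}

check_surv_params <- function(family, shape, scale) {
  if (!is.finite(shape) || !is.finite(scale)) {
    stop("non-finite survival parameters", call. = FALSE)
  }
  if (family == "lognormal") {
    if (shape <= 0) stop("lognormal sigma must be > 0", call. = FALSE)
  } else if (family == "gompertz") {
    if (scale <= 0) stop("gompertz lambda must be > 0", call. = FALSE)
  } else {
    if (scale <= 0) stop("scale lambda must be > 0", call. = FALSE)
    if (shape <= 0) stop("shape gamma must be > 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Parametric survival fit:", x$family, "\n")
  cat(sprintf("  shape = %.6g, scale = %.6g\n", x$shape, x$scale))
  if (is.finite(x$log_likelihood)) {
    cat(sprintf("  logLik = %.4f, AIC = %.4f (k = %d, n = %d)\n",
                x$log_likelihood, x$aic, x$n_params, x$n))
  }
  invisible(x)
}

#' Survival probability S(t)
#'
#' Evaluates the survival function of a fitted or constructed parametric
#' model at times `t` (days). For the Gompertz family with negative shape the
#' survival function plateaus at `exp(-lambda/|gamma|)` rather than tending
#' to zero.
#'
#' @param fit A `survival_fit`.
#' @param t Numeric vector of times in days, all `>= 0`.
#' @return Survival probabilities in `[0, 1]`, same length as `t`.
#' @examples
#' survival_at(survival_model("loglogistic", 1, 1), 1)  # 0.5
#' @export
survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "survival_fit"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  g <- fit$shape
  l <- fit$scale
  s <- switch(fit$family,
    exponential = exp(-l * t),
    weibull = exp(-l * t^g),
    loglogistic = 1 / (1 + l * t^g),
    lognormal = ifelse(t == 0, 1, 1 - stats::pnorm((log(pmax(t, .Machine$double.xmin)) - l) / g)),
    gompertz = if (abs(g) < 1e-12) exp(-l * t) else exp(-(l / g) * (exp(g * t) - 1)),
    stop("unknown family: ", fit$family, call. = FALSE)
  )
  pmin(pmax(s, 0), 1)
}

# hazard h(t) on the same parameterizations; vectorized over t > 0
surv_hazard <- function(family, shape, scale, t) {
  g <- shape
  l <- scale
  switch(family,
    exponential = rep(l, length(t)),
    weibull = l * g * t^(g - 1),
    loglogistic = l * g * t^(g - 1) / (1 + l * t^g),
    lognormal = {
      z <- (log(t) - l) / g
      stats::dnorm(z) / (g * t * pmax(stats::pnorm(z, lower.tail = FALSE), .Machine$double.xmin))
    },
    gompertz = l * exp(g * t)
  )
}

# log S(t), numerically careful
surv_logsurv <- function(family, shape, scale, t) {
  g <- shape
  l <- scale
  switch(family,
    exponential = -l * t,
    weibull = -l * t^g,
    loglogistic = -log1p(l * t^g),
    lognormal = stats::pnorm((log(t) - l) / g, lower.tail = FALSE, log.p = TRUE),
    gompertz = if (abs(g) < 1e-12) -l * t else -(l / g) * expm1(g * t)
  )
}

# right-censored log-likelihood: sum(d * log h) + sum(log S)
surv_loglik <- function(family, shape, scale, times, events) {
  lh <- log(pmax(surv_hazard(family, shape, scale, times), .Machine$double.xmin))
  ll <- sum(events * lh) + sum(surv_logsurv(family, shape, scale, times))
  if (!is.finite(ll)) -Inf else ll
}

# transform between optimizer scale (unconstrained) and natural parameters
surv_to_natural <- function(family, par) {
  switch(family,
    exponential = c(shape = 1, scale = exp(par[1])),
    lognormal = c(shape = exp(par[2]), scale = par[1]),        # sigma, mu
    gompertz = c(shape = par[2], scale = exp(par[1])),         # gamma free sign
    c(shape = exp(par[2]), scale = exp(par[1]))
  )
}

surv_start_values <- function(family, times, events) {
  d <- sum(events)
  rate0 <- d / sum(times)
  m <- stats::median(times[events == 1])
  if (!is.finite(m) || m <= 0) m <- stats::median(times)
  lt <- log(times)
  switch(family,
    exponential = list(log(rate0)),
    weibull = lapply(c(0.8, 1, 1.5), function(g0) c(log(log(2) / m^g0), log(g0))),
    loglogistic = lapply(c(0.8, 1.2, 1.8), function(g0) c(log(1 / m^g0), log(g0))),
    lognormal = lapply(c(0.5, 1, 2), function(f) c(mean(lt), log(max(stats::sd(lt), 0.1) * f))),
    gompertz = lapply(c(-5e-4, 1e-6, 5e-4), function(g0) c(log(rate0), g0))
  )
}

#' Fit a parametric survival model by maximum likelihood
#'
#' Maximizes the right-censored log-likelihood
#' \eqn{\sum_i d_i \log h(t_i) + \sum_i \log S(t_i)} by numerical
#' optimization on log-transformed parameters, with three starting points to
#' guard against local optima (the exponential rate has the closed form
#' events / total follow-up and is computed directly).
#'
#' @param data A [survival_dataset()].
#' @param family One of the five supported families.
#' @return A `survival_fit` with `log_likelihood` and `aic` populated.
#' @examples
#' set.seed(1)
#' d <- survival_dataset(rexp(200, 0.01), rep(1, 200))
#' fit_parametric(d, "exponential")$scale  # ~ 0.01
#' @export
fit_parametric <- function(data, family) {
  stopifnot(inherits(data, "survival_dataset"))
  family <- match.arg(family, surv_families)
  times <- data$time_days
  events <- data$event
  if (sum(events) < 1) {
    stop("cannot fit: dataset contains no observed events", call. = FALSE)
  }

  if (family == "exponential") {
    # closed-form MLE under right censoring
    rate <- sum(events) / sum(times)
    ll <- surv_loglik("exponential", 1, rate, times, events)
    return(new_survival_fit("exponential", 1, rate, ll, length(times)))
  }

  nll <- function(par) {
    nat <- surv_to_natural(family, par)
    -surv_loglik(family, nat[["shape"]], nat[["scale"]], times, events)
  }
  best <- NULL
  for (start in surv_start_values(family, times, events)) {
    opt <- tryCatch(
      stats::optim(start, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("optimizer failed to converge for family `", family, "`", call. = FALSE)
  }
  if (best$convergence != 0) {
    stop("optimizer did not converge for family `", family,
         "` (code ", best$convergence, ")", call. = FALSE)
  }
  nat <- surv_to_natural(family, best$par)
  new_survival_fit(family, nat[["shape"]], nat[["scale"]], -best$value, length(times))
}

#' Fit all five parametric families to one dataset
#'
#' @param data A [survival_dataset()].
#' @param families Character vector of families to fit; defaults to all five.
#' @return A named list of `survival_fit` objects (families whose optimizer
#'   fails are dropped with a warning).
#' @export
fit_all_families <- function(data, families = surv_families) {
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fit_parametric(data, fam), error = function(e) {
      warning("family `", fam, "` failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (length(fits) == 0L) stop("no family could be fitted", call. = FALSE)
  fits
}

#' Select the best fit by AIC
#'
#' Returns the fit with minimal AIC. Ties go to the fit with fewest
#' parameters, then to a fixed family order (exponential, weibull,
#' loglogistic, lognormal, gompertz).
#'
#' @param fits A non-empty list of `survival_fit` objects fitted on the same
#'   dataset.
#' @return The selected `survival_fit`.
#' @export
select_best <- function(fits) {
  if (length(fits) == 0L) stop("empty list of fits", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "survival_fit")))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "n_params")
  fam <- vapply(fits, `[[`, character(1), "family")
  ord <- order(aic, k, match(fam, surv_families))
  fits[[ord[1L]]]
}

#' Tabulate a set of fits as a fit report
#'
#' @param fits List of `survival_fit` objects.
#' @return A data.frame with columns `family`, `params` (name=value;...),
#'   `loglik`, `aic`, `selected` (0/1 flag for the AIC winner).
#' @export
fit_report <- function(fits) {
  best <- select_best(fits)
  do.call(rbind, lapply(fits, function(f) {
    pn <- if (f$family == "lognormal") c("mu", "sigma") else c("lambda", "gamma")
    params <- sprintf("%s=%.8g;%s=%.8g", pn[1], f$scale, pn[2], f$shape)
    if (f$family == "exponential") params <- sprintf("lambda=%.8g", f$scale)
    data.frame(family = f$family, params = params, loglik = f$log_likelihood,
               aic = f$aic, selected = as.integer(identical(f$family, best$family)))
  }))
}

#' Apply a proportional-hazards ratio to a survival curve
#'
#' Scales the cumulative hazard, i.e. `S_hr(t) = S(t)^hr`; `hr = 1` is the
#' identity and composing two ratios multiplies them.
#'
#' @param fit A `survival_fit`.
#' @param hr Hazard ratio, `> 0`.
#' @return A function of `t` returning the adjusted survival probability.
#' @examples
#' s2 <- apply_hazard_ratio(survival_model("loglogistic", 1, 1), 2)
#' s2(1)  # 0.25
#' @export
apply_hazard_ratio <- function(fit, hr) {
  hr <- if (is.list(hr)) hr$value else hr
  if (!is.finite(hr) || hr <= 0) stop("hazard ratio must be > 0", call. = FALSE)
  force(fit)
  function(t) survival_at(fit, t)^hr
}

#' Per-cycle progression probability from a survival curve
#'
#' Converts a survival function into the conditional probability of
#' progressing during cycle `i`:
#' `p_i = 1 - S((i+1) c) / S(i c)`, so that the product of `(1 - p_i)` over
#' cycles telescopes back to the survival curve.
#'
#' @param surv A survival function of time in days (e.g. from
#'   [apply_hazard_ratio()] or `function(t) survival_at(fit, t)`).
#' @param cycle_index Non-negative integer cycle index (vectorized).
#' @param cycle_length Cycle length in days, `> 0`.
#' @return Probabilities in `[0, 1]`.
#' @export
per_cycle_progression_prob <- function(surv, cycle_index, cycle_length) {
  if (any(cycle_index < 0) || any(cycle_index != floor(cycle_index))) {
    stop("cycle_index must be a non-negative integer", call. = FALSE)
  }
  if (cycle_length <= 0) stop("cycle_length must be > 0", call. = FALSE)
  s0 <- surv(cycle_index * cycle_length)
  s1 <- surv((cycle_index + 1) * cycle_length)
  if (any(s0 <= 0)) {
    stop("survival at cycle start is zero: cohort already fully progressed",
         call. = FALSE)
  }
  pmin(pmax(1 - s1 / s0, 0), 1)
}
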