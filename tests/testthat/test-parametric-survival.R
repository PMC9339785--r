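test_that("survival functions obey their closed forms and boundary behaviour", {
  ll <- survival_model("loglogistic", shape = 1, scale = 1)
  expect_equal(survival_at(ll, 1), 0.5)
  ex <- survival_model("exponential", scale = 0.01)
  expect_equal(survival_at(ex, 100), exp(-1))
  for (fit in list(
    ll, ex,
    survival_model("weibull", 1.5, 0.005),
    survival_model("lognormal", shape = 0.8, scale = 5),
    survival_model("gompertz", 0.001, 1e-4)
  )) {
    expect_equal(survival_at(fit, 0), 1)
    t <- seq(0, 5000, by = 50)
    s <- survival_at(fit, t)
    expect_true(all(diff(s) <= 1e-12), info = fit$family)
    expect_true(all(s >= 0 & s <= 1))
  }
  # negative-shape Gompertz plateaus at exp(-lambda/|gamma|)
  gz <- survival_model("gompertz", -0.002, 1e-4)
  expect_equal(survival_at(gz, 1e7), exp(-1e-4 / 0.002), tolerance = 1e-10)
  expect_error(survival_at(ll, -1), "finite")
  expect_error(survival_model("loglogistic", shape = 1, scale = -1))
})

test_that("exponential MLE matches events / exposure exactly", {
  set.seed(7)
  for (cens_frac in c(0, 0.3)) {
    t <- rexp(500, rate = 0.004)
    ev <- as.numeric(runif(500) >= cens_frac)
    d <- survival_dataset(t, ev)
    fit <- fit_parametric(d, "exponential")
    expect_equal(fit$scale, sum(ev) / sum(t), tolerance = 1e-8)
    expect_equal(fit$aic, 2 * 1 - 2 * fit$log_likelihood)
  }
})

test_that("log-logistic parameters are recovered from censored synthetic data", {
  # ~20% right-censoring: administrative cut at the 80th percentile of the
  # curve; the scale estimate is noisy seed-by-seed (it is strongly correlated
  # with the shape), so the recovery claim is on the median over seeds
  t80 <- pcacea:::surv_quantile(survival_model("loglogistic", 1.5, 0.005), 0.2)
  errs <- t(vapply(1:5, function(s) {
    d <- loglogistic_sample(2000, lambda = 0.005, gamma = 1.5, t_max = t80,
                            seed = s)
    fit <- fit_parametric(d, "loglogistic")
    c(cens = 1 - mean(d$event),
      lam = abs(fit$scale - 0.005) / 0.005,
      gam = abs(fit$shape - 1.5) / 1.5)
  }, numeric(3)))
  expect_equal(mean(errs[, "cens"]), 0.2, tolerance = 0.05)
  expect_lt(median(errs[, "lam"]), 0.10)
  expect_lt(median(errs[, "gam"]), 0.10)
})

test_that("fitted log-likelihood at the MLE dominates the generating parameters", {
  lls <- vapply(1:5, function(s) {
    d <- loglogistic_sample(500, lambda = 0.005, gamma = 1.5, seed = s)
    fit <- fit_parametric(d, "loglogistic")
    fit$log_likelihood -
      pcacea:::surv_loglik("loglogistic", 1.5, 0.005, d$time_days, d$event)
  }, numeric(1))
  expect_true(all(lls > -1e-6))
  expect_gt(mean(lls), 0)
})

test_that("maximum-likelihood fits agree with an independent implementation", {
  skip_if_not_installed("flexsurv")
  d <- loglogistic_sample(800, lambda = 0.003, gamma = 1.4, seed = 11)
  fs <- flexsurv::flexsurvreg(survival::Surv(time_days, event) ~ 1,
                              data = d, dist = "llogis")
  fit <- fit_parametric(d, "loglogistic")
  # flexsurv: S = 1/(1 + (t/scale)^shape)  =>  lambda = scale^-shape
  fs_shape <- fs$res["shape", "est"]
  fs_scale <- fs$res["scale", "est"]
  expect_equal(fit$shape, fs_shape, tolerance = 1e-3)
  expect_equal(fit$scale, fs_scale^(-fs_shape), tolerance = 1e-3)
  expect_equal(fit$log_likelihood, fs$loglik, tolerance = 1e-6)

  fsw <- flexsurv::flexsurvreg(survival::Surv(time_days, event) ~ 1,
                               data = d, dist = "weibull")
  fitw <- fit_parametric(d, "weibull")
  expect_equal(fitw$log_likelihood, fsw$loglik, tolerance = 1e-6)
})

test_that("degenerate fitting inputs are rejected", {
  expect_error(survival_dataset(c(1, -2), c(1, 1)), "positive")
  expect_error(survival_dataset(1:3, c(1, 2, 1)), "0 or 1")
  d <- survival_dataset(c(10, 20, 30), c(0, 0, 0))
  expect_error(fit_parametric(d, "loglogistic"), "no observed events")
})

test_that("AIC selection takes the minimum with documented tie-breaks", {
  mk <- function(fam, aic) {
    f <- survival_model(fam, shape = 1, scale = 0.01)
    f$log_likelihood <- (2 * f$n_params - aic) / 2
    f$aic <- aic
    f
  }
  fits <- list(mk("weibull", 310.2), mk("loglogistic", 305.1), mk("exponential", 320.0))
  expect_equal(select_best(fits)$family, "loglogistic")
  # tie: fewer parameters wins
  tie <- list(mk("weibull", 300), mk("exponential", 300))
  expect_equal(select_best(tie)$family, "exponential")
  # tie at equal parameter count: fixed family order
  tie2 <- list(mk("lognormal", 300), mk("weibull", 300))
  expect_equal(select_best(tie2)$family, "weibull")
  expect_error(select_best(list()), "empty")
})

test_that("AIC recovers the generating family on a large log-logistic sample", {
  d <- loglogistic_sample(5000, lambda = 0.005, gamma = 1.5, seed = 99)
  fits <- fit_all_families(d)
  expect_equal(select_best(fits)$family, "loglogistic")
  rep <- fit_report(fits)
  expect_equal(sum(rep$selected), 1L)
  expect_equal(rep$family[rep$selected == 1], "loglogistic")
})

test_that("hazard ratios act on the cumulative-hazard scale", {
  ll <- survival_model("loglogistic", 1, 1)
  t <- c(0, 0.5, 1, 2, 10)
  expect_equal(apply_hazard_ratio(ll, 1)(t), survival_at(ll, t))
  expect_equal(apply_hazard_ratio(ll, 2)(1), 0.25)
  # exponential: hr folds into the rate
  ex1 <- survival_model("exponential", scale = 0.01)
  ex2 <- survival_model("exponential", scale = 0.02)
  expect_equal(apply_hazard_ratio(ex1, 2)(t), survival_at(ex2, t))
  # composition multiplies
  s_ab <- function(t) apply_hazard_ratio(ll, 1.7)(t)^1.3
  expect_equal(s_ab(t), apply_hazard_ratio(ll, 1.7 * 1.3)(t))
  expect_error(apply_hazard_ratio(ll, 0), "> 0")
})

test_that("per-cycle progression probabilities telescope back to the curve", {
  # memorylessness: exponential gives a constant per-cycle probability
  ex <- survival_model("exponential", scale = 0.002)
  s_ex <- function(t) survival_at(ex, t)
  p <- per_cycle_progression_prob(s_ex, 0:50, 28)
  expect_equal(p, rep(1 - exp(-0.002 * 28), 51))

  ll <- survival_model("loglogistic", 1, 1)
  expect_equal(per_cycle_progression_prob(function(t) survival_at(ll, t), 0, 1), 0.5)

  # telescoping identity over random parameters
  set.seed(5)
  for (rep in 1:10) {
    lam <- runif(1, 1e-5, 1e-2)
    gam <- runif(1, 0.7, 2)
    fit <- survival_model("loglogistic", gam, lam)
    s <- function(t) survival_at(fit, t)
    k <- 391
    p <- per_cycle_progression_prob(s, 0:(k - 1), 28)
    expect_equal(prod(1 - p), s(k * 28), tolerance = 1e-10)
  }
  expect_error(per_cycle_progression_prob(s_ex, -1, 28), "non-negative")
})
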