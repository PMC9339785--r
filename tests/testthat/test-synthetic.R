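test_that("inverse-CDF sampling hits the closed-form median", {
  # for S = 1/(1 + lambda t^gamma) with lambda = gamma = 1, U = 0.5 gives T = 1
  fit <- survival_model("loglogistic", 1, 1)
  expect_equal(pcacea:::surv_quantile(fit, 0.5), 1)
  # quantile inverts the survival function on every family
  for (fam in list(c("exponential", 1, 0.01), c("weibull", 1.5, 0.005),
                   c("loglogistic", 1.3, 1e-4), c("lognormal", 0.8, 6),
                   c("gompertz", 0.001, 1e-4))) {
    f <- survival_model(fam[1], as.numeric(fam[2]), as.numeric(fam[3]))
    s <- c(0.9, 0.5, 0.1)
    expect_equal(survival_at(f, pcacea:::surv_quantile(f, s)), s,
                 tolerance = 1e-9, info = fam[1])
  }
})

test_that("empirical survival of uncensored draws stays inside the DKW band", {
  n <- 10000
  d <- gen_survival(n, "loglogistic", lambda = 0.005, gamma = 1.5,
                    t_max = Inf, seed = 31)$reference
  expect_true(all(d$event == 1))
  eps <- sqrt(log(2 / 0.01) / (2 * n))  # alpha = 0.01
  fit <- survival_model("loglogistic", 1.5, 0.005)
  for (t in c(10, 50, 100, 250, 500)) {
    emp <- mean(d$time_days > t)
    expect_lt(abs(emp - survival_at(fit, t)), eps)
  }
})

test_that("administrative censoring and dropout behave as specified", {
  d <- gen_survival(2000, lambda = 0.005, gamma = 1.5, t_max = 364,
                    dropout = 0.1, seed = 5)
  for (arm in d) {
    expect_true(all(arm$time_days <= 364))
    expect_true(any(arm$event == 0))
    # all times at the administrative boundary are censored
    expect_true(all(arm$event[arm$time_days == 364] == 0))
  }
})

test_that("a null hazard ratio leaves the two arms exchangeable", {
  skip_if_not_installed("survival")
  pvals <- vapply(1:3, function(s) {
    d <- gen_survival(800, lambda = 0.005, gamma = 1.5, hr = 1, seed = s)
    df <- rbind(cbind(d$reference, arm = 0), cbind(d$treated, arm = 1))
    survival::survdiff(survival::Surv(time_days, event) ~ arm, data = df)$pvalue
  }, numeric(1))
  expect_gt(max(pvals), 0.05)        # not systematically separated
  expect_true(all(pvals > 1e-4))
})

test_that("a protective hazard ratio lengthens treated-arm survival", {
  d <- gen_survival(5000, lambda = 0.005, gamma = 1.5, hr = 0.5,
                    t_max = Inf, seed = 9)
  expect_gt(median(d$treated$time_days), median(d$reference$time_days))
})

test_that("generators are bit-reproducible given the seed", {
  a <- gen_survival(100, lambda = 0.005, gamma = 1.5, seed = 77)
  b <- gen_survival(100, lambda = 0.005, gamma = 1.5, seed = 77)
  expect_identical(a, b)
  c <- gen_survival(100, lambda = 0.005, gamma = 1.5, seed = 78)
  expect_false(identical(a$reference$time_days, c$reference$time_days))
})

test_that("the logistic life-table generator evaluates the curve exactly", {
  lt <- gen_life_table(0.7, 0.09, 97, age_range = 40:100)
  expect_equal(lt$qx[lt$age == 97], 0.35)  # L / 2 at the midpoint
  # near-flat limit
  flat <- gen_life_table(0.5, 1e-9, 70, age_range = 60:80)
  expect_true(all(abs(flat$qx - 0.25) < 1e-6))
  # round-trip through the logistic fit
  fit <- fit_logistic_mortality(lt)
  expect_lt(abs(fit$L - 0.7) / 0.7, 0.01)
  expect_lt(abs(fit$k - 0.09) / 0.09, 0.01)
  expect_lt(abs(fit$a0 - 97) / 97, 0.01)
})

test_that("the fixture carries the published values verbatim", {
  p <- gen_fixture()
  expect_silent(validate_parameters(p))
  expect_equal(param_get(p, "settings.cycle_length_days"), 28)
  expect_equal(param_get(p, "settings.horizon_years"), 30)
  expect_equal(param_get(p, "settings.start_age"), 68)
  expect_equal(param_get(p, "settings.discount_cost"), 0.05)
  expect_equal(param_get(p, "transitions.response_aa_addition"), 0.83)
  expect_equal(param_get(p, "transitions.response_aa_withdrawal"), 0.83)
  expect_equal(param_get(p, "transitions.response_docetaxel"), 0.91)
  expect_equal(param_get(p, "transitions.response_abiraterone"), 0.84)
  expect_equal(param_get(p, "transitions.chemo_skip_fraction"), 0.35)
  expect_equal(param_get(p, "prices.degarelix_first_cycle"), 8900)
  expect_equal(param_get(p, "prices.degarelix_maintenance"), 3200)
  expect_equal(param_get(p, "prices.leuprorelin_per_cycle"), 1389.29)
  expect_equal(param_get(p, "prices.flare_cover_daily"), 169.37)
  expect_equal(param_get(p, "costs.supportive_care_cycle"), 7500.92)
  expect_equal(param_get(p, "costs.palliative_care_cycle"), 5804.82)
  expect_equal(param_get(p, "costs.post_abiraterone_cycle"), 25200)
  expect_equal(param_get(p, "utilities.first_line"), 0.90)
  expect_equal(param_get(p, "utilities.aa_addition"), 0.80)
  expect_equal(param_get(p, "utilities.docetaxel"), 0.69)
  expect_equal(param_get(p, "utilities.supportive_care"), 0.40)
  expect_equal(param_get(p, "mortality.hr_post_progression"), 2.39)
  expect_equal(param_get(p, "ae.costs.cv_fatal"), 28723.96)
  expect_equal(param_get(p, "ae.disutility.cardiovascular"), -0.73)
  expect_equal(param_get(p, "economics.gdp_per_capita"), 80976)
  # the per-cycle comparator price is the mean of its component prices
  expect_equal(mean_price(param_get(p, "prices.leuprorelin_components")),
               param_get(p, "prices.leuprorelin_per_cycle"))
})

test_that("provenance separates published from synthetic fields", {
  p <- gen_fixture()
  prov <- parameter_provenance(p)
  expect_setequal(unique(prov$source), c("printed", "synthetic"))
  get_src <- function(path) prov$source[prov$path == path]
  expect_equal(get_src("utilities.first_line"), "printed")
  expect_equal(get_src("costs.supportive_care_cycle"), "printed")
  expect_equal(get_src("survival.lambda"), "synthetic")
  expect_equal(get_src("survival.hr_psa_recurrence"), "synthetic")
  expect_equal(get_src("ae.incidence.degarelix.cardiovascular"), "synthetic")
  # every leaf is tagged
  expect_setequal(prov$path, param_paths(p))
  # the seed annotates metadata only; values are constants
  expect_identical(unclass(gen_fixture(1))[-1], unclass(gen_fixture(99))[-1])
})

test_that("AIC family recovery holds across seeds at n = 5000", {
  hits <- vapply(1:20, function(s) {
    d <- gen_survival(5000, "loglogistic", lambda = 0.005, gamma = 1.5,
                      t_max = 364, seed = 1000 + s)$reference
    fits <- fit_all_families(d)
    identical(select_best(fits)$family, "loglogistic")
  }, logical(1))
  expect_gte(sum(hits), 18)
})
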