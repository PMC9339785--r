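test_that("one-way analysis ranks parameters by ICER range with exact zero for unread ones", {
  p <- short_params()
  pert <- data.frame(
    path = c("prices.degarelix_maintenance",
             "prices.enzalutamide_daily",   # priced but never charged by the model
             "prices.leuprorelin_per_cycle"),
    low = c(0.8 * 3200, 0.8 * 216.67, 0.8 * 1389.29),
    high = c(1.2 * 3200, 1.2 * 216.67, 1.2 * 1389.29),
    class = "cost"
  )
  tor <- one_way(p, pert)
  base_icer <- attr(tor, "base_icer")
  unread <- tor[tor$path == "prices.enzalutamide_daily", ]
  expect_equal(unread$icer_low, base_icer)
  expect_equal(unread$icer_high, base_icer)
  expect_equal(unread$range, 0)
  # intervention price: higher price, higher ICER
  dg <- tor[tor$path == "prices.degarelix_maintenance", ]
  expect_lt(dg$icer_low, base_icer)
  expect_gt(dg$icer_high, base_icer)
  expect_true(all(diff(tor$range) <= 0))  # sorted descending
  expect_error(one_way(p, data.frame(path = "no.such.leaf", low = 1, high = 2)),
               "not found")
})

test_that("one-way output is invariant to input order and duplicates rows verbatim", {
  p <- short_params()
  pert <- default_perturbations(p)[c(1, 3, 11), ]
  tor_a <- one_way(p, pert)
  tor_b <- one_way(p, pert[c(3, 1, 2), ])
  expect_equal(tor_a[order(tor_a$path), ], tor_b[order(tor_b$path), ],
               ignore_attr = TRUE)
  dup <- one_way(p, pert[c(1, 1), ])
  expect_equal(dup[1, -1], dup[2, -1], ignore_attr = TRUE)
})

test_that("scenario runs are pure and respond in the expected direction", {
  p <- short_params()
  base <- run_cea(p)
  same <- scenario_run(p, list())
  expect_equal(same$icer, base$icer)
  expect_equal(same$delta_cost, base$delta_cost)

  doubled <- scenario_run(p, list(prices.leuprorelin_per_cycle = 2 * 1389.29))
  expect_gt(doubled$arm_b$cost, base$arm_b$cost)
  expect_equal(doubled$arm_a$cost, base$arm_a$cost)  # intervention arm untouched
  expect_equal(p$prices$leuprorelin_per_cycle, 1389.29)  # base unchanged

  long <- gen_fixture()
  short <- scenario_run(long, list(settings.horizon_years = 10))
  full <- run_cea(long)
  expect_lt(short$arm_a$cost, full$arm_a$cost)
  expect_lt(short$arm_b$cost, full$arm_b$cost)
  expect_lt(short$arm_a$qalys, full$arm_a$qalys)
  expect_lt(short$arm_b$qalys, full$arm_b$qalys)
})

test_that("threshold search returns the base price when targeting the base ICER", {
  p <- short_params()
  base <- run_cea(p)
  thr <- threshold_price(p, "prices.degarelix_maintenance", base$icer,
                         tol_icer = 0.01, tol_price = 1e-4)
  expect_equal(thr$price, p$prices$degarelix_maintenance, tolerance = 1e-3)
  expect_equal(thr$pct_change, 0, tolerance = 1e-3)
})

test_that("threshold bisection matches the algebraic solution of a toy model", {
  # two-cycle toy: ICER is affine in the maintenance price, solvable by hand
  p <- short_params()
  base <- run_cea(p)
  tr <- attr(base, "traces")$degarelix
  # discounted degarelix first-line occupancy from maintenance cycles (>= 1)
  n <- nrow(tr$occupancy) - 1
  df <- discount_factor(p$settings$discount_cost, 1:(n - 1), 28)
  exposure <- sum(tr$occupancy[2:n, "first_line"] * df)
  target <- 80976
  # ICER(price) = [dC0 + (price - 3200) * exposure] / dE
  price_star <- 3200 + (target * base$delta_qalys - base$delta_cost) / exposure
  thr <- threshold_price(p, "prices.degarelix_maintenance", target,
                         tol_icer = 1e-6, tol_price = 1e-6)
  expect_equal(thr$price, price_star, tolerance = 0.01)
  expect_error(threshold_price(p, "prices.degarelix_maintenance", -1e9),
               "not bracketed")
})

test_that("percent decrease to the published threshold price reproduces 7.23%", {
  expect_equal(round(100 * (3200 - 2968.59) / 3200, 2), 7.23)
})

test_that("degenerate distributions collapse the PSA to the deterministic result", {
  p <- short_params()
  det <- run_cea(p)
  dists <- default_psa_distributions(p, rse = 0)
  ps <- psa(p, dists, n_iter = 20, seed = 3, wtp_grid = seq(0, 3e5, 5e4))
  expect_true(all(ps$samples$delta_cost == det$delta_cost))
  expect_true(all(ps$samples$delta_qaly == det$delta_qalys))
  # CEAC is a step function jumping 0 -> 1 at the base ICER
  expect_equal(ps$ceac$probability,
               as.numeric(ps$ceac$wtp > det$icer))
})

test_that("PSA summaries satisfy their defining identities", {
  p <- short_params()
  ps <- psa(p, n_iter = 60, seed = 7, wtp_grid = seq(0, 3e5, 5e4))
  s <- ps$samples
  expect_equal(nrow(s), 60)
  expect_equal(ceac_at(ps, 0), mean(s$delta_cost < 0))
  expect_true(all(ps$ceac$probability >= 0 & ps$ceac$probability <= 1))
  expect_equal(ceac_at(ps, 1e12), mean(s$delta_qaly > 0))
  expect_equal(sum(ce_plane_quadrants(ps)), 60)
  # deterministic given the seed
  ps2 <- psa(p, n_iter = 60, seed = 7, wtp_grid = seq(0, 3e5, 5e4))
  expect_identical(ps$samples, ps2$samples)
  ps3 <- psa(p, n_iter = 60, seed = 8, wtp_grid = seq(0, 3e5, 5e4))
  expect_false(identical(ps$samples$delta_cost, ps3$samples$delta_cost))
})

test_that("parameter-major draws keep earlier draws stable when a parameter is added", {
  p <- short_params()
  dists <- default_psa_distributions(p)
  short <- dists[1:5, ]
  longer <- dists[1:6, ]
  draw_first5 <- function(d) {
    set.seed(11)
    lapply(seq_len(nrow(d)), function(i) {
      pcacea:::psa_draw(d$family[i], param_get(p, d$path[i]), d$rse[i], 50)
    })[1:5]
  }
  expect_identical(draw_first5(short), draw_first5(longer))
})

test_that("beta draws respect the unit interval even for extreme utilities", {
  # a 20% RSE near the boundary is capped at the feasible beta variance;
  # utilities live in the closed interval, so boundary draws are in-domain
  d <- pcacea:::psa_draw("beta", 0.97, 0.2, 5000)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(mean(d), 0.97, tolerance = 0.05)
  g <- pcacea:::psa_draw("gamma", 3200, 0.2, 5000)
  expect_true(all(g > 0))
  expect_equal(mean(g), 3200, tolerance = 0.05)
  ln <- pcacea:::psa_draw("lognormal", 2.39, 0.2, 5000)
  expect_equal(mean(ln), 2.39, tolerance = 0.05)
})
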