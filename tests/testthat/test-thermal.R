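test_that("curve evaluation matches hand computation", {
  # symmetric case: peak at z, zeros at z +/- w/2
  expect_equal(tpc_value(10, a = 0.5, b = 0, z = 10, w = 20), 0.5)
  expect_equal(tpc_value(0, a = 0.5, b = 0, z = 10, w = 20), 0)
  expect_equal(tpc_value(20, a = 0.5, b = 0, z = 10, w = 20), 0)
  # hand evaluation with temperature sensitivity
  expect_equal(tpc_value(12, a = 0.5, b = 0.05, z = 10, w = 20),
               0.5 * exp(0.6) * (1 - 0.04), tolerance = 1e-10)
  # negative beyond the viable window
  expect_lt(tpc_value(25, a = 0.5, b = 0, z = 10, w = 20), 0)
  expect_error(tpc_value(10, a = -1, b = 0, z = 10, w = 20), "positive")
  expect_error(tpc_value(10, a = 1, b = 0, z = 10, w = 0), "positive")
})

test_that("derived traits of the symmetric curve match the closed form", {
  d <- derive_params(list(a = 0.5, b = 0, z = 10, w = 20), c(-5, 25))
  expect_equal(d$t_opt, 10, tolerance = 1e-6)
  expect_equal(d$mu_max, 0.5, tolerance = 1e-9)
  # mu = 0.8 mu_max at z +/- (w/2) sqrt(0.2): breadth 2 * 10 * sqrt(0.2)
  expect_equal(d$tb80, 2 * 10 * sqrt(0.2), tolerance = 1e-6)
  expect_false(d$tb80_clipped)
})

test_that("the 80% level is attained exactly at the breadth bounds", {
  for (p in list(list(a = 0.5, b = 0.05, z = 10, w = 20),
                 list(a = 1.2, b = 0.1, z = 15, w = 12),
                 list(a = 0.3, b = -0.02, z = 5, w = 30))) {
    d <- derive_params(p, c(p$z - p$w, p$z + p$w))
    mu_at <- tpc_value(d$tb80_bounds, p$a, p$b, p$z, p$w)
    expect_lt(max(abs(mu_at - 0.8 * d$mu_max)), 1e-6)
  }
})

test_that("breadth shrinks as the threshold fraction rises", {
  p <- list(a = 0.5, b = 0.07, z = 12, w = 18)
  th <- c(0.8, 0.85, 0.9, 0.95, 0.99)
  br <- vapply(th, function(f)
    derive_params(p, c(0, 24), threshold = f)$tb80, numeric(1))
  expect_true(all(diff(br) < 0))
})

test_that("numeric optimum matches the analytic root on random parameter draws", {
  set.seed(11)
  for (i in 1:100) {
    a <- runif(1, 0.1, 2); b <- runif(1, -0.1, 0.15)
    z <- runif(1, 0, 25); w <- runif(1, 5, 40)
    truth <- analytic_topt(a, b, z, w)
    d <- derive_params(list(a = a, b = b, z = z, w = w),
                       c(z - w / 2, z + w / 2))
    expect_lt(abs(d$t_opt - truth), 1e-4)
  }
})

test_that("breadth bounds clip to the tested range and are flagged", {
  # tested range ends right of the peak: upper 80% crossing lies outside
  d <- derive_params(list(a = 0.5, b = 0, z = 10, w = 20), c(5, 11))
  expect_true(d$tb80_clipped)
  expect_equal(d$tb80_bounds[2], 11)
})

test_that("activation energy is recovered exactly from Arrhenius data", {
  k_b <- 8.617e-5
  temps <- seq(0, 10, by = 1)
  rate <- 3e10 * exp(-0.65 / (k_b * (temps + 273.15)))
  expect_equal(arrhenius_ea(temps, rate), 0.65, tolerance = 0.01 / 0.65)
  expect_warning(ea <- arrhenius_ea(5, 0.5), "fewer than 2")
  expect_true(is.na(ea))
})

test_that("noiseless rates are fit back to four significant digits", {
  truth <- list(a = 0.5, b = 0.05, z = 10, w = 20)
  rates <- simulate_tpc_experiment(truth, seq(-2, 20, length.out = 8),
                                   replicates = 1, noise_sd = 0)
  fit <- fit_tpc(rates)
  for (p in names(truth))
    expect_equal(unname(fit$params[p]), truth[[p]], tolerance = 1e-4)
})

test_that("degenerate flat rate tables are rejected as unidentifiable", {
  flat <- data.frame(temperature = seq(0, 20, length.out = 6), rate = 0.4)
  expect_error(fit_tpc(flat), "unidentifiable")
  expect_error(fit_tpc(data.frame(temperature = c(1, 2, 3, 4),
                                  rate = c(0.1, 0.2, 0.2, 0.1))),
               "5 distinct")
})

test_that("the fit is invariant to row order and table duplication", {
  truth <- list(a = 0.5, b = 0.05, z = 10, w = 20)
  rates <- simulate_tpc_experiment(truth, seq(-2, 20, length.out = 8),
                                   replicates = 3, noise_sd = 0.03, seed = 5)
  f1 <- fit_tpc(rates)
  f2 <- fit_tpc(rates[sample.int(nrow(rates)), ])
  f3 <- fit_tpc(rbind(rates, rates))
  expect_equal(f1$params, f2$params, tolerance = 1e-8)
  expect_equal(f1$params, f3$params, tolerance = 1e-6)
})

test_that("noiseless bootstrap intervals are tight and contain the point estimate", {
  truth <- list(a = 0.5, b = 0.05, z = 10, w = 20)
  rates <- simulate_tpc_experiment(truth, seq(-2, 20, length.out = 8),
                                   replicates = 2, noise_sd = 0)
  bt <- bootstrap_tpc(rates, n_boot = 200, seed = 1)
  for (p in c("t_opt", "mu_max", "tb80")) {
    expect_lt(bt$ci[p, "high"] - bt$ci[p, "low"], 1e-3)
    pt <- switch(p, t_opt = bt$point$derived$t_opt,
                 mu_max = bt$point$derived$mu_max,
                 tb80 = bt$point$derived$tb80)
    expect_gte(pt, bt$ci[p, "low"] - 1e-9)
    expect_lte(pt, bt$ci[p, "high"] + 1e-9)
  }
})

test_that("bootstrap intervals are reproducible under a fixed seed", {
  truth <- list(a = 0.5, b = 0.05, z = 10, w = 20)
  rates <- simulate_tpc_experiment(truth, seq(-2, 20, length.out = 8),
                                   replicates = 4, noise_sd = 0.03, seed = 2)
  b1 <- bootstrap_tpc(rates, n_boot = 200, seed = 9)
  b2 <- bootstrap_tpc(rates, n_boot = 200, seed = 9)
  expect_identical(b1$ci, b2$ci)
  expect_error(bootstrap_tpc(rates, n_boot = 100, seed = 1), "at least 200")
})

test_that("Welch test matches hand computation and is antisymmetric", {
  w <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -1.2247, tolerance = 1e-4)
  expect_equal(w$df, 4.000, tolerance = 1e-6)
  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  a <- rnorm(5); b <- rnorm(6, 1)
  expect_equal(welch_test(a, b)$t, -welch_test(b, a)$t)
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})
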