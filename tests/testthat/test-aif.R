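test_that("gamma-variate bolus: zero before arrival, peak at t0 + alpha*beta", {
  times <- seq(0, 40, by = 0.01)
  a <- simulate_aif(times, t0 = 2, alpha = 2.5, beta = 1.5, peak = 1)
  expect_true(all(a$concentration[times <= 2] == 0))
  expect_true(all(a$concentration >= 0))
  expect_equal(times[which.max(a$concentration)], 2 + 2.5 * 1.5,
               tolerance = 0.02)
  expect_equal(max(a$concentration), 1, tolerance = 1e-10)
  expect_error(simulate_aif(times, alpha = -1), class = "cmrquant_config_error")
  expect_error(simulate_aif(times, beta = 0), class = "cmrquant_config_error")
})

test_that("bolus area matches the closed form A beta^(alpha+1) Gamma(alpha+1)", {
  times <- seq(0, 120, by = 0.005)  # long fine grid captures the full tail
  amp <- 0.37; alpha <- 2.5; beta <- 1.5
  a <- simulate_aif(times, t0 = 2, alpha = alpha, beta = beta, amplitude = amp)
  area_num <- sum(a$concentration) * 0.005
  area_closed <- amp * beta^(alpha + 1) * gamma(alpha + 1)
  expect_lt(abs(area_num - area_closed) / area_closed, 0.01)
})

test_that("dual-bolus scaling multiplies amplitude by the dose ratio only", {
  a <- simulate_aif()
  hi <- scale_dual_bolus_aif(a, 0.01, 0.09)
  expect_equal(hi$dose_scale_applied, 9)
  expect_equal(hi$concentration, 9 * a$concentration)
  expect_equal(which.max(hi$concentration), which.max(a$concentration))
  same <- scale_dual_bolus_aif(a, 0.05, 0.05)
  expect_equal(same$concentration, a$concentration)
  expect_error(scale_dual_bolus_aif(a, 0, 0.09),
               class = "cmrquant_config_error")
})

test_that("AIF container validates its grid", {
  expect_error(aif(c(0, 1, 1.5), c(0, 1, 0)), "uniform")
  expect_error(aif(c(0, 1, 0.5), c(0, 1, 0)), "increasing")
  expect_message(aif(0:10, c(-0.001, rep(1, 10))), "negative")
  expect_error(aif(0:10, c(-0.9, rep(1, 10))), "negative concentrations")
})

test_that("signal_to_concentration inverts relative enhancement", {
  s0 <- 3.2
  x <- c(rep(0, 5), 0.1, 0.5, 0.2, 0, 0)
  conc <- signal_to_concentration(s0 * (1 + x), n_baseline_frames = 5)
  expect_equal(conc, x, tolerance = 1e-12)
  expect_equal(signal_to_concentration(rep(4, 30)), rep(0, 30))
  expect_warning(signal_to_concentration(c(1, 1, 1, 5, 8, 9, 9), 5), "flat")
  expect_error(signal_to_concentration(rep(-1, 10), 5), "positive")
  expect_error(signal_to_concentration(rep(1, 10), 2), ">= 3")
})
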