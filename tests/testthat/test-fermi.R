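test_that("Fermi residue: R(tau0) = f_amp, nonincreasing, vanishing tail", {
  t <- seq(0, 60, by = 0.05)
  p <- fermi_params(0.04, tau0 = 2, w = 4, k = 1)
  r <- fermi_residue(t, p)
  expect_equal(r[t == 2], 0.04, tolerance = 1e-12)
  expect_true(all(r[t < 2] == 0))
  expect_true(all(diff(r[t >= 2]) <= 1e-12))
  expect_lt(r[length(r)], 1e-8)
  # wide plateau: height f_amp held for about w seconds
  pw <- fermi_params(0.05, tau0 = 0, w = 20, k = 0.5)
  rw <- fermi_residue(t, pw)
  expect_true(all(abs(rw[t > 1 & t < 15] - 0.05) < 1e-3))
  expect_error(fermi_params(0.05, k = 0), class = "cmrquant_config_error")
  expect_error(fermi_params(-0.1), class = "cmrquant_config_error")
})

test_that("noise-free deconvolution recovers flow within 1%", {
  a <- simulate_aif()
  for (f in c(0.5, 1.0, 1.31, 2.40, 3.0)) {
    fit <- fermi_deconvolve(a, simulate_tissue_curve(a, f))
    expect_lt(abs(fit$mbf - f) / f, 0.01)
    expect_true(fit$converged)
  }
  # zero tissue means zero flow, not an error
  z <- fermi_deconvolve(a, rep(0, length(a$times)))
  expect_equal(z$mbf, 0)
})

test_that("deconvolution errors on degenerate inputs", {
  a <- simulate_aif()
  expect_error(fermi_deconvolve(a, rep(0, 10)), "grid")
  expect_error(fermi_deconvolve(aif(a$times, rep(0, length(a$times)) + 0),
                                simulate_tissue_curve(a, 1)), "zero")
  short <- simulate_aif(seq(0, by = 0.4, length.out = 15))
  expect_error(fermi_deconvolve(short, rep(0.1, 15)), "20 frames")
})

test_that("deconvolution is scale-consistent", {
  a <- simulate_aif()
  tis <- simulate_tissue_curve(a, 1.4)
  base <- fermi_deconvolve(a, tis)$mbf
  # common rescaling of AIF and tissue leaves MBF unchanged
  a2 <- aif(a$times, a$concentration * 3.7)
  expect_equal(fermi_deconvolve(a2, tis * 3.7)$mbf, base, tolerance = 1e-3)
  # rescaling tissue alone rescales MBF
  expect_equal(fermi_deconvolve(a, tis * 1.5)$mbf, 1.5 * base,
               tolerance = 1e-3)
})

test_that("delaying the tissue curve moves tau0, not the flow", {
  a <- simulate_aif()
  dt <- 0.4
  tis <- simulate_tissue_curve(a, 2.0, fermi_shape = list(tau0 = 1, w = 4, k = 1))
  shifted <- c(rep(0, 3), tis[1:(length(tis) - 3)])  # delay by 3 frames = 1.2 s
  f0 <- fermi_deconvolve(a, tis)
  f1 <- fermi_deconvolve(a, shifted)
  # the delay is only estimable to about one frame interval
  expect_lt(abs((f1$params$tau0 - f0$params$tau0) - 3 * dt), 0.25)
  expect_equal(f1$mbf, f0$mbf, tolerance = 0.02)
})

test_that("median flow error stays below 10% at SNR 20", {
  a <- simulate_aif()
  errs <- withr::with_seed(77, {
    unlist(lapply(c(0.5, 1.0, 2.0, 3.0), function(f) {
      clean <- simulate_tissue_curve(a, f)
      replicate(50, {
        noisy <- clean + rnorm(length(clean), sd = max(clean) / 20)
        abs(fermi_deconvolve(a, noisy)$mbf - f) / f
      })
    }))
  })
  expect_length(errs, 200L)
  expect_lt(median(errs), 0.10)
})

test_that("dual-bolus analysis equals true high-dose analysis under linearity", {
  a_low <- simulate_aif(peak = 0.5)
  a_high_true <- aif(a_low$times, a_low$concentration * 9)
  a_high_scaled <- scale_dual_bolus_aif(a_low, 0.01, 0.09)
  tis <- simulate_tissue_curve(a_high_true, 1.31)
  mbf_scaled <- fermi_deconvolve(a_high_scaled, tis)$mbf
  mbf_true <- fermi_deconvolve(a_high_true, tis)$mbf
  expect_lt(abs(mbf_scaled - mbf_true) / mbf_true, 0.01)
  expect_lt(abs(mbf_scaled - 1.31) / 1.31, 0.01)
})
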