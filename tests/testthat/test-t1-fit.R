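ir_signal <- function(tis, a, b, t1_star) abs(a - b * exp(-tis / t1_star))

test_that("noise-free fits recover the generating parameters exactly", {
  tis <- c(100, 500, 900, 1300, 1700, 180, 580, 980)
  fit <- fit_ir_three_param(tis, ir_signal(tis, 1, 2, 500))
  expect_true(fit$valid)
  expect_equal(fit$t1, 500, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-8)

  # parameters other than the canonical B/A = 2
  fit2 <- fit_ir_three_param(tis, ir_signal(tis, 1.3, 2.2, 800))
  expect_equal(fit2$t1, 800 * (2.2 / 1.3 - 1), tolerance = 1e-5)
})

test_that("corrected T1 is invariant to rescaling all signals", {
  tis <- c(100, 500, 900, 1300, 1700, 180, 580, 980)
  s <- ir_signal(tis, 1, 2, 700)
  f1 <- fit_ir_three_param(tis, s)
  f2 <- fit_ir_three_param(tis, 37.5 * s)
  expect_equal(f2$t1, f1$t1, tolerance = 1e-8)
  expect_equal(f2$a_param / f1$a_param, 37.5, tolerance = 1e-6)
})

test_that("fitted T1 increases with ground-truth T1 (noise-free)", {
  sch <- molli_scheme("5(3)3")
  t1s <- vapply(c(300, 500, 800, 1200, 1600, 2000), function(t1) {
    sim <- simulate_molli_series(matrix(t1, 1, 1), sch, 0)
    fit_ir_three_param(sim$tis$ti_ms, sim$stack[1, 1, ])$t1
  }, 0)
  expect_true(all(diff(t1s) > 0))
})

test_that("degenerate inputs flag invalid rather than erroring", {
  tis <- c(100, 500, 900, 1300)
  const <- fit_ir_three_param(tis, rep(2, 4))
  expect_false(const$valid)
  expect_true(is.na(const$t1))
  expect_error(fit_ir_three_param(c(100, 500, 900), c(1, 2, 3)),
               "at least 4")
  expect_error(fit_ir_three_param(c(100, 100, 500, 900), rep(1, 4)),
               "distinct")
})

test_that("look_locker_correct applies t1_star * (b/a - 1) and flags b/a <= 1", {
  expect_equal(as.numeric(look_locker_correct(1, 2, 500)), 500)
  expect_equal(as.numeric(look_locker_correct(1, 1.5, 900)), 450)
  bad <- look_locker_correct(1, 0.9, 500)
  expect_true(is.na(as.numeric(bad)))
  expect_false(attr(bad, "valid"))
  expect_error(look_locker_correct(0, 2, 500), class = "cmrquant_config_error")
  expect_error(look_locker_correct(1, 2, -5), class = "cmrquant_config_error")
})

test_that("median T1 error stays below 2% at SNR 30", {
  tis <- molli_ti_schedule(molli_scheme("5(3)3"))$ti_ms
  clean <- 1 - 2 * exp(-tis / 600)  # signed signal, T1* = 600, B/A = 2
  withr::with_seed(101, {
    errs <- replicate(500, {
      fit <- fit_ir_three_param(tis, abs(clean + rnorm(length(tis), sd = 1 / 30)))
      abs(fit$t1 - 600) / 600
    })
  })
  expect_lt(median(errs), 0.02)
})

test_that("T1 maps reproduce uniform phantoms and handle empty/bad masks", {
  ph <- tiny_phantom()
  sim <- simulate_molli_series(ph$t1_pre, molli_scheme("5(3)3"), 0)
  t1 <- compute_t1_map(sim$stack, sim$tis, ph$myo_mask)
  expect_equal(as.numeric(roi_mean(t1)), 1200, tolerance = 1e-5)
  expect_true(all(abs(t1$values[t1$valid] - 1200) < 1e-3))

  expect_warning(
    empty <- compute_t1_map(sim$stack, sim$tis,
                            matrix(FALSE, nrow(ph$labels), ncol(ph$labels))),
    "empty")
  expect_equal(sum(empty$valid), 0L)
  expect_error(compute_t1_map(sim$stack, sim$tis[-1, ], ph$myo_mask),
               "frames")
  expect_error(compute_t1_map(sim$stack, sim$tis, matrix(TRUE, 2, 2)),
               "mask shape")
})
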