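test_that("zero-flow pixels give flat noise-free signal; NA pixels baseline", {
  a <- simulate_aif()
  flow <- matrix(c(0, 1.5, NA, 2), 2, 2)
  sim <- simulate_perfusion_series(a, flow, noise_sd = 0)
  expect_true(all(sim$stack[1, 1, ] == 1))  # flow 0
  expect_true(all(sim$stack[1, 2, ] == 1))  # NA -> baseline only
  expect_gt(max(sim$stack[2, 1, ]), 1)      # flow 1.5 enhances
})

test_that("tissue enhancement is linear in flow", {
  a <- simulate_aif()
  sim <- simulate_perfusion_series(a, matrix(c(1, 2), 1, 2), noise_sd = 0)
  c1 <- sim$stack[1, 1, ] - 1
  c2 <- sim$stack[1, 2, ] - 1
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("perfusion series are reproducible under a fixed seed", {
  a <- simulate_aif()
  flow <- matrix(1.3, 2, 2)
  s1 <- simulate_perfusion_series(a, flow, noise_sd = 0.02, seed = 5)
  s2 <- simulate_perfusion_series(a, flow, noise_sd = 0.02, seed = 5)
  expect_identical(s1$stack, s2$stack)
  expect_error(simulate_perfusion_series(a, matrix(-1, 1, 1)),
               class = "cmrquant_config_error")
})

test_that("pixel-wise perfusion maps recover a uniform-flow phantom", {
  a_high <- scale_dual_bolus_aif(simulate_aif(), 0.01, 0.09)
  flow <- matrix(NA_real_, 6, 6)
  mask <- matrix(FALSE, 6, 6)
  mask[2:4, 2:4] <- TRUE
  flow[mask] <- 2.40
  sim <- simulate_perfusion_series(a_high, flow, noise_sd = 0)
  pmap <- compute_perfusion_map(sim$stack, a_high, mask, n_baseline = 5)
  expect_true(all(abs(pmap$values[pmap$valid] - 2.40) / 2.40 < 0.01))
  expect_true(all(is.na(pmap$values[!mask])))  # masked-out pixels absent
  expect_equal(pmap$meta$roi_mean, 2.40, tolerance = 0.01)
  expect_error(compute_perfusion_map(sim$stack, a_high, mask[1:3, 1:3]),
               "shape")
})

test_that("MPR is stress over rest for scalars and maps alike", {
  expect_equal(compute_mpr(1.31, 2.40), 2.40 / 1.31, tolerance = 1e-12)
  expect_equal(round(compute_mpr(1.31, 2.40), 2), 1.83)
  expect_equal(compute_mpr(1.7, 1.7), 1)
  expect_error(compute_mpr(0, 2), class = "cmrquant_config_error")

  mk <- function(v) cmrquant:::new_cmr_map(matrix(v, 3, 3),
                                           matrix(TRUE, 3, 3),
                                           matrix(TRUE, 3, 3),
                                           "perfusion", "ml/min/g")
  mpr_map <- compute_mpr(mk(1.31), mk(2.40))
  expect_equal(unique(as.vector(mpr_map$values)), compute_mpr(1.31, 2.40))
})
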