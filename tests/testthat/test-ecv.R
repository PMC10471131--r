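test_that("delta_r1 is the difference of relaxation rates", {
  expect_equal(delta_r1(1200, 600), 1 / 600 - 1 / 1200, tolerance = 1e-15)
  expect_equal(delta_r1(1000, 1000), 0)
  expect_lt(delta_r1(600, 1200), 0)
  expect_error(delta_r1(-5, 600), class = "cmrquant_config_error")
})

test_that("compute_ecv_value matches the arithmetic oracle to 1e-12", {
  oracle <- (1 - 0.51) * (1 / 600 - 1 / 1200) / (1 / 400 - 1 / 1600)
  got <- compute_ecv_value(1200, 600, 1600, 400, 0.51)
  expect_equal(as.numeric(got), oracle, tolerance = 1e-12)
  # printed-percent convention: 21.78%
  expect_equal(round(100 * as.numeric(got), 2), 21.78)

  # symmetry: equal delta-R1s give ECV = 1 - hct
  expect_equal(as.numeric(compute_ecv_value(1200, 600, 1200, 600, 0.5)), 0.5)
  # no myocardial enhancement: ECV = 0
  expect_equal(as.numeric(compute_ecv_value(1000, 1000, 1600, 400, 0.4)), 0)
  expect_error(compute_ecv_value(1200, 600, 1600, 400, 1.3),
               class = "cmrquant_config_error")
  # negative blood delta-R1 flags invalid
  bad <- compute_ecv_value(1200, 600, 400, 1600, 0.5)
  expect_true(is.na(as.numeric(bad)))
})

test_that("ECV is invariant under common T1 rescaling and decreasing in hct", {
  base <- as.numeric(compute_ecv_value(1200, 600, 1600, 400, 0.45))
  for (c in c(0.5, 2, 7.3)) {
    scaled <- as.numeric(compute_ecv_value(1200 * c, 600 * c, 1600 * c,
                                           400 * c, 0.45))
    expect_equal(scaled, base, tolerance = 1e-12)
  }
  hcts <- seq(0.1, 0.9, by = 0.1)
  ecvs <- vapply(hcts, function(h)
    as.numeric(compute_ecv_value(1200, 600, 1600, 400, h)), 0)
  expect_true(all(diff(ecvs) < 0))
})

test_that("ECV maps are pixel-wise correct with a single blood delta-R1", {
  ph <- tiny_phantom()
  m <- compute_ecv_map(ph$t1_pre, ph$t1_post,
                       blood_roi_pre_mean = ph$truth$t1_pre_blood,
                       blood_roi_post_mean = ph$truth$t1_post_blood,
                       hct = ph$truth$hct, myo_mask = ph$myo_mask)
  expect_equal(unique(round(m$values[m$valid], 10)),
               round(ph$truth$ecv, 10))
  # hct -> 1 limit drives ECV to 0
  m1 <- compute_ecv_map(ph$t1_pre, ph$t1_post, 1600, 400,
                        hct = 1 - 1e-9, myo_mask = ph$myo_mask)
  expect_lt(max(m1$values[m1$valid]), 1e-6)
  # percent-style hct input is converted
  expect_message(
    m2 <- compute_ecv_map(ph$t1_pre, ph$t1_post, 1600, 400, hct = 51,
                          myo_mask = ph$myo_mask),
    "percent")
  expect_equal(m2$meta$hct, 0.51)
  expect_error(compute_ecv_map(ph$t1_pre, ph$t1_post[1:10, 1:10], 1600, 400,
                               0.5, ph$myo_mask), "shape")
})

test_that("roi_mean averages valid pixels only and reports n", {
  vals <- matrix(c(0.2, 0.3, 0.2, 0.3), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  m <- cmrquant:::new_cmr_map(vals, matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2),
                              mask, "ecv", "fraction")
  out <- roi_mean(m)
  expect_equal(as.numeric(out), mean(c(0.2, 0.3, 0.2)))
  expect_equal(attr(out, "n"), 3L)
  expect_equal(as.numeric(roi_mean(matrix(5, 3, 3))), 5)
  empty <- cmrquant:::new_cmr_map(vals, matrix(FALSE, 2, 2), mask,
                                  "ecv", "fraction")
  expect_error(roi_mean(empty), "empty")
})
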