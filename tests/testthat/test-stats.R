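# Explicit-formula oracles, written independently of the implementations.

anova_oracle <- function(v, g) {
  g <- factor(g)
  k <- nlevels(g); n <- length(v)
  grand <- mean(v)
  ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  c(f = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

test_that("one-way ANOVA matches the sums-of-squares oracle to 1e-12", {
  withr::with_seed(5, {
    d <- tibble::tibble(g = rep(c("a", "b", "c"), times = c(5, 7, 6)),
                        v = c(rnorm(5, 10), rnorm(7, 12, 2), rnorm(6, 9, 0.5)))
  })
  got <- one_way_anova(d, v, g)
  want <- anova_oracle(d$v, d$g)
  expect_equal(got$f, unname(want["f"]), tolerance = 1e-12)
  expect_equal(got$p_value, unname(want["p"]), tolerance = 1e-12)
})

test_that("two-group ANOVA F equals the squared pooled-variance t statistic", {
  withr::with_seed(6, {
    d <- tibble::tibble(g = rep(c("a", "b"), each = 9),
                        v = c(rnorm(9, 1), rnorm(9, 1.8)))
  })
  f <- one_way_anova(d, v, g)$f
  tt <- t.test(v ~ g, data = d, var.equal = TRUE)$statistic
  expect_equal(f, unname(tt)^2, tolerance = 1e-12)
})

test_that("ANOVA degenerates gracefully and validates group sizes", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 4), v = rep(2, 8))
  out <- one_way_anova(d, v, g)
  expect_true(out$degenerate)
  expect_true(is.na(out$f))
  expect_error(one_way_anova(tibble::tibble(g = "a", v = 1), v, g), "2 groups")
  expect_error(one_way_anova(tibble::tibble(g = c("a", "a", "b"),
                                            v = c(1, 2, 3)), v, g),
               "2 subjects")
})

test_that("ANOVA F is shift-invariant and scale-invariant", {
  withr::with_seed(7, {
    d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 6), v = rnorm(18))
  })
  f0 <- one_way_anova(d, v, g)$f
  expect_equal(one_way_anova(dplyr::mutate(d, v = v + 100), v, g)$f, f0,
               tolerance = 1e-9)
  expect_equal(one_way_anova(dplyr::mutate(d, v = v * 13), v, g)$f, f0,
               tolerance = 1e-9)
})

test_that("ANCOVA coefficients match the normal-equations oracle to 1e-10", {
  withr::with_seed(8, {
    d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 7),
                        age = rnorm(21, 12, 3))
    d$v <- 20 + 2 * (d$g == "b") + 5 * (d$g == "c") + 0.4 * d$age + rnorm(21)
  })
  anc <- ancova_age_adjust(d, v, g, age)
  # design matrix: intercept, age, indicators for b and c
  X <- cbind(1, d$age, d$g == "b", d$g == "c")
  beta <- solve(t(X) %*% X, t(X) %*% d$v)
  expect_equal(unname(coef(anc$model)), as.vector(beta[c(1, 2, 3, 4)]),
               tolerance = 1e-10)
  # adjusted means are predictions at the grand-mean age
  abar <- mean(d$age)
  want <- c(beta[1] + beta[2] * abar,
            beta[1] + beta[2] * abar + beta[3],
            beta[1] + beta[2] * abar + beta[4])
  expect_equal(anc$adjusted_means$adjusted_mean, unname(want),
               tolerance = 1e-10)
})

test_that("ANCOVA removes a pure age confound and respects orthogonality", {
  # groups differ only through age; value is age plus noise
  withr::with_seed(9, {
    d <- tibble::tibble(g = rep(c("young", "old"), each = 15),
                        age = c(rnorm(15, 8, 1), rnorm(15, 18, 1)))
    d$v <- 2 * d$age + rnorm(30, sd = 0.5)
  })
  anc <- ancova_age_adjust(d, v, g, age)
  expect_gt(anc$p_value, 0.05)

  # age orthogonal to value and balanced groups: adjusted ~ unadjusted means
  withr::with_seed(10, {
    d2 <- tibble::tibble(g = rep(c("a", "b"), each = 200),
                         age = rep(rnorm(200, 12, 2), 2),
                         v = rep(c(0, 3), each = 200) + rnorm(400))
  })
  anc2 <- ancova_age_adjust(d2, v, g, age)
  raw <- tapply(d2$v, d2$g, mean)
  expect_equal(anc2$adjusted_means$adjusted_mean, unname(as.vector(raw)),
               tolerance = 0.05)
  expect_error(ancova_age_adjust(dplyr::filter(d2, g == "a"), v, g, age),
               "2 groups")
  expect_error(ancova_age_adjust(dplyr::mutate(d2, age = 5), v, g, age),
               "zero variance")
})

test_that("correlations match closed-form partial-correlation oracle", {
  withr::with_seed(12, {
    z <- rnorm(25)
    x <- z + rnorm(25)
    y <- 0.5 * z + rnorm(25)
  })
  out <- correlations(x, y, covariate = z)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(out$partial_r, oracle, tolerance = 1e-12)
  expect_equal(out$r, rxy, tolerance = 1e-12)
  # p-value agrees with cor.test on n - 3 df logic
  tt <- oracle * sqrt((25 - 3) / (1 - oracle^2))
  expect_equal(out$partial_p, 2 * pt(-abs(tt), 22), tolerance = 1e-12)
})

test_that("correlation edge cases behave as documented", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlations(x, x)$r, 1)
  const_cov <- correlations(x, c(2, 1, 4, 3, 6), covariate = rep(7, 5))
  expect_equal(const_cov$partial_r, const_cov$r)
  expect_error(correlations(rep(1, 5), x), "zero variance")
})
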