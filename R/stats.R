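# Cohort statistics: classical one-way ANOVA, age-adjusted ANCOVA, Pearson
# and partial correlation. Model fits go through stats::lm/anova; the
# functions here wrap them with the conventions used throughout the package
# (tibbles in, tibbles out, raw two-sided p-values, no multiplicity
# correction).

#' Classical one-way ANOVA
#'
#' Between/within decomposition with p from the F distribution on
#' (k - 1, N - k) degrees of freedom. A Welch correction is available behind
#' `welch = TRUE` but is off by default (the classical test is the named
#' method of the analysis this package reproduces).
#'
#' @param data Data frame.
#' @param value,group Columns (bare names) holding the response and the
#'   group labels.
#' @param welch Use Welch's heteroscedastic ANOVA instead.
#' @return One-row tibble: `f`, `df1`, `df2`, `p_value`, `n`, `k`,
#'   `degenerate` (TRUE when the within-group variance is zero, in which
#'   case `f`/`p_value` are NA rather than an error).
#' @export
one_way_anova <- function(data, value, group, welch = FALSE) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- factor(g[keep])
  g <- droplevels(g)
  if (nlevels(g) < 2) stop_cfg("ANOVA needs at least 2 groups")
  if (any(table(g) < 2)) stop_cfg("every group needs at least 2 subjects")
  k <- nlevels(g); n <- length(v)
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  if (ssw <= .Machine$double.eps * sum(v^2)) {
    return(tibble(f = NA_real_, df1 = k - 1, df2 = n - k, p_value = NA_real_,
                  n = n, k = k, degenerate = TRUE))
  }
  if (welch) {
    ft <- stats::oneway.test(v ~ g, var.equal = FALSE)
    return(tibble(f = unname(ft$statistic), df1 = unname(ft$parameter[1]),
                  df2 = unname(ft$parameter[2]), p_value = ft$p.value,
                  n = n, k = k, degenerate = FALSE))
  }
  tab <- anova(lm(v ~ g))
  tibble(f = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
         p_value = tab$`Pr(>F)`[1], n = n, k = k, degenerate = FALSE)
}

#' Age-adjusted group comparison (ANCOVA)
#'
#' Fits `value ~ age + group` and tests the group effect by the
#' extra-sum-of-squares F test against `value ~ age` (Type II: the covariate
#' is always retained). Adjusted group means are the model predictions at
#' the grand-mean age.
#'
#' @param data Data frame.
#' @param value,group,age Columns (bare names).
#' @return A `cmr_ancova`: list with `adjusted_means` tibble (`group`,
#'   `adjusted_mean`), `f`, `df1`, `df2`, `p_value`, `n`, `grand_mean_age`
#'   and the full `model`.
#' @export
ancova_age_adjust <- function(data, value, group, age) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  a <- dplyr::pull(data, {{ age }})
  keep <- !is.na(v) & !is.na(g) & !is.na(a)
  v <- v[keep]; a <- a[keep]
  g <- droplevels(factor(g[keep]))
  if (nlevels(g) < 2) stop_cfg("ANCOVA needs at least 2 groups")
  if (!all(is.finite(a))) stop_cfg("age must be finite")
  if (sd(a) == 0) stop_cfg("age has zero variance; adjustment is degenerate")
  d <- data.frame(v = v, g = g, a = a)
  fit_full <- lm(v ~ a + g, data = d)
  fit_red <- lm(v ~ a, data = d)
  cmp <- anova(fit_red, fit_full)
  abar <- mean(a)
  adj <- predict(fit_full, newdata = data.frame(g = levels(g), a = abar))
  structure(
    list(adjusted_means = tibble(group = levels(g),
                                 adjusted_mean = unname(adj)),
         f = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
         p_value = cmp$`Pr(>F)`[2], n = nrow(d), grand_mean_age = abar,
         model = fit_full),
    class = "cmr_ancova"
  )
}

#' @export
print.cmr_ancova <- function(x, ...) {
  cat(sprintf("<cmr_ancova> group effect F(%d, %d) = %.3f, p = %.4g (n = %d, at age %.2f)\n",
              x$df1, x$df2, x$f, x$p_value, x$n, x$grand_mean_age))
  print(x$adjusted_means)
  invisible(x)
}

#' @rdname ancova_age_adjust
#' @param x A `cmr_ancova`.
#' @param ... Unused.
#' @method tidy cmr_ancova
#' @export
tidy.cmr_ancova <- function(x, ...) x$adjusted_means

#' @rdname ancova_age_adjust
#' @method glance cmr_ancova
#' @export
glance.cmr_ancova <- function(x, ...) {
  tibble(f = x$f, df1 = x$df1, df2 = x$df2, p_value = x$p_value, n = x$n,
         grand_mean_age = x$grand_mean_age)
}

#' Pearson and (optionally) partial correlation
#'
#' Pearson r with the usual t-test p-value; when a covariate is supplied the
#' partial correlation is computed on the residuals of `x` and `y` each
#' regressed on the covariate, with the t-test on n - 3 degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param covariate Optional numeric covariate (e.g. age) to partial out.
#' @return One-row tibble: `r`, `p_value`, `n`, and when a covariate is
#'   given also `partial_r`, `partial_p`.
#' @export
correlations <- function(x, y, covariate = NULL) {
  keep <- !is.na(x) & !is.na(y) & (is.null(covariate) | !is.na(covariate %||% x))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) stop_cfg("zero variance in x or y")
  ct <- cor.test(x, y)
  out <- tibble(r = unname(ct$estimate), p_value = ct$p.value, n = n)
  if (!is.null(covariate)) {
    z <- covariate[keep]
    if (n < 4) stop_cfg("partial correlation needs n >= 4")
    if (sd(z) == 0) {
      # constant covariate adjusts nothing
      out$partial_r <- out$r
      out$partial_p <- out$p_value
      return(out)
    }
    rx <- stats::resid(lm(x ~ z))
    ry <- stats::resid(lm(y ~ z))
    pr <- cor(rx, ry)
    tt <- pr * sqrt((n - 3) / (1 - pr^2))
    out$partial_r <- pr
    out$partial_p <- 2 * pt(-abs(tt), df = n - 3)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form AUC of two Gaussian score distributions
#'
#' For scores `N(mu_pos, sd_pos^2)` in the diseased class and
#' `N(mu_neg, sd_neg^2)` in the reference class, the population ROC AUC is
#' `pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))`. Vectorised; used
#' as the analytic limit against which empirical replicate AUCs converge.
#'
#' @param mu_pos,sd_pos,mu_neg,sd_neg Gaussian parameters per class.
#' @export
gaussian_auc <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))
}
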