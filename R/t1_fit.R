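# Per-pixel three-parameter inversion-recovery fitting with Look-Locker
# correction. The magnitude signal model is S(TI) = |A - B exp(-TI/T1*)|;
# polarity restoration tries every split point between the inverted early
# samples and the recovered late samples and keeps the minimum-RSS signed fit.
#
# The fit itself uses variable projection: for fixed T1* the model is linear
# in (A, B), so A and B come from a closed-form least-squares solve and only
# T1* is searched (coarse log-spaced grid, then 1-D bounded refinement).
# This is deterministic and cannot fail to converge, which matters when it is
# run on every myocardial pixel.

# Closed-form least squares for y ~ A - B * x. Returns c(A, B, rss).
ir_linfit <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  den <- n * sum(x * x) - sx * sx
  if (abs(den) < 1e-300) {
    a <- sy / n
    return(c(a, 0, sum((y - a)^2)))
  }
  slope <- (n * sum(x * y) - sx * sy) / den
  b <- -slope
  a <- (sy + b * sx) / n
  c(a, b, sum((y - (a - b * x))^2))
}

#' Fit the three-parameter inversion-recovery model to one pixel
#'
#' Minimises \eqn{\sum_i (|A - B e^{-TI_i/T1^*}| - S_i)^2} over A, B, T1*
#' with polarity restoration for magnitude data: for every candidate count
#' `k = 0..n-1` the `k` earliest-TI samples are negated, the signed model is
#' fitted, and the minimum-RSS candidate wins. The Look-Locker-corrected
#' `t1 = t1_star * (b/a - 1)` is returned alongside the apparent `t1_star`.
#'
#' @param tis Inversion times in ms (>= 4 distinct positive values).
#' @param signals Magnitude signals, same length as `tis`.
#' @param t1_star_bounds Search bounds for the apparent T1* (ms); fits landing
#'   on a bound are marked invalid.
#' @param n_grid Number of log-spaced grid points for the coarse T1* search.
#' @return An `ir_fit` with fields `a_param`, `b_param`, `t1_star`, `t1`,
#'   `rss`, `valid`, `polarity_index`. `valid` is `FALSE` (never an error)
#'   when the fit is degenerate: `b/a <= 1`, non-positive A, or T1* at a
#'   bound.
#' @export
fit_ir_three_param <- function(tis, signals, t1_star_bounds = c(50, 5000),
                               n_grid = 48L) {
  if (length(tis) != length(signals))
    stop_cfg("tis and signals must have the same length")
  if (length(tis) < 4L)
    stop_cfg("at least 4 samples are required for a 3-parameter fit")
  if (any(tis <= 0) || anyDuplicated(tis))
    stop_cfg("inversion times must be distinct and positive")
  lo <- t1_star_bounds[1]; hi <- t1_star_bounds[2]
  stopifnot(lo > 0, hi > lo)

  n <- length(tis)
  ord <- order(tis)
  t1_grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  # n x n_grid matrix of exp(-TI/T1*) shared by all polarity candidates
  xg <- exp(-outer(tis, 1 / t1_grid))

  best <- NULL
  for (k in 0:(n - 1L)) {
    y <- signals
    if (k > 0) y[ord[seq_len(k)]] <- -y[ord[seq_len(k)]]
    # vectorised grid RSS via the closed-form linear solve
    sy <- sum(y); syy <- sum(y * y)
    sx <- colSums(xg); sxx <- colSums(xg * xg); sxy <- colSums(xg * y)
    den <- n * sxx - sx^2
    slope <- ifelse(abs(den) < 1e-300, 0, (n * sxy - sx * sy) / den)
    a0 <- (sy - slope * sx) / n
    rss_g <- syy - 2 * (a0 * sy + slope * sxy) +
      n * a0^2 + 2 * a0 * slope * sx + slope^2 * sxx
    i <- which.min(rss_g)
    bracket <- c(t1_grid[max(1L, i - 1L)], t1_grid[min(n_grid, i + 1L)])
    f <- function(t1s) ir_linfit(exp(-tis / t1s), y)[3]
    opt <- optimize(f, interval = bracket, tol = 1e-4)
    # keep whichever of grid point / refined point is better
    t1s <- if (opt$objective <= rss_g[i]) opt$minimum else t1_grid[i]
    fit <- ir_linfit(exp(-tis / t1s), y)
    cand <- list(a = fit[1], b = fit[2], t1_star = t1s, rss = fit[3], k = k)
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }

  at_bound <- best$t1_star <= lo * 1.005 || best$t1_star >= hi * 0.995
  valid <- is.finite(best$rss) && best$a > 0 && best$b > 0 &&
    best$b / best$a > 1 && !at_bound
  t1 <- if (valid) best$t1_star * (best$b / best$a - 1) else NA_real_
  structure(
    list(a_param = best$a, b_param = best$b, t1_star = best$t1_star,
         t1 = t1, rss = best$rss, valid = valid, polarity_index = best$k),
    class = "ir_fit"
  )
}

#' @export
print.ir_fit <- function(x, ...) {
  cat(sprintf("<ir_fit> T1 = %s ms (T1* %.1f, B/A %.3f, %d early samples flipped, rss %.3g)%s\n",
              if (x$valid) sprintf("%.1f", x$t1) else "NA",
              x$t1_star, x$b_param / x$a_param, x$polarity_index, x$rss,
              if (x$valid) "" else " [invalid]"))
  invisible(x)
}

#' @rdname fit_ir_three_param
#' @param x An `ir_fit`.
#' @param ... Unused.
#' @method tidy ir_fit
#' @export
tidy.ir_fit <- function(x, ...) {
  tibble(a_param = x$a_param, b_param = x$b_param, t1_star = x$t1_star,
         t1 = x$t1, rss = x$rss, valid = x$valid,
         polarity_index = x$polarity_index)
}

#' Look-Locker correction
#'
#' Converts the apparent relaxation time of a continuously sampled inversion
#' recovery into true T1: `t1 = t1_star * (b/a - 1)`.
#'
#' @param a,b Fitted equilibrium and inversion amplitudes (a > 0).
#' @param t1_star Apparent T1 in ms (> 0).
#' @return Corrected T1 (ms) with attribute `valid`; `valid = FALSE` and
#'   value `NA` when `b/a <= 1` (non-physical inversion).
#' @export
look_locker_correct <- function(a, b, t1_star) {
  if (any(a <= 0)) stop_cfg("a must be positive")
  if (any(t1_star <= 0)) stop_cfg("t1_star must be positive")
  valid <- b / a > 1
  out <- ifelse(valid, t1_star * (b / a - 1), NA_real_)
  attr(out, "valid") <- valid
  out
}

#' Compute a Look-Locker-corrected T1 map from a MOLLI stack
#'
#' Runs [fit_ir_three_param()] on every pixel inside `mask`; pixels whose fit
#' is degenerate are flagged invalid and excluded from downstream ROI means.
#' The fraction of invalid pixels is reported via a message and stored in the
#' map metadata.
#'
#' @param stack rows x cols x n_images array of magnitude images.
#' @param tis Inversion times (ms), one per frame; a tibble from
#'   [molli_ti_schedule()] is also accepted.
#' @param mask Logical matrix selecting the pixels to fit.
#' @param ... Passed to [fit_ir_three_param()].
#' @return A `cmr_map` of T1 in ms.
#' @export
compute_t1_map <- function(stack, tis, mask, ...) {
  if (is.data.frame(tis)) tis <- tis$ti_ms
  stopifnot(length(dim(stack)) == 3L, is.matrix(mask))
  if (dim(stack)[3] != length(tis))
    stop_cfg("stack has ", dim(stack)[3], " frames but ", length(tis), " TIs given")
  if (!all(dim(stack)[1:2] == dim(mask)))
    stop_cfg("mask shape does not match image shape")
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  values <- matrix(NA_real_, nr, nc)
  valid <- matrix(FALSE, nr, nc)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warn("mask is empty; returning an empty T1 map")
    return(new_cmr_map(values, valid, mask, "t1", "ms",
                       meta = list(n_fitted = 0L, invalid_fraction = NA_real_)))
  }
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    fit <- fit_ir_three_param(tis, stack[i, j, ], ...)
    if (fit$valid) {
      values[i, j] <- fit$t1
      valid[i, j] <- TRUE
    }
  }
  inv_frac <- 1 - sum(valid) / nrow(idx)
  if (inv_frac > 0)
    inform(sprintf("T1 map: %.1f%% of %d fitted pixels invalid",
                   100 * inv_frac, nrow(idx)))
  new_cmr_map(values, valid, mask, "t1", "ms",
              meta = list(n_fitted = nrow(idx), invalid_fraction = inv_frac))
}
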