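# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed when `seed` is given, without disturbing
# the caller's RNG state; run as-is when seed is NULL.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), expr)
  }
}

stop_cfg <- function(...) {
  abort(paste0(...), class = "cmrquant_config_error")
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_cfg(name, " must be a finite numeric scalar")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_cfg(name, " = ", format(x), " is outside the allowed range (",
             if (strict_lower) "(" else "[", lower, ", ", upper,
             if (strict_upper) ")" else "]")
  }
  invisible(x)
}

# A 2-D quantitative map with a validity mask: the common container for the
# T1, ECV and perfusion stages.
new_cmr_map <- function(values, valid, mask, kind, units, meta = list()) {
  stopifnot(is.matrix(values), is.matrix(valid), is.matrix(mask),
            all(dim(values) == dim(valid)), all(dim(values) == dim(mask)))
  structure(
    list(values = values, valid = valid, mask = mask,
         kind = kind, units = units, meta = meta),
    class = "cmr_map"
  )
}

#' @export
print.cmr_map <- function(x, ...) {
  n_mask <- sum(x$mask)
  n_valid <- sum(x$valid & x$mask)
  vals <- x$values[x$valid & x$mask]
  cat(sprintf("<cmr_map: %s [%s]> %d x %d pixels, %d in mask, %d valid\n",
              x$kind, x$units, nrow(x$values), ncol(x$values), n_mask, n_valid))
  if (length(vals)) {
    cat(sprintf("  valid-pixel range: %.4g .. %.4g (mean %.4g)\n",
                min(vals), max(vals), mean(vals)))
  }
  invisible(x)
}

#' Mean of the valid pixels of a map inside a region of interest
#'
#' Arithmetic mean over pixels that are inside `mask` and flagged valid;
#' invalid pixels are excluded, and the number of pixels actually used is
#' attached as attribute `n`.
#'
#' @param map A `cmr_map` (or a plain numeric matrix).
#' @param mask Logical matrix; defaults to the map's own mask.
#' @return Scalar mean with attribute `n` (pixel count used).
#' @export
roi_mean <- function(map, mask = NULL) {
  if (inherits(map, "cmr_map")) {
    if (is.null(mask)) mask <- map$mask
    use <- mask & map$valid
    values <- map$values
  } else {
    stopifnot(is.matrix(map))
    if (is.null(mask)) mask <- !is.na(map)
    use <- mask & !is.na(map)
    values <- map
  }
  if (!any(use)) stop_cfg("ROI is empty after validity filtering")
  out <- mean(values[use])
  attr(out, "n") <- sum(use)
  out
}
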