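# MOLLI acquisition schemes and simulation of inversion-recovery image stacks.

#' Define a MOLLI acquisition scheme
#'
#' A MOLLI scheme strings together several inversion experiments over
#' consecutive heartbeats: the notation "5(3)3" means 5 images after the first
#' inversion, 3 recovery beats, then 3 images after a second inversion.
#' Within an inversion group the k-th image is read at
#' `ti_min[g] + k * rr_interval` because readouts are gated one per heartbeat.
#'
#' @param scheme Scheme string such as `"5(3)3"` or `"4(1)3(1)2"`, or a list
#'   of `(images, recovery_beats)` pairs.
#' @param rr_interval R-R interval in ms (400 ms at the heart rate of
#'   ~150 bpm typical of cynomolgus monkeys).
#' @param ti_min Minimum inversion time (ms) of each inversion group;
#'   defaults to 100 ms for the first group, staggered by 80 ms for each
#'   later group (100, 180, 260, ...) so effective TIs interleave rather
#'   than repeat.
#' @return A `molli_scheme` object.
#' @export
molli_scheme <- function(scheme = "5(3)3", rr_interval = 400, ti_min = NULL) {
  if (is.character(scheme)) {
    groups <- parse_molli_scheme(scheme)
  } else {
    groups <- lapply(scheme, function(g) {
      stopifnot(length(g) == 2L)
      list(images = as.integer(g[[1]]), recovery_beats = as.integer(g[[2]]))
    })
  }
  check_scalar(rr_interval, "rr_interval", lower = 0, strict_lower = TRUE)
  n_groups <- length(groups)
  if (n_groups < 1L) stop_cfg("scheme must contain at least one inversion group")
  if (any(vapply(groups, function(g) g$images < 1L || g$recovery_beats < 0L, TRUE)))
    stop_cfg("images per inversion must be >= 1 and recovery beats >= 0")
  if (is.null(ti_min)) ti_min <- 100 + 80 * (seq_len(n_groups) - 1)
  if (length(ti_min) != n_groups)
    stop_cfg("ti_min must supply one value per inversion group")
  if (any(ti_min <= 0)) stop_cfg("ti_min values must be positive")
  structure(
    list(groups = groups, rr_interval = rr_interval, ti_min = as.numeric(ti_min),
         label = if (is.character(scheme)) scheme else format_molli_groups(groups)),
    class = "molli_scheme"
  )
}

# "5(3)3" -> list(list(images=5, recovery_beats=3), list(images=3, recovery_beats=0))
parse_molli_scheme <- function(s) {
  if (!grepl("^\\d+(\\(\\d+\\)\\d+)*$", s))
    stop_cfg("cannot parse MOLLI scheme string: ", s)
  tokens <- as.integer(regmatches(s, gregexpr("\\d+", s))[[1]])
  images <- tokens[seq(1, length(tokens), by = 2)]
  recov <- tokens[seq(2, length(tokens), by = 2)]
  lapply(seq_along(images), function(i) {
    list(images = images[i],
         recovery_beats = if (i <= length(recov)) recov[i] else 0L)
  })
}

format_molli_groups <- function(groups) {
  paste(vapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (i < length(groups)) sprintf("%d(%d)", g$images, g$recovery_beats)
    else as.character(g$images)
  }, ""), collapse = "")
}

#' @export
print.molli_scheme <- function(x, ...) {
  cat(sprintf("<molli_scheme> %s, RR %g ms, ti_min [%s] ms (%d images)\n",
              x$label, x$rr_interval, paste(x$ti_min, collapse = ", "),
              sum(vapply(x$groups, `[[`, 1L, "images"))))
  invisible(x)
}

#' Inversion-time schedule of a MOLLI scheme
#'
#' Enumerates the effective inversion time of every image: group `g`
#' contributes `images[g]` readouts at `ti_min[g] + k * rr_interval`,
#' `k = 0, 1, ...`, in acquisition order.
#'
#' @param scheme A [molli_scheme()].
#' @return Tibble with `ti_ms`, `inversion_group`, and acquisition `index`.
#' @export
molli_ti_schedule <- function(scheme) {
  stopifnot(inherits(scheme, "molli_scheme"))
  rows <- purrr::imap(scheme$groups, function(g, i) {
    tibble(ti_ms = scheme$ti_min[i] + (seq_len(g$images) - 1) * scheme$rr_interval,
           inversion_group = i)
  })
  out <- dplyr::bind_rows(rows)
  out$index <- seq_len(nrow(out))
  out
}

#' Simulate a MOLLI image stack from a ground-truth T1 map
#'
#' Pixel signals follow the three-parameter apparent inversion recovery
#' \eqn{S(TI) = |A - B e^{-TI/T1^*}|}. The apparent parameters are obtained by
#' inverting the Look-Locker correction: with the inversion-efficiency ratio
#' `b_over_a` (2 for an ideal inversion), `T1* = T1 / (b_over_a - 1)` and
#' `A = 1`, `B = b_over_a`. Gaussian noise of standard deviation `noise_sd`
#' (in units of the equilibrium signal A = 1) is added to the signed signal
#' before the magnitude operation.
#'
#' @param t1_truth_map Numeric matrix of ground-truth T1 (ms); NA pixels give
#'   zero signal.
#' @param scheme A [molli_scheme()].
#' @param noise_sd Gaussian noise SD; 0 for noise-free. SNR is `1/noise_sd`.
#' @param seed Optional integer seed; identical seeds give identical stacks.
#' @param b_over_a Apparent-to-equilibrium signal ratio B/A (default 2).
#' @return List with `stack` (rows x cols x n_images array), `tis` (the
#'   schedule tibble), and the `scheme`.
#' @export
simulate_molli_series <- function(t1_truth_map, scheme = molli_scheme(),
                                  noise_sd = 0, seed = NULL, b_over_a = 2) {
  stopifnot(is.matrix(t1_truth_map))
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(b_over_a, "b_over_a", lower = 1, strict_lower = TRUE)
  sched <- molli_ti_schedule(scheme)
  nr <- nrow(t1_truth_map); nc <- ncol(t1_truth_map)
  t1_star <- t1_truth_map / (b_over_a - 1)
  stack <- with_seed_if(seed, {
    out <- array(0, dim = c(nr, nc, nrow(sched)))
    for (j in seq_len(nrow(sched))) {
      signed <- 1 - b_over_a * exp(-sched$ti_ms[j] / t1_star)
      signed[is.na(signed)] <- 0
      if (noise_sd > 0) signed <- signed + rnorm(nr * nc, sd = noise_sd)
      out[, , j] <- abs(signed)
    }
    out
  })
  list(stack = stack, tis = sched, scheme = scheme)
}
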