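# Cohort simulator: draws per-subject scalar records (echo indices, age,
# hematocrit, ECV, perfusion) from group-level means and SDs, the way the
# cynomolgus heart-failure cohort it emulates is reported.

COHORT_VARIABLES <- c("age", "hct", "ecv", "perf_rest", "perf_stress",
                      "ef", "e_a", "ep_ap", "septal_ep", "e_ep")

COHORT_COLUMNS <- c(age = "age_years", hct = "hct", ecv = "ecv_pct",
                    perf_rest = "perf_rest", perf_stress = "perf_stress",
                    ef = "ef_pct", e_a = "e_a", ep_ap = "ep_ap",
                    septal_ep = "septal_ep", e_ep = "e_ep")

#' Specify one simulated group
#'
#' Each variable is given as `c(mean, sd)`; omitted variables are simulated
#' as missing (the perfusion exam, for instance, is skipped in HFrEF
#' subjects for safety). Units: `age` years, `hct` fraction, `ecv` percent,
#' `perf_rest`/`perf_stress` ml/min/g, `ef` percent, `septal_ep` cm/s;
#' `e_a`, `ep_ap`, `e_ep` are ratios.
#'
#' @param label Group label: `"healthy"`, `"HFpEF"` or `"HFrEF"`.
#' @param n Number of subjects (>= 1).
#' @param ... Named `c(mean, sd)` pairs for any of: `age`, `hct`, `ecv`,
#'   `perf_rest`, `perf_stress`, `ef`, `e_a`, `ep_ap`, `septal_ep`, `e_ep`.
#' @return Tibble in long form: `label`, `n`, `variable`, `mean`, `sd`.
#' @export
group_spec <- function(label, n, ...) {
  vars <- list(...)
  if (!length(vars)) stop_cfg("at least one variable must be specified")
  bad <- setdiff(names(vars), COHORT_VARIABLES)
  if (length(bad))
    stop_cfg("unknown cohort variables: ", paste(bad, collapse = ", "))
  if (n < 1) stop_cfg("n must be >= 1")
  rows <- purrr::imap(vars, function(ms, nm) {
    if (length(ms) != 2L || !all(is.finite(ms)))
      stop_cfg("variable ", nm, " must be c(mean, sd) with finite values")
    if (ms[2] < 0) stop_cfg("sd for ", nm, " must be >= 0")
    tibble(label = label, n = as.integer(n), variable = nm,
           mean = ms[1], sd = ms[2])
  })
  dplyr::bind_rows(rows)
}

#' Reference group parameters of the cynomolgus heart-failure cohort
#'
#' Group means and SDs of age, hematocrit, ECV, rest/stress perfusion and
#' the echocardiographic indices for healthy, HFpEF and HFrEF cynomolgus
#' monkeys (n = 10 per group); these are the default conditions the
#' simulator emulates. Perfusion is absent in HFrEF (the stress exam is not
#' performed there for safety).
#'
#' @param n Subjects per group.
#' @return Long-form spec tibble suitable for [generate_cohort()].
#' @export
default_cohort_specs <- function(n = 10) {
  dplyr::bind_rows(
    group_spec("healthy", n,
               age = c(9.6, 1.3), hct = c(0.5140, 0.065),
               ecv = c(20.79, 3.65),
               perf_rest = c(1.31, 0.20), perf_stress = c(2.40, 0.34),
               ef = c(73.96, 4.55), e_a = c(1.26, 0.23),
               ep_ap = c(1.16, 0.25), septal_ep = c(9.50, 2.31),
               e_ep = c(8.04, 2.2)),
    group_spec("HFpEF", n,
               age = c(19.9, 1.4), hct = c(0.5149, 0.050),
               ecv = c(27.06, 3.37),
               perf_rest = c(1.05, 0.21), perf_stress = c(1.28, 0.24),
               ef = c(76.64, 8.72), e_a = c(0.69, 0.03),
               ep_ap = c(0.77, 0.16), septal_ep = c(4.78, 0.77),
               e_ep = c(11.49, 1.42)),
    group_spec("HFrEF", n,
               age = c(16.2, 2.7), hct = c(0.5083, 0.050),
               ecv = c(31.11, 4.50),
               ef = c(47.99, 8.95), e_a = c(0.82, 0.22),
               ep_ap = c(0.67, 0.12), septal_ep = c(5.02, 1.54),
               e_ep = c(10.1, 2.36))
  )
}

#' Simulate a cohort from group specifications
#'
#' Draws every variable independently as Gaussian(mean, sd) within its group
#' (the source tables report only marginal mean +/- SD, so no covariance
#' structure is imposed). Non-physical Gaussian tails are clipped: hematocrit
#' to (0, 1), ejection fraction to (0, 100), and strictly positive
#' quantities (ratios, velocities, flows, age) to a small positive floor.
#' Per-subject MPR is derived as `perf_stress / perf_rest`. An optional linear age-ECV term
#' (`age_ecv_slope`, percent ECV per year of within-group age deviation) can
#' be added to exercise age-adjusted analyses; it preserves the group ECV
#' means.
#'
#' @param specs Long-form spec tibble from [group_spec()] /
#'   [default_cohort_specs()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param age_ecv_slope ECV percent added per year of within-group age
#'   deviation (default 0 = independent draws).
#' @return Tibble with columns `subject_id`, `group`, `age_years`, `hct`,
#'   `ecv_pct`, `perf_rest`, `perf_stress`, `mpr`, `ef_pct`, `e_a`,
#'   `ep_ap`, `septal_ep`, `e_ep`.
#' @export
generate_cohort <- function(specs, seed = NULL, age_ecv_slope = 0) {
  stopifnot(is.data.frame(specs), nrow(specs) > 0)
  if (any(specs$sd < 0)) stop_cfg("sd must be >= 0")
  labels <- unique(specs$label)
  with_seed_if(seed, {
    groups <- purrr::map(labels, function(lab) {
      sp <- specs[specs$label == lab, ]
      n <- sp$n[1]
      draws <- purrr::map(COHORT_VARIABLES, function(v) {
        row <- sp[sp$variable == v, ]
        if (nrow(row) == 0) rep(NA_real_, n)
        else rnorm(n, row$mean, row$sd)
      })
      names(draws) <- COHORT_VARIABLES
      # clip non-physical Gaussian tails: fractions to (0,1), EF to (0,100),
      # strictly positive quantities away from zero
      draws$hct <- pmin(pmax(draws$hct, 1e-6), 1 - 1e-6)
      draws$ef <- pmin(pmax(draws$ef, 1), 99.9)
      for (v in c("e_a", "ep_ap", "septal_ep", "e_ep",
                  "perf_rest", "perf_stress", "age")) {
        draws[[v]] <- pmax(draws[[v]], 0.01)
      }
      if (age_ecv_slope != 0 && !all(is.na(draws$age))) {
        draws$ecv <- draws$ecv + age_ecv_slope * (draws$age - mean(draws$age))
      }
      cols <- c(list(group = rep(lab, n)),
                setNames(draws[COHORT_VARIABLES],
                         COHORT_COLUMNS[COHORT_VARIABLES]))
      tibble::as_tibble(cols)
    })
    cohort <- dplyr::bind_rows(groups)
    cohort$mpr <- cohort$perf_stress / cohort$perf_rest
    cohort <- dplyr::relocate(cohort, "mpr", .after = "perf_stress")
    cohort$subject_id <- sprintf("S%03d", seq_len(nrow(cohort)))
    dplyr::relocate(cohort, "subject_id", .before = "group")
  })
}
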