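# Cohort-level analysis battery: descriptives, ANOVA, age-adjusted ANCOVA,
# ECV correlations (plain and age-partial), and ECV ROC analyses.

REPORT_VARIABLES <- c("ecv_pct", "perf_rest", "perf_stress", "mpr", "ef_pct",
                      "e_a", "ep_ap", "septal_ep", "e_ep", "hct", "age_years")

#' Run the full cohort statistical analysis
#'
#' For every available variable: group mean +/- SD, classical one-way ANOVA
#' p, and (optionally) the age-adjusted ANCOVA p. ECV is additionally
#' correlated with EF, septal E', E/A and E'/A' (Pearson and age-partial),
#' and its discrimination is assessed by ROC with Youden cutoffs for
#' HF-like (HFpEF + HFrEF) vs healthy and HFrEF vs HFpEF. No multiplicity
#' correction is applied (raw two-sided p-values); the number of tests
#' performed is reported.
#'
#' @param cohort Cohort tibble (schema of [generate_cohort()]); a single
#'   group degrades gracefully to descriptives only.
#' @param adjust_age Run the age-adjusted analyses (needs `age_years`).
#' @return A `cmr_cohort_report`: list of tibbles `summary` (per variable
#'   and group), `tests` (ANOVA / ANCOVA p per variable), `correlations`,
#'   plus `roc` (named list of `cmr_roc`), `n_tests`, and `skipped`.
#' @export
run_cohort_analysis <- function(cohort, adjust_age = TRUE) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  groups <- unique(cohort$group)
  vars <- intersect(REPORT_VARIABLES, names(cohort))
  skipped <- character()
  n_tests <- 0L

  summary_tbl <- cohort |>
    dplyr::select(dplyr::all_of(c("group", vars))) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable") |>
    dplyr::group_by(.data$group, .data$variable) |>
    dplyr::summarise(n = sum(!is.na(.data$value)),
                     mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     .groups = "drop")

  tests <- NULL
  cors <- NULL
  rocs <- list()

  if (length(groups) >= 2) {
    test_rows <- purrr::map(vars, function(v) {
      present <- summary_tbl$n[summary_tbl$variable == v] >= 2
      if (sum(present) < 2) {
        skipped <<- c(skipped, v)
        return(NULL)
      }
      res <- one_way_anova(cohort, v, "group")
      n_tests <<- n_tests + 1L
      row <- tibble(variable = v, f = res$f, p_value = res$p_value,
                    k = res$k, n = res$n, p_age_adjusted = NA_real_)
      if (adjust_age && "age_years" %in% names(cohort) && v != "age_years") {
        anc <- tryCatch(
          ancova_age_adjust(cohort, v, "group", "age_years"),
          error = function(e) NULL)
        if (!is.null(anc)) {
          row$p_age_adjusted <- anc$p_value
          n_tests <<- n_tests + 1L
        }
      }
      row
    })
    tests <- dplyr::bind_rows(test_rows)

    if ("ecv_pct" %in% vars) {
      cor_vars <- intersect(c("ef_pct", "septal_ep", "e_a", "ep_ap"),
                            names(cohort))
      cov <- if (adjust_age && "age_years" %in% names(cohort))
        cohort$age_years else NULL
      cors <- purrr::map(cor_vars, function(v) {
        res <- correlations(cohort$ecv_pct, cohort[[v]], covariate = cov)
        n_tests <<- n_tests + 1L + as.integer(!is.null(cov))
        dplyr::bind_cols(tibble(x = "ecv_pct", y = v), res)
      }) |> dplyr::bind_rows()

      cls <- cohort$group
      if (all(c("healthy") %in% cls) && any(cls %in% c("HFpEF", "HFrEF"))) {
        hf <- cls %in% c("HFpEF", "HFrEF")
        rocs$hf_vs_healthy <- roc_youden(cohort$ecv_pct, hf, positive = TRUE)
        n_tests <- n_tests + 1L
      }
      if (all(c("HFpEF", "HFrEF") %in% cls)) {
        sub <- cohort[cls %in% c("HFpEF", "HFrEF"), ]
        rocs$hfref_vs_hfpef <- roc_youden(sub$ecv_pct, sub$group,
                                          positive = "HFrEF")
        n_tests <- n_tests + 1L
      }
    }
  } else {
    inform("single group: reporting descriptives only")
  }

  structure(
    list(summary = summary_tbl, tests = tests, correlations = cors,
         roc = rocs, n_tests = n_tests, skipped = unique(skipped),
         groups = groups),
    class = "cmr_cohort_report"
  )
}

#' @export
print.cmr_cohort_report <- function(x, ...) {
  cat(sprintf("<cmr_cohort_report> groups: %s; %d tests performed (no multiplicity correction)\n",
              paste(x$groups, collapse = ", "), x$n_tests))
  if (!is.null(x$tests)) {
    cat("\nGroup comparisons:\n")
    print(x$tests, n = Inf)
  }
  if (!is.null(x$correlations)) {
    cat("\nECV correlations:\n")
    print(x$correlations, n = Inf)
  }
  for (nm in names(x$roc)) {
    cat("\nROC", nm, ":\n")
    print(x$roc[[nm]])
  }
  if (length(x$skipped))
    cat("\nskipped (insufficient groups with data):",
        paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Renders `report.json` (all statistics), `summary.csv` (group means/SDs in
#' a table layout) and `roc.csv` (FPR/TPR points of every ROC analysis).
#'
#' @param report A `cmr_cohort_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cmr_cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(json = file.path(dir, "report.json"),
             summary = file.path(dir, "summary.csv"),
             roc = file.path(dir, "roc.csv"))
  payload <- list(
    groups = report$groups,
    n_tests = report$n_tests,
    summary = report$summary,
    tests = report$tests,
    correlations = report$correlations,
    roc = purrr::map(report$roc, function(r)
      as.list(glance(r))),
    skipped = report$skipped
  )
  jsonlite::write_json(payload, paths["json"], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  readr::write_csv(report$summary, paths["summary"])
  roc_pts <- purrr::imap(report$roc, function(r, nm)
    dplyr::mutate(r$points, analysis = nm, .before = 1))
  readr::write_csv(dplyr::bind_rows(roc_pts), paths["roc"])
  invisible(paths)
}
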