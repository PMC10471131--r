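# Echocardiographic group classification. Thresholds are the monkey-specific
# criteria used to phenotype the cohort: EF < 65% defines HFrEF; otherwise a
# subject with at least two of three diastolic-dysfunction criteria is HFpEF.

#' Classify a subject from echocardiographic scalars
#'
#' Rules: `ef_pct < 65` gives HFrEF. Otherwise the three diastolic criteria
#' are counted: (1) `ep_ap` or `e_a` ratio below 0.8 or above 3;
#' (2) septal E' below 7 cm/s; (3) E/E' above 10. Two or more give HFpEF,
#' fewer give healthy.
#'
#' @param ef_pct Ejection fraction in percent, in (0, 100).
#' @param e_a Mitral inflow E/A ratio (> 0).
#' @param ep_ap Tissue-Doppler E'/A' ratio (> 0).
#' @param septal_ep Septal E' velocity in cm/s (> 0).
#' @param e_ep E/E' ratio (> 0).
#' @return Character vector in `{"healthy", "HFpEF", "HFrEF"}` (vectorised).
#' @export
classify_subject <- function(ef_pct, e_a, ep_ap, septal_ep, e_ep) {
  args <- list(ef_pct = ef_pct, e_a = e_a, ep_ap = ep_ap,
               septal_ep = septal_ep, e_ep = e_ep)
  for (nm in names(args)) {
    if (any(is.na(args[[nm]]))) stop_cfg("missing values in ", nm)
  }
  if (any(ef_pct <= 0 | ef_pct >= 100)) stop_cfg("ef_pct must be in (0, 100)")
  if (any(e_a <= 0 | ep_ap <= 0 | septal_ep <= 0 | e_ep <= 0))
    stop_cfg("ratios and velocities must be positive")
  out_of_band <- function(x) x < 0.8 | x > 3
  crit1 <- out_of_band(ep_ap) | out_of_band(e_a)
  crit2 <- septal_ep < 7
  crit3 <- e_ep > 10
  n_crit <- crit1 + crit2 + crit3
  dplyr::case_when(
    ef_pct < 65 ~ "HFrEF",
    n_crit >= 2 ~ "HFpEF",
    .default = "healthy"
  )
}

#' Classify every subject of a cohort table
#'
#' Data-frame-first wrapper around [classify_subject()]: adds a
#' `class` column from the echo columns of a cohort tibble (schema of
#' [generate_cohort()]).
#'
#' @param data Cohort tibble with columns `ef_pct`, `e_a`, `ep_ap`,
#'   `septal_ep`, `e_ep`.
#' @return `data` with an added character column `class`.
#' @export
classify_cohort <- function(data) {
  needed <- c("ef_pct", "e_a", "ep_ap", "septal_ep", "e_ep")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop_cfg("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  dplyr::mutate(data,
                class = classify_subject(.data$ef_pct, .data$e_a, .data$ep_ap,
                                         .data$septal_ep, .data$e_ep))
}
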