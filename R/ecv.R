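# Extracellular volume fraction from pre/post-contrast T1 and hematocrit:
# ECV = (1 - Hct) * dR1_myo / dR1_blood, with R1 = 1/T1.

#' Change in longitudinal relaxation rate across contrast
#'
#' `delta_r1(t1_pre, t1_post) = 1/t1_post - 1/t1_pre`, in 1/ms.
#'
#' @param t1_pre,t1_post T1 in ms; both must be positive. Vectorised.
#' @export
delta_r1 <- function(t1_pre, t1_post) {
  if (any(t1_pre <= 0, na.rm = TRUE) || any(t1_post <= 0, na.rm = TRUE))
    stop_cfg("T1 values must be positive")
  1 / t1_post - 1 / t1_pre
}

#' Extracellular volume fraction from four T1 values and hematocrit
#'
#' `ECV = (1 - hct) * delta_r1(myo) / delta_r1(blood)`. The result is a
#' fraction; multiply by 100 for the percent convention used in reports.
#' Values outside `[0, 1]` (or a non-positive blood delta-R1) are flagged
#' invalid rather than clipped.
#'
#' @param t1_pre_myo,t1_post_myo Myocardial T1 (ms) pre/post contrast.
#' @param t1_pre_blood,t1_post_blood Blood-pool T1 (ms) pre/post contrast.
#' @param hct Hematocrit fraction in (0, 1).
#' @return ECV fraction (vectorised over the myocardial T1s), with attribute
#'   `valid`; invalid entries are `NA`.
#' @export
compute_ecv_value <- function(t1_pre_myo, t1_post_myo,
                              t1_pre_blood, t1_post_blood, hct) {
  if (any(hct <= 0) || any(hct >= 1))
    stop_cfg("hct must be a fraction strictly inside (0, 1)")
  dr1_myo <- delta_r1(t1_pre_myo, t1_post_myo)
  dr1_blood <- delta_r1(t1_pre_blood, t1_post_blood)
  valid <- dr1_blood > 0
  ecv <- ifelse(valid, (1 - hct) * dr1_myo / dr1_blood, NA_real_)
  valid <- valid & !is.na(ecv) & ecv >= 0 & ecv <= 1
  ecv[!valid] <- NA_real_
  attr(ecv, "valid") <- valid
  ecv
}

#' Pixel-wise ECV map from co-registered T1 maps
#'
#' Computes ECV over the myocardial mask using a single blood delta-R1 taken
#' from blood-pool ROI means (pixel-wise blood values are avoided because of
#' flow artifacts). Pixels invalid in either T1 map, or with ECV outside
#' `[0, 1]`, are flagged and excluded from ROI summaries.
#'
#' @param t1_pre_map,t1_post_map `cmr_map`s (or matrices) of T1 in ms.
#' @param blood_roi_pre_mean,blood_roi_post_mean Blood-pool ROI mean T1 (ms).
#' @param hct Hematocrit fraction in (0, 1); values > 1 are interpreted as
#'   percent and divided by 100 (with a message), matching the percent
#'   convention of cohort tables.
#' @param myo_mask Logical matrix; defaults to the pre-contrast map's mask.
#' @return A `cmr_map` of ECV as a fraction.
#' @export
compute_ecv_map <- function(t1_pre_map, t1_post_map,
                            blood_roi_pre_mean, blood_roi_post_mean,
                            hct, myo_mask = NULL) {
  get_vals <- function(m) if (inherits(m, "cmr_map")) m$values else m
  get_valid <- function(m) if (inherits(m, "cmr_map")) m$valid else !is.na(m)
  pre <- get_vals(t1_pre_map); post <- get_vals(t1_post_map)
  if (!all(dim(pre) == dim(post)))
    stop_cfg("pre and post T1 maps must have the same shape")
  if (is.null(myo_mask)) {
    if (!inherits(t1_pre_map, "cmr_map"))
      stop_cfg("myo_mask is required when maps are plain matrices")
    myo_mask <- t1_pre_map$mask
  }
  if (!all(dim(myo_mask) == dim(pre))) stop_cfg("mask shape mismatch")
  if (hct > 1) {
    inform(sprintf("hct = %.3g interpreted as percent -> %.3f", hct, hct / 100))
    hct <- hct / 100
  }
  check_scalar(hct, "hct", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  dr1_blood <- delta_r1(blood_roi_pre_mean, blood_roi_post_mean)
  if (dr1_blood <= 0) stop_cfg("blood delta-R1 must be positive")

  ok_in <- myo_mask & get_valid(t1_pre_map) & get_valid(t1_post_map) &
    !is.na(pre) & !is.na(post) & pre > 0 & post > 0
  values <- matrix(NA_real_, nrow(pre), ncol(pre))
  values[ok_in] <- (1 - hct) * delta_r1(pre[ok_in], post[ok_in]) / dr1_blood
  valid <- ok_in & !is.na(values) & values >= 0 & values <= 1
  values[!valid] <- NA_real_
  n_excl <- sum(myo_mask) - sum(valid)
  new_cmr_map(values, valid, myo_mask, "ecv", "fraction",
              meta = list(hct = hct, blood_delta_r1 = dr1_blood,
                          n_excluded = n_excl))
}
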