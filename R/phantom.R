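# Digital short-axis heart phantom: blood pool disc + myocardial annulus on a
# background, with per-pixel ground-truth tissue parameters.

#' Geometry of the digital short-axis phantom
#'
#' Describes a mid-ventricular short-axis slice as concentric discs: a blood
#' pool of radius `blood_radius` inside a myocardial annulus spanning
#' `myo_inner_radius`..`myo_outer_radius` pixels, centred at `lv_center`.
#'
#' @param image_size Integer vector (rows, cols).
#' @param lv_center Pixel coordinates (row, col) of the LV centre; defaults to
#'   the image centre.
#' @param blood_radius,myo_inner_radius,myo_outer_radius Radii in pixels with
#'   `blood_radius < myo_inner_radius < myo_outer_radius`.
#' @param pixel_spacing Pixel size in mm (isotropic).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(image_size = c(128L, 128L),
                         lv_center = (image_size + 1) / 2,
                         blood_radius = 12,
                         myo_inner_radius = 18,
                         myo_outer_radius = 28,
                         pixel_spacing = 1.0) {
  if (length(image_size) != 2L || any(image_size < 8))
    stop_cfg("image_size must be two integers >= 8")
  check_scalar(blood_radius, "blood_radius", lower = 0, strict_lower = TRUE)
  check_scalar(myo_inner_radius, "myo_inner_radius", lower = 0, strict_lower = TRUE)
  check_scalar(myo_outer_radius, "myo_outer_radius", lower = 0, strict_lower = TRUE)
  check_scalar(pixel_spacing, "pixel_spacing", lower = 0, strict_lower = TRUE)
  if (!(blood_radius < myo_inner_radius && myo_inner_radius < myo_outer_radius))
    stop_cfg("radii must satisfy blood_radius < myo_inner_radius < myo_outer_radius")
  margin <- c(lv_center[1], image_size[1] - lv_center[1] + 1,
              lv_center[2], image_size[2] - lv_center[2] + 1)
  if (myo_outer_radius > min(margin))
    stop_cfg("myocardial annulus does not fit inside the image bounds")
  structure(
    list(image_size = as.integer(image_size), lv_center = as.numeric(lv_center),
         blood_radius = blood_radius, myo_inner_radius = myo_inner_radius,
         myo_outer_radius = myo_outer_radius, pixel_spacing = pixel_spacing),
    class = "phantom_spec"
  )
}

#' Ground-truth tissue parameters for the phantom
#'
#' Longitudinal relaxation times (ms) for myocardium and blood before and
#' after contrast, serum hematocrit (fraction), and rest/stress myocardial
#' blood flow (ml/min/g). Native T1 values default to typical 1.5 T
#' myocardium/blood; post-contrast values to the equilibrium shortening seen
#' 15-20 min after a gadolinium bolus.
#'
#' @param t1_pre_myo,t1_post_myo,t1_pre_blood,t1_post_blood T1 in ms.
#' @param hct Hematocrit as a fraction in (0, 1).
#' @param flow_rest,flow_stress Myocardial blood flow in ml/min/g.
#' @return A `tissue_truth` object. Its implied ground-truth ECV (fraction)
#'   is attached as field `ecv`.
#' @export
tissue_truth <- function(t1_pre_myo = 1200, t1_post_myo = 600,
                         t1_pre_blood = 1600, t1_post_blood = 400,
                         hct = 0.51,
                         flow_rest = 1.31, flow_stress = 2.40) {
  for (nm in c("t1_pre_myo", "t1_post_myo", "t1_pre_blood", "t1_post_blood"))
    check_scalar(get(nm), nm, lower = 0, strict_lower = TRUE)
  if (t1_post_myo >= t1_pre_myo || t1_post_blood >= t1_pre_blood)
    stop_cfg("post-contrast T1 must be below pre-contrast T1")
  check_scalar(hct, "hct", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(flow_rest, "flow_rest", lower = 0, strict_lower = TRUE)
  check_scalar(flow_stress, "flow_stress", lower = 0, strict_lower = TRUE)
  ecv <- compute_ecv_value(t1_pre_myo, t1_post_myo, t1_pre_blood, t1_post_blood, hct)
  structure(
    list(t1_pre_myo = t1_pre_myo, t1_post_myo = t1_post_myo,
         t1_pre_blood = t1_pre_blood, t1_post_blood = t1_post_blood,
         hct = hct, flow_rest = flow_rest, flow_stress = flow_stress,
         ecv = as.numeric(ecv)),
    class = "tissue_truth"
  )
}

#' Tissue truth with a prescribed ground-truth ECV
#'
#' Solves for the post-contrast myocardial T1 that makes the phantom's true
#' ECV equal `ecv`, holding the other T1 values and hematocrit fixed. Used to
#' build phantoms at the group ECV levels of the cohort being emulated.
#'
#' @param ecv Target extracellular volume fraction in (0, 1).
#' @inheritParams tissue_truth
#' @export
tissue_truth_from_ecv <- function(ecv, hct = 0.51,
                                  t1_pre_myo = 1200,
                                  t1_pre_blood = 1600, t1_post_blood = 400,
                                  flow_rest = 1.31, flow_stress = 2.40) {
  check_scalar(ecv, "ecv", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  dr1_blood <- delta_r1(t1_pre_blood, t1_post_blood)
  dr1_myo <- ecv * dr1_blood / (1 - hct)
  t1_post_myo <- 1 / (dr1_myo + 1 / t1_pre_myo)
  tissue_truth(t1_pre_myo = t1_pre_myo, t1_post_myo = t1_post_myo,
               t1_pre_blood = t1_pre_blood, t1_post_blood = t1_post_blood,
               hct = hct, flow_rest = flow_rest, flow_stress = flow_stress)
}

#' Rasterise the phantom into a label map and ground-truth parameter maps
#'
#' Every pixel receives exactly one label: 0 background, 1 blood pool,
#' 2 myocardium (a pixel belongs to a region when its centre lies within the
#' region's radii). T1 and flow maps are constant within each label.
#'
#' @param spec A [phantom_spec()].
#' @param truth A [tissue_truth()].
#' @return A `cmr_phantom`: list with `labels` (integer matrix), logical masks
#'   `myo_mask` / `blood_mask`, per-pixel maps `t1_pre`, `t1_post`,
#'   `flow_rest`, `flow_stress` (ms / ml/min/g; NA outside tissue), plus the
#'   `spec` and `truth` used.
#' @export
make_phantom <- function(spec = phantom_spec(), truth = tissue_truth()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(truth, "tissue_truth"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  r <- sqrt(outer((seq_len(nr) - spec$lv_center[1])^2,
                  (seq_len(nc) - spec$lv_center[2])^2, `+`))
  labels <- matrix(0L, nr, nc)
  labels[r <= spec$blood_radius] <- 1L
  labels[r >= spec$myo_inner_radius & r <= spec$myo_outer_radius] <- 2L
  myo <- labels == 2L
  blood <- labels == 1L
  if (!any(myo)) stop_cfg("myocardial mask is empty for this geometry")

  fill <- function(myo_val, blood_val) {
    m <- matrix(NA_real_, nr, nc)
    m[myo] <- myo_val
    m[blood] <- blood_val
    m
  }
  structure(
    list(labels = labels, myo_mask = myo, blood_mask = blood,
         t1_pre = fill(truth$t1_pre_myo, truth$t1_pre_blood),
         t1_post = fill(truth$t1_post_myo, truth$t1_post_blood),
         flow_rest = fill(truth$flow_rest, 0),
         flow_stress = fill(truth$flow_stress, 0),
         spec = spec, truth = truth),
    class = "cmr_phantom"
  )
}

#' @export
print.cmr_phantom <- function(x, ...) {
  cat(sprintf("<cmr_phantom> %d x %d, blood %d px, myocardium %d px (true ECV %.2f%%)\n",
              nrow(x$labels), ncol(x$labels), sum(x$blood_mask), sum(x$myo_mask),
              100 * x$truth$ecv))
  invisible(x)
}
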