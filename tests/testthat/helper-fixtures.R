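# Shared fixtures: small phantoms and cohort specs sized for fast tests.

tiny_phantom <- function(ecv = NULL, hct = 0.51, ...) {
  spec <- phantom_spec(image_size = c(32L, 32L), lv_center = c(16.5, 16.5),
                       blood_radius = 4, myo_inner_radius = 6,
                       myo_outer_radius = 10)
  truth <- if (is.null(ecv)) tissue_truth(hct = hct, ...)
           else tissue_truth_from_ecv(ecv, hct = hct, ...)
  make_phantom(spec, truth)
}

# ECV-only group specs at the reference group levels, for fast replicate loops
ecv_only_specs <- function(n = 10) {
  dplyr::bind_rows(
    group_spec("healthy", n, ecv = c(20.79, 3.65)),
    group_spec("HFpEF", n, ecv = c(27.06, 3.37)),
    group_spec("HFrEF", n, ecv = c(31.11, 4.50))
  )
}

# brute-force AUC: concordant pairs + half ties over all pos/neg pairs
pairwise_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  total <- 0
  for (p in sp) for (q in sn) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(sp) * length(sn))
}
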