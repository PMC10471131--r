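# Empirical ROC analysis with Youden-index cutoff selection. The AUC uses
# the midrank (Mann-Whitney) convention so ties contribute 1/2; the cutoff
# convention is "call diseased when score >= cutoff", with J-ties broken
# toward the lowest cutoff so output is deterministic.

#' Empirical ROC curve, AUC and Youden cutoff
#'
#' Orientation is fixed, not auto-flipped: higher scores are taken to
#' indicate the diseased (positive) class, matching a marker like ECV that
#' rises with disease. When the empirical AUC falls below 0.5 the result
#' carries an orientation note instead of silently reversing the marker.
#'
#' @param scores Numeric marker values.
#' @param labels Class labels with exactly two observed classes (logical
#'   allowed, `TRUE` = positive).
#' @param positive The diseased-class label; defaults to `TRUE` for logical
#'   labels, otherwise the last sorted unique value.
#' @return A `cmr_roc`: `auc`, `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`, `points` (threshold/FPR/TPR tibble), class counts, and
#'   `orientation_note` (NA unless AUC < 0.5).
#' @export
roc_youden <- function(scores, labels, positive = NULL) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop_cfg("labels must contain exactly two classes")
  if (is.null(positive)) {
    positive <- if (is.logical(labels)) TRUE else classes[2]
  }
  if (!positive %in% classes) stop_cfg("positive class not present in labels")
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_cfg("both classes must be present")

  # midrank AUC == Mann-Whitney U / (n1 * n0)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores))
  sens <- vapply(thr, function(th) mean(scores[pos] >= th), 0)
  spec <- vapply(thr, function(th) mean(scores[!pos] < th), 0)
  j <- sens + spec - 1
  best <- which.max(j)  # ties resolve to the lowest threshold
  points <- tibble(threshold = c(-Inf, thr, Inf),
                   tpr = c(1, sens, 0),
                   fpr = c(1, 1 - spec, 0))
  points <- dplyr::arrange(points, .data$fpr, .data$tpr)
  structure(
    list(auc = auc, cutoff = thr[best], sensitivity = sens[best],
         specificity = spec[best], youden_j = j[best], points = points,
         n_pos = n1, n_neg = n0, positive = positive,
         orientation_note = if (auc < 0.5)
           "empirical AUC < 0.5: marker orientation may be reversed"
         else NA_character_),
    class = "cmr_roc"
  )
}

#' @export
print.cmr_roc <- function(x, ...) {
  cat(sprintf("<cmr_roc> AUC = %.3f (%d pos '%s' vs %d neg)\n",
              x$auc, x$n_pos, x$positive, x$n_neg))
  cat(sprintf("  Youden cutoff %.4g: sensitivity %.3f, specificity %.3f, J = %.3f\n",
              x$cutoff, x$sensitivity, x$specificity, x$youden_j))
  if (!is.na(x$orientation_note)) cat("  note:", x$orientation_note, "\n")
  invisible(x)
}

#' @rdname roc_youden
#' @param x A `cmr_roc`.
#' @param ... Unused.
#' @method tidy cmr_roc
#' @export
tidy.cmr_roc <- function(x, ...) x$points

#' @rdname roc_youden
#' @method glance cmr_roc
#' @export
glance.cmr_roc <- function(x, ...) {
  tibble(auc = x$auc, cutoff = x$cutoff, sensitivity = x$sensitivity,
         specificity = x$specificity, youden_j = x$youden_j,
         n_pos = x$n_pos, n_neg = x$n_neg)
}
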