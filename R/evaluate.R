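# Segmentation agreement statistics: pixel confusion metrics, Hausdorff
# distance between boundaries, Bland-Altman limits of agreement and area
# regression.

#' Pixel confusion counts between a predicted and a reference mask
#'
#' @param pred,truth Logical `H x W` matrices of the same shape.
#' @param valid Optional logical matrix restricting the evaluation (pixels
#'   excluded by vignette removal carry no meaningful prediction).
#' @return List of class `confusion_counts` with integers `TP`, `TN`,
#'   `FP`, `FN`; their sum equals the number of evaluated pixels.
#' @export
confusion_counts <- function(pred, truth, valid = NULL) {
  assert_mask(pred); assert_mask(truth, dim(pred), arg = "truth")
  if (!is.null(valid)) {
    assert_mask(valid, dim(pred), arg = "valid")
    pred <- pred[valid]; truth <- truth[valid]
  }
  out <- list(TP = sum(pred & truth), TN = sum(!pred & !truth),
              FP = sum(pred & !truth), FN = sum(!pred & truth))
  class(out) <- "confusion_counts"
  out
}

#' Confusion-based segmentation metrics
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, Jaccard `TP/(TP+FP+FN)`, Dice `2TP/(2TP+FP+FN)` and the
#' F-measure (harmonic mean of precision and recall, which equals Dice for
#' binary masks).  A ratio with a zero denominator is reported as `NaN`
#' and its name is listed in the `undefined` field — never silently 0.
#'
#' @param cc A `confusion_counts` object.
#' @return List of class `seg_metrics` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `jaccard`, `dice`, `f_measure`,
#'   `undefined` (character vector).
#' @export
seg_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  tot <- cc$TP + cc$TN + cc$FP + cc$FN
  if (tot == 0) stop("confusion counts are all zero", call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NaN
  m <- list(accuracy = (cc$TP + cc$TN) / tot,
            sensitivity = ratio(cc$TP, cc$TP + cc$FN),
            specificity = ratio(cc$TN, cc$TN + cc$FP),
            jaccard = ratio(cc$TP, cc$TP + cc$FP + cc$FN),
            dice = ratio(2 * cc$TP, 2 * cc$TP + cc$FP + cc$FN))
  precision <- ratio(cc$TP, cc$TP + cc$FP)
  recall <- m$sensitivity
  m$f_measure <- if (is.nan(precision) || is.nan(recall) ||
                     precision + recall == 0) NaN
                 else 2 * precision * recall / (precision + recall)
  m$undefined <- names(m)[vapply(m[names(m) != "undefined"], is.nan, TRUE)]
  class(m) <- "seg_metrics"
  m
}

#' Symmetric Hausdorff distance between mask boundaries
#'
#' Largest boundary-to-boundary disagreement: for each boundary point set
#' (8-connected boundary pixels) the maximum distance to the nearest point
#' of the other set, symmetrized by taking the larger direction.  Reported
#' both in raw Euclidean pixels and normalized by the image diagonal
#' `sqrt(H^2 + W^2)`, a dimensionless 0-to-1 scale comparable across image
#' sizes.
#'
#' @param pred,truth Non-empty logical `H x W` matrices of the same shape.
#' @return List of class `hausdorff` with `raw` (pixels), `norm`
#'   (diagonal-normalized) and `diagonal`.
#' @export
hausdorff_distance <- function(pred, truth) {
  assert_mask(pred); assert_mask(truth, dim(pred), arg = "truth")
  if (!any(pred) || !any(truth))
    stop("Hausdorff distance requires two non-empty masks", call. = FALSE)
  a <- boundary_points(pred)
  b <- boundary_points(truth)
  raw <- max(hausdorff_directed_cpp(a * 1.0, b * 1.0),
             hausdorff_directed_cpp(b * 1.0, a * 1.0))
  diag <- sqrt(sum(dim(pred)^2))
  out <- list(raw = raw, norm = raw / diag, diagonal = diag)
  class(out) <- "hausdorff"
  out
}

#' Bland-Altman and regression agreement of lesion areas
#'
#' Differences `d = pred - truth` give the mean bias, SD and 1.96-SD
#' limits of agreement; ordinary least squares of predicted on reference
#' area gives slope, intercept and Pearson r.  Constant reference areas
#' leave the regression undefined (`NaN`, flagged).
#'
#' @param areas_pred,areas_truth Numeric vectors of equal length >= 3
#'   (areas in pixels^2).
#' @return List of class `agreement_report` with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `slope`, `intercept`, `r`,
#'   `regression_defined`.
#' @export
area_agreement <- function(areas_pred, areas_truth) {
  stopifnot(length(areas_pred) == length(areas_truth),
            length(areas_pred) >= 3)
  d <- areas_pred - areas_truth
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  out <- list(mean_diff = mean_diff, sd_diff = sd_diff,
              loa_low = mean_diff - 1.96 * sd_diff,
              loa_high = mean_diff + 1.96 * sd_diff)
  if (stats::sd(areas_truth) == 0) {
    out$slope <- NaN; out$intercept <- NaN; out$r <- NaN
    out$regression_defined <- FALSE
  } else {
    fit <- stats::lm(areas_pred ~ areas_truth)
    out$slope <- unname(stats::coef(fit)[2])
    out$intercept <- unname(stats::coef(fit)[1])
    out$r <- stats::cor(areas_pred, areas_truth)
    out$regression_defined <- TRUE
  }
  class(out) <- "agreement_report"
  out
}

#' All per-image metrics against a reference mask
#'
#' Convenience wrapper: confusion metrics over the valid region plus the
#' Hausdorff distance (skipped, `NA`, when either mask is empty).
#'
#' @param pred,truth Logical masks of equal shape.
#' @param valid Optional valid-region mask for the confusion counts.
#' @return A `seg_metrics` list extended with `hausdorff_raw` and
#'   `hausdorff_norm`.
#' @export
evaluate_masks <- function(pred, truth, valid = NULL) {
  m <- seg_metrics(confusion_counts(pred, truth, valid))
  if (any(pred) && any(truth)) {
    hd <- hausdorff_distance(pred, truth)
    m$hausdorff_raw <- hd$raw
    m$hausdorff_norm <- hd$norm
  } else {
    m$hausdorff_raw <- NA_real_
    m$hausdorff_norm <- NA_real_
  }
  m
}
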