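# Segmentation evaluation: confusion-matrix rates, Dice overlap, and the
# 95th-percentile Hausdorff distance between mask boundaries.

#' Voxelwise confusion counts
#'
#' @param pred,truth Logical arrays of identical shape.
#' @return List of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth shapes differ")
  pred <- pred != 0; truth <- truth != 0
  structure(list(tp = sum(pred & truth),
                 fp = sum(pred & !truth),
                 tn = sum(!pred & !truth),
                 fn = sum(!pred & truth)),
            class = "confusion_counts")
}

#' Rates derived from confusion counts
#'
#' Accuracy `(tp+tn)/total`, recall `tp/(tp+fn)`, precision `tp/(tp+fp)`,
#' specificity `tn/(tn+fp)` and Dice `2tp/(2tp+fp+fn)`. A rate whose
#' denominator is zero is reported as `NA` (undefined, not 0) and named in
#' the `undefined` field.
#'
#' @param cc A `confusion_counts`.
#' @return List with the five rates plus `undefined` (character vector).
#' @export
seg_rates <- function(cc) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  total <- cc$tp + cc$fp + cc$tn + cc$fn
  out <- list(accuracy = safe(cc$tp + cc$tn, total),
              recall = safe(cc$tp, cc$tp + cc$fn),
              precision = safe(cc$tp, cc$tp + cc$fp),
              specificity = safe(cc$tn, cc$tn + cc$fp),
              dice = safe(2 * cc$tp, 2 * cc$tp + cc$fp + cc$fn))
  out$undefined <- names(out)[vapply(out, function(v)
    is.numeric(v) && is.na(v), logical(1L))]
  out
}

directed_percentile_dist <- function(from, to, prob) {
  # nearest-neighbor distances from each row of `from` to the set `to`,
  # chunked to bound memory; linear-interpolation percentile.
  nf <- nrow(from)
  dmin <- numeric(nf)
  chunk <- max(1L, floor(2e6 / nrow(to)))
  for (start in seq(1L, nf, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nf)
    d2 <- outer(rowSums(from[idx, , drop = FALSE]^2), rowSums(to^2), "+") -
      2 * from[idx, , drop = FALSE] %*% t(to)
    dmin[idx] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  unname(stats::quantile(dmin, probs = prob, type = 7))
}

#' 95th-percentile Hausdorff distance
#'
#' Boundary point sets of both masks (4-connected boundary in 2D,
#' 6-connected in 3D) are extracted, coordinates scaled by `spacing`,
#' directed nearest-neighbour distances computed both ways, and HD95 is the
#' maximum of the two directions' 95th percentiles (linear-interpolation
#' percentile, the BraTS convention). Either mask empty gives `NA` with an
#' `undefined` attribute.
#'
#' @param pred,truth Logical arrays of identical shape, nonempty.
#' @param spacing Optional per-axis physical spacing; default 1 (pixels).
#' @param prob Percentile (default 0.95; 1 gives the full Hausdorff
#'   distance).
#' @return Distance in the `spacing` units.
#' @export
hausdorff95 <- function(pred, truth, spacing = NULL, prob = 0.95) {
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth shapes differ")
  pred <- pred != 0; truth <- truth != 0
  if (!any(pred) || !any(truth)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  nd <- length(dim(pred))
  if (is.null(spacing)) spacing <- rep(1, nd)
  bp <- which(boundary_voxels(pred), arr.ind = TRUE)
  bt <- which(boundary_voxels(truth), arr.ind = TRUE)
  bp <- sweep(matrix(as.numeric(bp), ncol = nd), 2L, spacing, "*")
  bt <- sweep(matrix(as.numeric(bt), ncol = nd), 2L, spacing, "*")
  max(directed_percentile_dist(bp, bt, prob),
      directed_percentile_dist(bt, bp, prob))
}

#' Full segmentation report
#'
#' Confusion rates, Dice, and HD95 for a predicted mask against ground
#' truth. When a `region` mask is supplied (typically the brain mask) the
#' confusion rates are computed over region voxels only, so accuracy is not
#' inflated by background true negatives; Dice and HD95 are unaffected by
#' the region restriction. Whole-array rates are always included as
#' `accuracy_whole`.
#'
#' @param pred,truth Logical arrays of identical shape.
#' @param spacing Optional physical spacing for HD95.
#' @param region Optional logical array restricting the rate domain.
#' @return List with all metrics.
#' @export
evaluate_segmentation <- function(pred, truth, spacing = NULL, region = NULL) {
  pred <- pred != 0; truth <- truth != 0
  cc_whole <- confusion_counts(pred, truth)
  rates_whole <- seg_rates(cc_whole)
  if (!is.null(region)) {
    region <- region != 0
    cc <- confusion_counts(pred[region], truth[region])
    # confusion_counts needs matching dims; vectors share length
    rates <- seg_rates(cc)
  } else {
    cc <- cc_whole
    rates <- rates_whole
  }
  hd <- hausdorff95(pred, truth, spacing)
  list(accuracy = rates$accuracy,
       recall = rates$recall,
       precision = rates$precision,
       specificity = rates$specificity,
       dice = rates_whole$dice,
       hd95 = as.numeric(hd),
       accuracy_whole = rates_whole$accuracy,
       undefined = union(rates$undefined,
                         if (isTRUE(attr(hd, "undefined"))) "hd95" else NULL),
       counts = cc_whole)
}
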