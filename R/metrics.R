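#' Pixel-level contingency counts
#'
#' Counts true/false positives/negatives between a predicted and a
#' ground-truth binary mask, optionally restricted to a region of
#' interest (e.g. the circular field of view of a fundus image).
#'
#' @param pred,gt Binary masks of one shape.
#' @param roi Optional binary mask; only pixels with `roi == 1` are
#'   counted.
#' @return An object of class `contingency`: list with integer `TP`,
#'   `FP`, `TN`, `FN` summing to the number of evaluated pixels.
#' @export
contingency <- function(pred, gt, roi = NULL) {
  if (!identical(dim(pred), dim(gt)))
    stop("pred and gt must have the same shape")
  p <- as.logical(pred)
  g <- as.logical(gt)
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(gt)))
      stop("roi must have the same shape as the masks")
    keep <- as.logical(roi)
    p <- p[keep]
    g <- g[keep]
  }
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 TN = sum(!p & !g), FN = sum(!p & g)),
            class = "contingency")
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warning("degenerate denominator for ", what, "; returning 0")
    return(0)
  }
  num / den
}

#' Scalar segmentation metrics from contingency counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy,
#' Dice similarity coefficient `2TP/(2TP+FP+FN)`, Jaccard index
#' `TP/(TP+FP+FN)` and Matthews correlation coefficient, all reported
#' as percentages (MCC in `[-100, 100]`).  Degenerate denominators
#' yield 0 with a warning.
#'
#' @param counts A [contingency()] object (or list with TP/FP/TN/FN).
#' @return Named numeric vector `SEN, SPE, ACC, DSC, JAC, MCC` in
#'   percent.
#' @export
scalar_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  100 * c(SEN = safe_div(TP, TP + FN, "SEN"),
          SPE = safe_div(TN, TN + FP, "SPE"),
          ACC = safe_div(TP + TN, total, "ACC"),
          DSC = safe_div(2 * TP, 2 * TP + FP + FN, "DSC"),
          JAC = safe_div(TP, TP + FP + FN, "JAC"),
          MCC = safe_div(TP * TN - FP * FN, mcc_den, "MCC"))
}

#' ROC and precision--recall curves with AUC
#'
#' Sweeps a threshold over every distinct score of a foreground
#' probability map against a binary ground truth, producing the ROC
#' curve (with trapezoid-rule AUC) and the precision--recall curve.
#'
#' @param prob Numeric scores in `[0, 1]` (any shape).
#' @param gt Binary ground truth of matching length.
#' @param roi Optional binary mask restricting the evaluated pixels.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`),
#'   `auc` in `[0, 1]`, and `pr` (data frame `recall`, `precision`).
#' @export
roc_pr_curves <- function(prob, gt, roi = NULL) {
  p <- as.numeric(prob)
  g <- as.numeric(gt) > 0
  if (length(p) != length(g)) stop("prob and gt must have matching length")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (!is.null(roi)) {
    keep <- as.logical(roi)
    p <- p[keep]
    g <- g[keep]
  }
  P <- sum(g)
  Nn <- sum(!g)
  if (P == 0 || Nn == 0)
    stop("ROC/PR undefined: ground truth contains a single class")
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]
  gs <- g[ord]
  cum_tp <- cumsum(gs)
  cum_fp <- cumsum(!gs)
  last <- c(ps[-1] != ps[-length(ps)], TRUE)  # last index of each score
  tp <- cum_tp[last]
  fp <- cum_fp[last]
  thr <- ps[last]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / Nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  precision <- tp / (tp + fp)
  recall <- tp / P
  list(roc = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       auc = auc,
       pr = data.frame(recall = recall, precision = precision))
}

#' Weighted aggregation of per-item metrics
#'
#' Summarizes per-item metric vectors (one test image or volume each)
#' into a weighted average, the weights being the item sample sizes
#' (e.g. pixel or slice counts), and returns the per-item table for
#' distribution plots.
#'
#' @param per_item List of equal-length named numeric vectors, or a
#'   data frame with one row per item.
#' @param weights Numeric weights, one per item; uniform by default.
#' @return List with `summary` (named weighted means) and `per_item`
#'   (data frame, one row per item).
#' @export
aggregate_metrics <- function(per_item, weights = NULL) {
  tab <- if (is.data.frame(per_item)) per_item
         else as.data.frame(do.call(rbind, per_item))
  n <- nrow(tab)
  if (n == 0) stop("no items to aggregate")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop("weights must match the number of items")
  w <- weights / sum(weights)
  list(summary = vapply(tab, function(col) sum(col * w), numeric(1)),
       per_item = tab)
}
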