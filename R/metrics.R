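# Pixel-wise evaluation against a reference segmentation: confusion
# counts, Se/Sp/Acc/Auc, Dice, difference maps, and the paired t-test used
# for model comparison.  Auc here is the (Se + Sp) / 2 summary, not a
# threshold-sweep ROC integral.

#' Confusion counts
#'
#' Counts true/false positives/negatives of a predicted vessel mask
#' against a reference, optionally restricted to a region of interest.
#'
#' @param pred,truth {0,1} matrices of the same shape.
#' @param roi Optional {0,1} matrix; only pixels with `roi == 1` are
#'   counted (default: all pixels).
#' @return List of class `mgdf_confusion` with integers `tp, fp, tn, fn`.
#' @export
confusion_counts <- function(pred, truth, roi = NULL) {
  check_binary_mask(pred, "pred")
  check_binary_mask(truth, "truth")
  check_same_shape(pred, truth, "pred", "truth")
  if (!is.null(roi)) {
    check_binary_mask(roi, "roi")
    check_same_shape(pred, roi, "pred", "roi")
    keep <- roi == 1
    pred <- pred[keep]; truth <- truth[keep]
  }
  structure(list(tp = sum(pred == 1 & truth == 1),
                 fp = sum(pred == 1 & truth == 0),
                 tn = sum(pred == 0 & truth == 0),
                 fn = sum(pred == 0 & truth == 1)),
            class = "mgdf_confusion")
}

#' Segmentation performance metrics
#'
#' Sensitivity `Se = tp / (tp + fn)`, specificity `Sp = tn / (tn + fp)`,
#' accuracy `Acc = (tp + tn) / n`, and the summary
#' `Auc = (Se + Sp) / 2`.
#'
#' @param counts An `mgdf_confusion` (or a list with `tp, fp, tn, fn`).
#' @return List of class `mgdf_metrics` with `se, sp, acc, auc` in
#'   \[0, 1\].
#' @export
performance_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fn == 0)
    stop_mgdf("sensitivity undefined: no positive pixels in truth",
              class = "mgdf_metric_error")
  if (tn + fp == 0)
    stop_mgdf("specificity undefined: no negative pixels in truth",
              class = "mgdf_metric_error")
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  structure(list(se = se, sp = sp,
                 acc = (tp + tn) / (tp + fp + tn + fn),
                 auc = (se + sp) / 2),
            class = "mgdf_metrics")
}

#' @export
print.mgdf_metrics <- function(x, digits = 3L, ...) {
  cat(sprintf("Se %.3f  Sp %.3f  Acc %.3f  Auc %.3f\n",
              round_half_up(x$se, digits), round_half_up(x$sp, digits),
              round_half_up(x$acc, digits), round_half_up(x$auc, digits)))
  invisible(x)
}

#' Dice similarity coefficient
#'
#' `2 tp / (2 tp + fp + fn)`; 1 for identical masks.  Defined as 1 when
#' both masks are empty.
#'
#' @inheritParams confusion_counts
#' @return Scalar in \[0, 1\].
#' @export
dice_score <- function(pred, truth, roi = NULL) {
  cc <- confusion_counts(pred, truth, roi)
  denom <- 2 * cc$tp + cc$fp + cc$fn
  if (denom == 0) return(1)
  2 * cc$tp / denom
}

#' Paired t-test
#'
#' Classical paired two-sided t-test on per-image metric values from two
#' methods.
#'
#' @param a,b Numeric vectors of equal length (n >= 2).
#' @return List with `t` (statistic), `p` (two-sided p-value), `df`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b))
    stop_mgdf("paired samples must have equal length",
              class = "mgdf_validation_error")
  if (length(a) < 2)
    stop_mgdf("paired t-test needs at least two pairs",
              class = "mgdf_validation_error")
  d <- a - b
  if (stats::var(d) == 0)
    stop_mgdf("degenerate paired t-test: differences have zero variance",
              class = "mgdf_metric_error")
  ht <- t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Pixel-wise difference map
#'
#' Labels every pixel of a prediction/reference pair for visual
#' inspection: 0 = true negative, 1 = false positive, 2 = false negative,
#' 3 = true positive.
#'
#' @inheritParams confusion_counts
#' @return Integer matrix of class `mgdf_diffmap` with a `legend`
#'   attribute.
#' @export
difference_map <- function(pred, truth) {
  check_binary_mask(pred, "pred")
  check_binary_mask(truth, "truth")
  check_same_shape(pred, truth, "pred", "truth")
  m <- matrix(0L, nrow(pred), ncol(pred))
  m[pred == 1 & truth == 0] <- 1L
  m[pred == 0 & truth == 1] <- 2L
  m[pred == 1 & truth == 1] <- 3L
  structure(m, legend = c(TN = 0L, FP = 1L, FN = 2L, TP = 3L),
            class = c("mgdf_diffmap", class(m)))
}
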