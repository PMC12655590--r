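#' Segmentation metrics from confusion counts
#'
#' Computes the four standard overlap metrics from aggregated per-class pixel
#' confusion counts:
#' \deqn{IoU = TP / (TP + FP + FN)}
#' \deqn{Dice = 2 TP / (2 TP + FP + FN)}
#' \deqn{Precision = TP / (TP + FP), \quad Recall = TP / (TP + FN)}
#' On aggregated counts the identities `Dice = 2PR/(P+R)` and
#' `Dice = 2 IoU/(1+IoU)` hold exactly. Metrics with an undefined
#' denominator are returned as `NA` and flagged in `undefined`.
#'
#' @param tp,fp,fn non-negative pixel counts (true positive, false positive,
#'   false negative), aggregated over the evaluation set.
#' @return list with `iou`, `dice`, `precision`, `recall`, `undefined`.
#' @export
seg_metrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  undef <- character(0)
  div <- function(num, den, name) {
    if (den <= 0) { undef <<- c(undef, name); return(NA_real_) }
    num / den
  }
  out <- list(
    iou = div(tp, tp + fp + fn, "iou"),
    dice = div(2 * tp, 2 * tp + fp + fn, "dice"),
    precision = div(tp, tp + fp, "precision"),
    recall = div(tp, tp + fn, "recall")
  )
  out$undefined <- undef
  out
}

#' Aggregate confusion counts for one foreground class
#'
#' @param pred,truth integer label maps (or logical masks) of equal shape.
#' @param class the foreground class code to score (ignored for logical
#'   inputs, where `TRUE` is foreground).
#' @return list with `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth, class = 1L) {
  if (!identical(dim(pred), dim(truth)))
    tp_stop("pred and truth must have identical shape", "tp_format_error")
  p <- if (is.logical(pred)) pred else pred == class
  t <- if (is.logical(truth)) truth else truth == class
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t))
}

#' Dice coefficient from precision and recall / from IoU
#'
#' Convenience forms of the confusion-count identities: on aggregated pixel
#' counts, `Dice = 2PR/(P+R)` (the F1 identity) and `Dice = 2 IoU/(1+IoU)`.
#'
#' @param precision,recall,iou metric values in `[0, 1]`.
#' @return Dice coefficient.
#' @export
dice_from_pr <- function(precision, recall) 2 * precision * recall / (precision + recall)

#' @rdname dice_from_pr
#' @export
dice_from_iou <- function(iou) 2 * iou / (1 + iou)

#' Regression metrics for paired measurements
#'
#' \deqn{RMSE = \sqrt{\frac{1}{N}\sum (y_i - \hat y_i)^2}, \quad
#'       MAE = \frac{1}{N}\sum |y_i - \hat y_i|, \quad
#'       R^2 = 1 - \frac{\sum(\hat y_i - y_i)^2}{\sum(y_i - \bar y)^2}}
#' `R^2` may be negative; with fewer than two observations or zero variance
#' in `y` it is `NA` and flagged.
#'
#' @param y ground-truth values.
#' @param yhat predicted values, same length as `y`.
#' @return list with `rmse`, `mae`, `r2`, `n`, `undefined`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat))
    tp_stop("y and yhat must have equal length", "tp_format_error")
  if (length(y) < 1L) tp_stop("need at least one pair", "tp_format_error")
  err <- y - yhat
  undef <- character(0)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (length(y) < 2L || ss_tot <= 0) { undef <- c(undef, "r2"); NA_real_ }
        else 1 - sum(err^2) / ss_tot
  list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)), r2 = r2,
       n = length(y), undefined = undef)
}

#' Evaluate predicted label maps against ground truth
#'
#' Aggregates pixel confusion counts over the whole set (not per-image
#' means) for one foreground class, then applies [seg_metrics()].
#'
#' @param preds,truths lists of label maps of identical shapes.
#' @param class foreground class code.
#' @return list of metrics as in [seg_metrics()], plus the raw counts.
#' @export
evaluate_segmentation <- function(preds, truths, class = 1L) {
  stopifnot(length(preds) == length(truths))
  tp <- fp <- fn <- 0
  for (i in seq_along(preds)) {
    cc <- confusion_counts(preds[[i]], truths[[i]], class)
    tp <- tp + cc$tp; fp <- fp + cc$fp; fn <- fn + cc$fn
  }
  out <- seg_metrics(tp, fp, fn)
  out$counts <- list(tp = tp, fp = fp, fn = fn)
  out
}
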