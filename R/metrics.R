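# Exact evaluation metrics: confusion-count formulas, Dice/IoU, exact
# symmetric Hausdorff distance, MCC, rank-based AUC.

#' Pixel-wise confusion counts
#'
#' @param pred,target binary masks (0/1) of identical shape.
#' @return list of class `confusion_counts` with `tp, fp, tn, fn`.
#' @export
confusion <- function(pred, target) {
  if (length(pred) != length(target)) stop("shape mismatch", call. = FALSE)
  if (!is_binary(pred) || !is_binary(target)) {
    stop("confusion() requires binary inputs", call. = FALSE)
  }
  tp <- sum(pred == 1 & target == 1)
  fp <- sum(pred == 1 & target == 0)
  tn <- sum(pred == 0 & target == 0)
  fn <- sum(pred == 0 & target == 1)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall (= sensitivity), F1, specificity and MCC.
#' Metrics with a zero denominator are reported as 0 and flagged in the
#' `degenerate` field.
#'
#' @param c a [confusion()] result.
#' @return named list of metrics plus `degenerate` (character vector of
#'   flagged metrics).
#' @export
scalar_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$fp + c$tn + c$fn
  degenerate <- character(0)
  flag <- function(name, den) {
    if (den == 0) degenerate <<- c(degenerate, name)
    den
  }
  precision <- safe_div(c$tp, flag("precision", c$tp + c$fp))
  recall <- safe_div(c$tp, flag("recall", c$tp + c$fn))
  mcc_den <- sqrt(as.numeric(c$tp + c$fp)) * sqrt(as.numeric(c$tp + c$fn)) *
    sqrt(as.numeric(c$tn + c$fp)) * sqrt(as.numeric(c$tn + c$fn))
  list(
    accuracy = safe_div(c$tp + c$tn, flag("accuracy", total)),
    precision = precision,
    recall = recall,
    sensitivity = recall,
    specificity = safe_div(c$tn, flag("specificity", c$tn + c$fp)),
    f1 = safe_div(2 * precision * recall, flag("f1", precision + recall)),
    mcc = safe_div(as.numeric(c$tp) * c$tn - as.numeric(c$fp) * c$fn,
                   flag("mcc", mcc_den)),
    degenerate = degenerate
  )
}

#' Dice coefficient and IoU
#'
#' `dice = 2|A n B| / (|A| + |B|)`, `iou = |A n B| / |A u B|`; when both
#' masks are empty both are 1 by convention.
#'
#' @param pred,target binary masks of identical shape.
#' @return named numeric vector `c(dice, iou)`.
#' @export
dice_iou <- function(pred, target) {
  if (length(pred) != length(target)) stop("shape mismatch", call. = FALSE)
  inter <- sum(pred * target)
  a <- sum(pred); b <- sum(target)
  if (a + b == 0) return(c(dice = 1, iou = 1))
  c(dice = 2 * inter / (a + b), iou = inter / (a + b - inter))
}

#' Exact symmetric Hausdorff distance
#'
#' `H(A, B) = max(h(A, B), h(B, A))` with
#' `h(A, B) = max_{a in A} min_{b in B} ||a - b||` over foreground pixel
#' coordinates (Euclidean, pixel units), computed with exact distance
#' transforms. If one mask is empty the image diagonal is returned; if
#' both are empty, 0. Both conventions carry a `degenerate` attribute.
#'
#' @param pred,target binary masks of identical shape.
#' @param normalize if `TRUE`, divide by the image diagonal (for
#'   comparing across image sizes).
#' @return distance in pixels (or diagonal fraction when normalized).
#' @export
hausdorff_distance <- function(pred, target, normalize = FALSE) {
  if (!identical(dim(pred), dim(target))) stop("shape mismatch", call. = FALSE)
  diag_len <- sqrt(nrow(pred)^2 + ncol(pred)^2)
  na <- sum(pred != 0); nb <- sum(target != 0)
  if (na == 0 && nb == 0) {
    return(structure(0, degenerate = "both masks empty"))
  }
  if (na == 0 || nb == 0) {
    d <- if (normalize) 1 else diag_len
    return(structure(d, degenerate = "one mask empty"))
  }
  dt_t <- cpp_edt_sq(target * 1)
  dt_p <- cpp_edt_sq(pred * 1)
  h_ab <- sqrt(max(dt_t[pred != 0]))
  h_ba <- sqrt(max(dt_p[target != 0]))
  d <- max(h_ab, h_ba)
  if (normalize) d / diag_len else d
}

#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney U normalization) with ties averaged.
#'
#' @param scores numeric scores.
#' @param targets binary labels (0/1), at least one of each class.
#' @return AUC in `[0, 1]`; single-class input returns `NA` with a
#'   warning.
#' @export
auc_score <- function(scores, targets) {
  stopifnot(length(scores) == length(targets))
  n1 <- sum(targets == 1); n0 <- sum(targets == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined for single-class targets")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[targets == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metrics report for a predicted mask
#'
#' Combines the confusion-count metrics, Dice, IoU, exact Hausdorff and
#' pixel-level AUC into one flat named list, mirroring a per-structure
#' results row.
#'
#' @param pred binary predicted mask.
#' @param target binary ground-truth mask.
#' @param scores optional probability map for the AUC (defaults to
#'   `pred` itself).
#' @param auc_subsample fraction of pixels used for the pixel-level ROC
#'   (stratified by class, default 1 = all pixels).
#' @param seed seed for the AUC subsample.
#' @return named list of metrics.
#' @export
metrics_report <- function(pred, target, scores = NULL, auc_subsample = 1,
                           seed = 1L) {
  cm <- scalar_metrics(confusion(pred, target))
  di <- dice_iou(pred, target)
  hd <- hausdorff_distance(pred, target)
  sc <- if (is.null(scores)) as.numeric(pred) else as.numeric(scores)
  tg <- as.numeric(target)
  if (auc_subsample < 1) {
    idx <- with_seed(seed, {
      pos <- which(tg == 1); neg <- which(tg == 0)
      c(sample(pos, max(1, ceiling(length(pos) * auc_subsample))),
        sample(neg, max(1, ceiling(length(neg) * auc_subsample))))
    })
    sc <- sc[idx]; tg <- tg[idx]
  }
  auc <- if (sum(tg == 1) > 0 && sum(tg == 0) > 0) auc_score(sc, tg) else NA_real_
  c(cm[setdiff(names(cm), "degenerate")],
    list(dice = unname(di["dice"]), iou = unname(di["iou"]),
         hausdorff = as.numeric(hd), auc = auc))
}
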