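# Training losses: focal, soft Dice, a differentiable Hausdorff
# surrogate, the 0.27/0.69/0.04 composite, and the Tversky family.
# Each loss has a companion *_grad() returning d(loss)/d(pred) with the
# same shape as `pred`, used by the backprop trainer; gradients are
# plain closed forms so they can be checked by finite differences.

FOCAL_EPS <- 1e-7

#' Focal loss parameters
#'
#' @param alpha foreground class weight in `[0, 1]`; the background gets
#'   `1 - alpha`. With `alpha = 0.5, gamma = 0` the focal loss reduces to
#'   0.5 x binary cross-entropy.
#' @param gamma focusing exponent (>= 0) down-weighting easy pixels.
#' @return list of class `focal_params`.
#' @export
focal_params <- function(alpha = 0.25, gamma = 2) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0,1]", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, gamma = gamma), class = "focal_params")
}

#' Loss mixture weights
#'
#' Defaults to the 27% focal / 69% Dice / 4% Hausdorff mixture.
#'
#' @param w_focal,w_dice,w_hausdorff non-negative component weights.
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(w_focal = 0.27, w_dice = 0.69, w_hausdorff = 0.04) {
  w <- c(w_focal, w_dice, w_hausdorff)
  if (any(w < 0)) stop("loss weights must be non-negative", call. = FALSE)
  structure(list(w_focal = w_focal, w_dice = w_dice, w_hausdorff = w_hausdorff),
            class = "loss_weights")
}

#' Tversky loss parameters
#'
#' @param alpha false-positive weight (default 0.7).
#' @param beta false-negative weight (default 0.3).
#' @param gamma_ft focal exponent for the focal-Tversky variant
#'   (default 0.75).
#' @return list of class `tversky_params`.
#' @export
tversky_params <- function(alpha = 0.7, beta = 0.3, gamma_ft = 0.75) {
  structure(list(alpha = alpha, beta = beta, gamma_ft = gamma_ft),
            class = "tversky_params")
}

clip_pred <- function(pred) pmin(pmax(pred, FOCAL_EPS), 1 - FOCAL_EPS)

#' Focal loss
#'
#' Mean over pixels of `-alpha_t (1 - p_t)^gamma log(p_t)` with
#' `p_t = pred` on foreground and `1 - pred` on background. Predictions
#' at exactly 0/1 are clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param pred predicted probabilities (any shape).
#' @param target binary mask of the same shape.
#' @param p a [focal_params()].
#' @return scalar loss.
#' @export
focal_loss <- function(pred, target, p = focal_params()) {
  stopifnot(length(pred) == length(target))
  pr <- clip_pred(pred)
  pt <- target * pr + (1 - target) * (1 - pr)
  at <- target * p$alpha + (1 - target) * (1 - p$alpha)
  mean(-at * (1 - pt)^p$gamma * log(pt))
}

focal_grad <- function(pred, target, p = focal_params()) {
  pr <- clip_pred(pred)
  pt <- target * pr + (1 - target) * (1 - pr)
  at <- target * p$alpha + (1 - target) * (1 - p$alpha)
  g <- p$gamma
  dpt <- if (g == 0) -at / pt else -at * (-g * (1 - pt)^(g - 1) * log(pt) + (1 - pt)^g / pt)
  grad <- dpt * (2 * target - 1) / length(pred)
  grad[pred <= FOCAL_EPS | pred >= 1 - FOCAL_EPS] <- 0
  array(grad, dim = dim(pred) %||% length(pred))
}

#' Soft Dice loss
#'
#' `1 - (2 sum(pred * target) + smooth) / (sum(pred) + sum(target) + smooth)`.
#'
#' @param pred predicted probabilities.
#' @param target binary mask of the same shape.
#' @param smooth smoothing constant added to numerator and denominator
#'   (default 1); also makes the both-empty case return 0.
#' @return scalar loss.
#' @export
dice_loss <- function(pred, target, smooth = 1) {
  stopifnot(length(pred) == length(target))
  inter <- sum(pred * target)
  1 - (2 * inter + smooth) / (sum(pred) + sum(target) + smooth)
}

dice_grad <- function(pred, target, smooth = 1) {
  den <- sum(pred) + sum(target) + smooth
  num <- 2 * sum(pred * target) + smooth
  grad <- -(2 * target * den - num) / den^2
  array(grad, dim = dim(pred) %||% length(pred))
}

#' Differentiable Hausdorff surrogate
#'
#' Distance-transform penalty used during training in place of the exact
#' (non-differentiable) Hausdorff distance: the mean over pixels of
#' `pred * dt_target^2 + (1 - pred) * target * dt_pred^2`, where
#' `dt_target` is the Euclidean distance to the target foreground and
#' `dt_pred` the distance to the thresholded prediction. Squared
#' distances are normalized by the squared image diagonal so the value
#' is scale-free in `[0, 1]`. The exact symmetric Hausdorff distance
#' ([hausdorff_distance()]) is used for reporting only.
#'
#' @param pred predicted probability matrix (or H x W x 1 x N array).
#' @param target binary mask of the same shape.
#' @param threshold binarization threshold for the prediction-side
#'   distance map (default 0.5).
#' @return scalar in `[0, 1]`.
#' @export
hausdorff_surrogate <- function(pred, target, threshold = 0.5) {
  hs <- hs_terms(pred, target, threshold)
  if (is.null(hs)) return(0)
  mean(hs$w * pred + hs$v * (1 - pred))
}

# shared weight maps: w = dt_target^2/diag^2, v = target * dt_pred^2/diag^2
hs_terms <- function(pred, target, threshold = 0.5) {
  d <- dim(pred) %||% stop("pred must be a matrix or array")
  H <- d[1]; W <- d[2]
  n_extra <- if (length(d) > 2) prod(d[-(1:2)]) else 1L
  diag2 <- H^2 + W^2
  w <- array(0, dim = d); v <- array(0, dim = d)
  any_content <- FALSE
  for (s in seq_len(n_extra)) {
    idx <- ((s - 1) * H * W + 1):(s * H * W)
    tg <- matrix(target[idx], H, W)
    pb <- matrix(pred[idx] >= threshold, H, W) * 1
    if (sum(tg) == 0 && sum(pb) == 0) next  # both empty: zero by convention
    any_content <- TRUE
    dt_t <- if (sum(tg) > 0) cpp_edt_sq(tg) else matrix(diag2, H, W)
    dt_p <- if (sum(pb) > 0) cpp_edt_sq(pb) else matrix(diag2, H, W)
    w[idx] <- dt_t / diag2
    v[idx] <- tg * dt_p / diag2
  }
  if (!any_content) return(NULL)
  list(w = w, v = v)
}

hausdorff_surrogate_grad <- function(pred, target, threshold = 0.5) {
  hs <- hs_terms(pred, target, threshold)
  if (is.null(hs)) return(array(0, dim = dim(pred)))
  (hs$w - hs$v) / length(pred)
}

#' Tri-composite segmentation loss
#'
#' `w_focal * FL + w_dice * DL + w_hausdorff * HD`. The individual
#' component values are attached as the `"components"` attribute for
#' logging.
#'
#' @param pred predicted probabilities.
#' @param target binary mask of the same shape.
#' @param w a [loss_weights()].
#' @param fp a [focal_params()].
#' @param components optional length-3 numeric `(FL, DL, HD)` overriding
#'   the computed components (used to verify mixture arithmetic).
#' @return scalar loss with attribute `components`.
#' @export
composite_loss <- function(pred, target, w = loss_weights(),
                           fp = focal_params(), components = NULL) {
  if (is.null(components)) {
    components <- c(FL = focal_loss(pred, target, fp),
                    DL = dice_loss(pred, target),
                    HD = hausdorff_surrogate(pred, target))
  } else {
    components <- stats::setNames(as.numeric(components), c("FL", "DL", "HD"))
  }
  total <- w$w_focal * components[["FL"]] + w$w_dice * components[["DL"]] +
    w$w_hausdorff * components[["HD"]]
  structure(total, components = components)
}

composite_grad <- function(pred, target, w = loss_weights(), fp = focal_params()) {
  w$w_focal * focal_grad(pred, target, fp) +
    w$w_dice * dice_grad(pred, target) +
    w$w_hausdorff * hausdorff_surrogate_grad(pred, target)
}

#' Tversky and focal-Tversky losses
#'
#' `1 - TI` with `TI = (TP + smooth) / (TP + alpha FP + beta FN + smooth)`
#' on soft counts; the focal variant is `(1 - TI)^gamma_ft`. With
#' `alpha = beta = 0.5` (and equal smoothing) the Tversky loss recovers
#' the soft Dice loss.
#'
#' @param pred predicted probabilities.
#' @param target binary mask of the same shape.
#' @param p a [tversky_params()].
#' @param smooth smoothing constant (default 0, exact set arithmetic).
#' @return scalar loss.
#' @export
tversky_loss <- function(pred, target, p = tversky_params(), smooth = 0) {
  stopifnot(length(pred) == length(target))
  tp <- sum(pred * target)
  fp <- sum(pred * (1 - target))
  fn <- sum((1 - pred) * target)
  ti <- (tp + smooth) / (tp + p$alpha * fp + p$beta * fn + smooth)
  if (!is.finite(ti)) ti <- 1  # both empty
  1 - ti
}

#' @rdname tversky_loss
#' @export
focal_tversky_loss <- function(pred, target, p = tversky_params(), smooth = 0) {
  tversky_loss(pred, target, p, smooth)^p$gamma_ft
}
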