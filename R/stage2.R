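# Stage 2: per-region feature extraction from predicted masks and
# gradient-boosted classification of tumor presence.

#' Gradient-booster configuration
#'
#' Leaf-wise boosted trees with the printed stage-2 settings:
#' learning rate 0.05, max depth 6, 40 leaves, feature fraction 0.9,
#' bagging fraction 0.8.
#'
#' @param learning_rate shrinkage per round.
#' @param max_depth maximum tree depth.
#' @param num_leaves maximum leaves per tree (<= 2^max_depth).
#' @param feature_fraction column subsample per tree.
#' @param bagging_fraction row subsample per tree.
#' @param n_rounds boosting rounds.
#' @param seed integer seed.
#' @return list of class `booster_config`.
#' @export
booster_config <- function(learning_rate = 0.05, max_depth = 6,
                           num_leaves = 40, feature_fraction = 0.9,
                           bagging_fraction = 0.8, n_rounds = 60, seed = 1L) {
  if (num_leaves > 2^max_depth) {
    stop("num_leaves must be <= 2^max_depth", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, max_depth = as.integer(max_depth),
                 num_leaves = as.integer(num_leaves),
                 feature_fraction = feature_fraction,
                 bagging_fraction = bagging_fraction,
                 n_rounds = as.integer(n_rounds), seed = as.integer(seed)),
            class = "booster_config")
}

# names of the per-component feature columns (order is part of the
# contract: feature masks are stored as JSON lists of these names)
region_feature_names <- function() {
  c("area", "perimeter", "mean_intensity", "sd_intensity",
    "centroid_row", "centroid_col",
    "bbox_min_row", "bbox_min_col", "bbox_max_row", "bbox_max_col",
    "eccentricity", "solidity", "skewness", "kurtosis",
    "glcm_contrast", "glcm_homogeneity", "glcm_energy", "glcm_correlation")
}

# Grey-level co-occurrence statistics at offset (0, 1) (0 degrees),
# symmetric, over pairs whose both pixels lie in the region. Intensities
# are quantized to `levels` bins over the in-region range; a constant
# region yields energy 1, contrast 0, homogeneity 1, correlation 0 (by
# convention, zero variance).
glcm_stats <- function(image, comp_mask, levels = 8) {
  vals <- image[comp_mask]
  lo <- min(vals); hi <- max(vals)
  q <- if (hi > lo) {
    pmin(floor((image - lo) / (hi - lo) * levels) + 1, levels)
  } else {
    matrix(1, nrow(image), ncol(image))
  }
  H <- nrow(comp_mask); W <- ncol(comp_mask)
  left <- comp_mask[, -W, drop = FALSE] & comp_mask[, -1, drop = FALSE]
  if (!any(left)) {
    return(c(glcm_contrast = 0, glcm_homogeneity = 1, glcm_energy = 1,
             glcm_correlation = 0))
  }
  i <- q[, -W, drop = FALSE][left]
  j <- q[, -1, drop = FALSE][left]
  P <- matrix(0, levels, levels)
  for (t in seq_along(i)) {
    P[i[t], j[t]] <- P[i[t], j[t]] + 1
    P[j[t], i[t]] <- P[j[t], i[t]] + 1
  }
  P <- P / sum(P)
  lv <- seq_len(levels)
  ii <- matrix(lv, levels, levels); jj <- t(ii)
  mu_i <- sum(ii * P); mu_j <- sum(jj * P)
  s_i <- sqrt(sum((ii - mu_i)^2 * P)); s_j <- sqrt(sum((jj - mu_j)^2 * P))
  corr <- if (s_i > 0 && s_j > 0) sum((ii - mu_i) * (jj - mu_j) * P) / (s_i * s_j) else 0
  c(glcm_contrast = sum((ii - jj)^2 * P),
    glcm_homogeneity = sum(P / (1 + abs(ii - jj))),
    glcm_energy = sum(P^2),
    glcm_correlation = corr)
}

#' Extract per-region features from a predicted mask
#'
#' Labels 8-connected foreground components, drops those below
#' `min_component_area`, and emits one feature row per component:
#' area, boundary-pixel perimeter, intensity mean/SD/skewness/kurtosis,
#' centroid and half-open bounding box (0-based pixel coordinates),
#' moment-based eccentricity, convex-hull solidity, and four
#' co-occurrence texture statistics at offset 1 pixel, 0 degrees.
#'
#' @param image intensity matrix.
#' @param pred_mask binary mask of the same shape.
#' @param sample_id identifier copied into every row.
#' @param min_component_area minimal component area in pixels.
#' @return data.frame, one row per retained component (zero rows for an
#'   empty mask).
#' @export
extract_features <- function(image, pred_mask, sample_id = "s1",
                             min_component_area = 5) {
  if (!identical(dim(image), dim(pred_mask))) stop("shape mismatch", call. = FALSE)
  lab <- cpp_label8(pred_mask * 1)
  rows <- list()
  for (comp in seq_len(max(lab))) {
    cm <- lab == comp
    area <- sum(cm)
    if (area < min_component_area) next
    idx <- which(cm, arr.ind = TRUE)
    r <- idx[, 1]; cc <- idx[, 2]
    vals <- image[cm]
    # boundary pixels: any 4-neighbor outside the component
    pad <- matrix(FALSE, nrow(cm) + 2, ncol(cm) + 2)
    pad[2:(nrow(cm) + 1), 2:(ncol(cm) + 1)] <- cm
    interior <- pad[1:nrow(cm), 2:(ncol(cm) + 1)] &
      pad[3:(nrow(cm) + 2), 2:(ncol(cm) + 1)] &
      pad[2:(nrow(cm) + 1), 1:ncol(cm)] &
      pad[2:(nrow(cm) + 1), 3:(ncol(cm) + 2)]
    perimeter <- sum(cm & !interior)
    # central moments -> ellipse eccentricity
    mr <- mean(r); mc <- mean(cc)
    mrr <- mean((r - mr)^2) + 1 / 12  # pixel-extent correction
    mcc <- mean((cc - mc)^2) + 1 / 12
    mrc <- mean((r - mr) * (cc - mc))
    common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
    l1 <- (mrr + mcc + common) / 2
    l2 <- (mrr + mcc - common) / 2
    ecc <- if (l1 > 0) sqrt(pmax(0, 1 - l2 / l1)) else 0
    # convex-hull solidity from pixel-corner polygon area
    pts <- unique(rbind(cbind(r - 0.5, cc - 0.5), cbind(r - 0.5, cc + 0.5),
                        cbind(r + 0.5, cc - 0.5), cbind(r + 0.5, cc + 0.5)))
    hull <- grDevices::chull(pts)
    hp <- pts[hull, , drop = FALSE]
    hull_area <- abs(sum(hp[, 1] * hp[c(2:nrow(hp), 1), 2] -
                           hp[c(2:nrow(hp), 1), 1] * hp[, 2])) / 2
    solidity <- if (hull_area > 0) min(1, area / hull_area) else 1
    sdv <- stats::sd(vals)
    if (!is.finite(sdv)) sdv <- 0
    sk <- if (sdv > 0) e1071::skewness(vals) else 0
    ku <- if (sdv > 0) e1071::kurtosis(vals) else 0
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sample_id, component_id = comp,
      area = area, perimeter = perimeter,
      mean_intensity = mean(vals), sd_intensity = sdv,
      centroid_row = mr - 1, centroid_col = mc - 1,
      bbox_min_row = min(r) - 1, bbox_min_col = min(cc) - 1,
      bbox_max_row = max(r), bbox_max_col = max(cc),
      eccentricity = ecc, solidity = solidity,
      skewness = sk, kurtosis = ku,
      t(glcm_stats(image, cm)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = 2 + length(region_feature_names())))
    names(out) <- c("sample_id", "component_id", region_feature_names())
    return(out)
  }
  do.call(rbind, rows)
}

#' Summarize component rows into one per-sample feature row
#'
#' The per-sample row used for tumor present/absent classification:
#' component count, total and maximal component area, plus the
#' area-weighted mean of every per-component feature. An empty mask
#' yields an all-zero row with `has_regions = FALSE`.
#'
#' @param comp_rows output of [extract_features()] for one sample.
#' @param sample_id identifier.
#' @return one-row data.frame.
#' @export
sample_feature_row <- function(comp_rows, sample_id = "s1") {
  fn <- setdiff(region_feature_names(),
                c("centroid_row", "centroid_col", "bbox_min_row",
                  "bbox_min_col", "bbox_max_row", "bbox_max_col"))
  if (nrow(comp_rows) == 0) {
    out <- data.frame(sample_id = sample_id, n_components = 0,
                      total_area = 0, max_component_area = 0,
                      has_regions = FALSE)
    for (f in fn) out[[paste0("mean_", f)]] <- 0
    return(out)
  }
  w <- comp_rows$area / sum(comp_rows$area)
  out <- data.frame(sample_id = sample_id, n_components = nrow(comp_rows),
                    total_area = sum(comp_rows$area),
                    max_component_area = max(comp_rows$area),
                    has_regions = TRUE)
  for (f in fn) out[[paste0("mean_", f)]] <- sum(w * comp_rows[[f]])
  out
}

stage2_feature_matrix <- function(sample_rows) {
  keep <- setdiff(names(sample_rows), c("sample_id", "has_regions"))
  X <- as.matrix(sample_rows[keep])
  storage.mode(X) <- "double"
  X
}

#' Train the stage-2 boosted classifier
#'
#' Fits a leaf-wise gradient-boosted tree ensemble (binary logistic) on
#' the masked feature columns and reports stratified 5-fold
#' cross-validation metrics computed with the package's own metric
#' formulas.
#'
#' @param features numeric feature matrix or data.frame.
#' @param labels binary labels (0/1), both classes present.
#' @param cfg a [booster_config()].
#' @param feature_mask optional 0/1 vector or character vector of
#'   column names to keep (e.g. from [go_select_features()]).
#' @param nfolds CV folds (default 5).
#' @return list of class `gravseg_classifier` with `model`,
#'   `feature_names`, `cv` (per-fold metrics + means), and `cfg`.
#' @export
train_classifier <- function(features, labels, cfg = booster_config(),
                             feature_mask = NULL, nfolds = 5) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("labels must contain both classes", call. = FALSE)
  cn <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  colnames(X) <- cn
  if (!is.null(feature_mask)) {
    keep <- if (is.character(feature_mask)) {
      missing <- setdiff(feature_mask, cn)
      if (length(missing)) {
        stop("unknown feature names in mask: ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      feature_mask
    } else {
      cn[feature_mask > 0.5]
    }
    if (length(keep) == 0) stop("feature mask selects no columns", call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  xgb_params <- list(objective = "binary:logistic", eta = cfg$learning_rate,
                     max_depth = cfg$max_depth, tree_method = "hist",
                     grow_policy = "lossguide", max_leaves = cfg$num_leaves,
                     colsample_bytree = cfg$feature_fraction,
                     subsample = cfg$bagging_fraction, nthread = 1,
                     seed = cfg$seed)
  folds <- with_seed(cfg$seed, stratified_folds(y, nfolds))
  fold_metrics <- list()
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
    fit <- xgboost::xgb.train(xgb_params, dtr, nrounds = cfg$n_rounds,
                              verbose = 0)
    p <- predict(fit, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
    yhat <- as.numeric(p >= 0.5)
    sm <- scalar_metrics(confusion(yhat, y[!tr]))
    auc <- if (length(unique(y[!tr])) == 2) auc_score(p, y[!tr]) else NA_real_
    fold_metrics[[f]] <- data.frame(fold = f, accuracy = sm$accuracy,
                                    precision = sm$precision,
                                    recall = sm$recall,
                                    specificity = sm$specificity,
                                    f1 = sm$f1, mcc = sm$mcc, auc = auc)
  }
  cv <- do.call(rbind, fold_metrics)
  dall <- xgboost::xgb.DMatrix(X, label = y)
  model <- xgboost::xgb.train(xgb_params, dall, nrounds = cfg$n_rounds,
                              verbose = 0)
  structure(list(model = model, feature_names = colnames(X),
                 cv = cv, cv_mean = colMeans(cv[-1], na.rm = TRUE),
                 cfg = cfg),
            class = "gravseg_classifier")
}

#' Predict class probabilities for sample feature rows
#'
#' @param object a `gravseg_classifier`.
#' @param features feature matrix/data.frame containing (at least) the
#'   columns the model was trained on.
#' @param ... unused.
#' @return matrix with columns `p_absent`, `p_present`; rows sum to 1.
#' @export
predict.gravseg_classifier <- function(object, features, ...) {
  X <- as.matrix(features)
  cn <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  colnames(X) <- cn
  missing <- setdiff(object$feature_names, cn)
  if (length(missing)) {
    stop("missing feature columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(X) == 0) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("p_absent", "p_present"))))
  }
  p <- predict(object$model,
               xgboost::xgb.DMatrix(X[, object$feature_names, drop = FALSE]))
  cbind(p_absent = 1 - p, p_present = p)
}

#' Synthetic stage-2 feature table with planted informative features
#'
#' Generates a labelled table in which the first `n_informative`
#' features shift between classes by `effect` standard deviations and
#' the rest are pure noise; used to validate wrapper feature selection.
#'
#' @param n samples, split evenly between the classes.
#' @param d total features.
#' @param n_informative number of class-informative features.
#' @param effect mean shift of informative features, in SD units.
#' @param seed integer seed.
#' @return list with `features` (matrix, columns `f1..fd`) and `labels`.
#' @export
make_stage2_table <- function(n = 200, d = 20, n_informative = 5,
                              effect = 1.5, seed = 1L) {
  with_seed(seed, {
    y <- rep(c(0, 1), length.out = n)
    X <- matrix(rnorm(n * d), n, d)
    for (j in seq_len(n_informative)) {
      X[y == 1, j] <- X[y == 1, j] + effect
    }
    colnames(X) <- paste0("f", seq_len(d))
    list(features = X, labels = y)
  })
}
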