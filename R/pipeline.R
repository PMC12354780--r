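# Orchestration: segmentation training loop, k-fold harness, overlay
# rendering, and the resumable end-to-end runner.

#' Segmentation training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size samples per optimizer step.
#' @param epochs maximal training epochs.
#' @param early_stop_patience stop after this many epochs without a new
#'   best validation Dice (default 15).
#' @param lr_reduce_on_plateau halve the learning rate after
#'   `lr_patience` epochs without improvement.
#' @param lr_patience plateau patience for the scheduler (default 5).
#' @param min_lr lower bound for the scheduled learning rate.
#' @param seed integer seed driving initialization, shuffling and
#'   dropout.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32, epochs = 100,
                         early_stop_patience = 15, lr_reduce_on_plateau = TRUE,
                         lr_patience = 5, min_lr = 1e-5, seed = 1L) {
  if (early_stop_patience >= epochs) {
    # allowed but pointless; training then always runs all epochs
    early_stop_patience <- min(early_stop_patience, epochs)
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_reduce_on_plateau = isTRUE(lr_reduce_on_plateau),
                 lr_patience = as.integer(lr_patience), min_lr = min_lr,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Preprocessing options for the training pipeline
#'
#' The canonical order: min-max normalization, RGB-to-grey, bilateral
#' denoising, optional Gaussian blur, per-slice z-score.
#'
#' @param bilateral apply the bilateral filter.
#' @param sigma_s,sigma_r bilateral kernel widths.
#' @param blur_sigma Gaussian blur sigma (0 disables).
#' @return list of class `prep_options`.
#' @export
prep_options <- function(bilateral = TRUE, sigma_s = 1.0, sigma_r = 0.15,
                         blur_sigma = 0) {
  structure(list(bilateral = isTRUE(bilateral), sigma_s = sigma_s,
                 sigma_r = sigma_r, blur_sigma = blur_sigma),
            class = "prep_options")
}

#' Preprocess one slice for the network
#'
#' @param img raw intensity matrix or RGB array.
#' @param opts a [prep_options()].
#' @return standardized matrix.
#' @export
prep_slice <- function(img, opts = prep_options()) {
  img <- min_max_normalize(img)
  if (length(dim(img)) == 3L) img <- to_grey(img)
  if (opts$bilateral) {
    img <- bilateral(img, bilateral_params(opts$sigma_s, opts$sigma_r))
  }
  if (opts$blur_sigma > 0) img <- gaussian_blur(img, opts$blur_sigma)
  zscore(img)
}

label_to_target <- function(lab, out_channels) {
  if (out_channels == 1) {
    array((lab == 2L) * 1, dim = c(dim(lab), 1L))
  } else {
    array(c((lab >= 1L) * 1, (lab == 2L) * 1), dim = c(dim(lab), 2L))
  }
}

# Load raw samples for the given manifest rows.
load_samples <- function(manifest, rows = seq_len(nrow(manifest))) {
  lapply(rows, function(i) {
    structure(list(
      image = read_slice(manifest_path(manifest, manifest$image_path[i])),
      label_map = read_label_map(manifest_path(manifest, manifest$mask_path[i])),
      has_tumor = manifest$has_tumor[i],
      tumor_count = NA_integer_), class = "phantom_sample")
  })
}

samples_to_batch <- function(samples, opts, out_channels) {
  n <- length(samples)
  d <- dim(samples[[1]]$label_map)
  x <- array(0, dim = c(d[1], d[2], 1L, n))
  y <- array(0, dim = c(d[1], d[2], out_channels, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- prep_slice(samples[[i]]$image, opts)
    y[, , , i] <- label_to_target(samples[[i]]$label_map, out_channels)
  }
  list(x = x, y = y)
}

# mean per-sample Dice / IoU on the tumor channel (last channel)
batch_seg_scores <- function(prob, y, threshold = 0.5) {
  ch <- dim(prob)[3]
  n <- dim(prob)[4]
  dice <- iou <- numeric(n)
  for (i in seq_len(n)) {
    di <- dice_iou((prob[, , ch, i] >= threshold) * 1, y[, , ch, i])
    dice[i] <- di["dice"]; iou[i] <- di["iou"]
  }
  list(dice = dice, iou = iou)
}

#' Train the segmentation network
#'
#' Minimizes the composite focal/Dice/Hausdorff loss on the manifest's
#' train split with Adam, monitors the validation Dice (tumor channel,
#' threshold 0.5), keeps the best-validation weights, halves the
#' learning rate on plateau, and early-stops. Fully deterministic under
#' `tc$seed` in single-threaded mode.
#'
#' @param manifest manifest with filled `split` column.
#' @param net a [net_config()].
#' @param tc a [train_config()].
#' @param w a [loss_weights()].
#' @param fp a [focal_params()].
#' @param prep a [prep_options()].
#' @param augment_plan optional [augmentation_plan()] applied to train
#'   rows only.
#' @param out_dir optional directory for `history.csv` and
#'   `checkpoint.rds`.
#' @param verbose print per-epoch progress.
#' @return list of class `gravseg_segmenter`: `network` (best
#'   weights), `history` (one row per epoch), `best_val_dice`,
#'   `best_epoch`.
#' @export
train_segmenter <- function(manifest, net = net_config(), tc = train_config(),
                            w = loss_weights(), fp = focal_params(),
                            prep = prep_options(), augment_plan = NULL,
                            out_dir = NULL, verbose = FALSE) {
  tr_rows <- which(manifest$split == "train")
  va_rows <- which(manifest$split == "val")
  if (length(tr_rows) == 0) stop("manifest has no train split", call. = FALSE)
  if (length(va_rows) == 0) stop("manifest has no val split", call. = FALSE)
  tr_samples <- load_samples(manifest, tr_rows)
  if (!is.null(augment_plan)) {
    extra <- list()
    for (i in seq_along(tr_samples)) {
      extra <- c(extra, augment(tr_samples[[i]], augment_plan,
                                seed = tc$seed + 7919L + i))
    }
    tr_samples <- c(tr_samples, extra)
  }
  tr <- samples_to_batch(tr_samples, prep, net$out_channels)
  va <- samples_to_batch(load_samples(manifest, va_rows), prep, net$out_channels)

  with_seed(tc$seed, {
    network <- build_network(net, seed = tc$seed)
    opt <- adam_new(network$params, lr = tc$learning_rate)
    n_tr <- dim(tr$x)[4]
    history <- list()
    best_dice <- -Inf; best_epoch <- 0L; best_snap <- NULL
    stall <- 0L; lr_stall <- 0L
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(n_tr)
      comp_sum <- c(FL = 0, DL = 0, HD = 0); tot_sum <- 0; nb <- 0
      for (b in seq(1, n_tr, by = tc$batch_size)) {
        idx <- ord[b:min(b + tc$batch_size - 1, n_tr)]
        xb <- tr$x[, , , idx, drop = FALSE]
        yb <- tr$y[, , , idx, drop = FALSE]
        fwd <- net_forward(network, xb, training = TRUE)
        loss <- composite_loss(fwd$output, yb, w, fp)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d, batch starting %d", epoch, b),
               call. = FALSE)
        }
        grad <- composite_grad(fwd$output, yb, w, fp)
        tape_backward(fwd$tape, fwd$out_node, grad)
        opt <- adam_step(opt)
        comp_sum <- comp_sum + attr(loss, "components")
        tot_sum <- tot_sum + as.numeric(loss); nb <- nb + 1
      }
      val_prob <- predict_prob(network, va$x)
      sc <- batch_seg_scores(val_prob, va$y)
      val_dice <- mean(sc$dice); val_iou <- mean(sc$iou)
      improved <- val_dice > best_dice + 1e-9
      if (improved) {
        best_dice <- val_dice; best_epoch <- epoch
        best_snap <- net_snapshot(network)
        stall <- 0L; lr_stall <- 0L
      } else {
        stall <- stall + 1L; lr_stall <- lr_stall + 1L
      }
      if (tc$lr_reduce_on_plateau && lr_stall >= tc$lr_patience &&
          opt$lr > tc$min_lr) {
        opt$lr <- max(tc$min_lr, opt$lr * 0.5)
        lr_stall <- 0L
      }
      history[[epoch]] <- data.frame(
        epoch = epoch, lr = opt$lr, train_loss = tot_sum / nb,
        train_focal = comp_sum[["FL"]] / nb, train_dice = comp_sum[["DL"]] / nb,
        train_hd = comp_sum[["HD"]] / nb, val_dice = val_dice,
        val_iou = val_iou, best_val_dice = best_dice)
      if (verbose) {
        message(sprintf("epoch %3d | loss %.4f | val dice %.4f (best %.4f)",
                        epoch, tot_sum / nb, val_dice, best_dice))
      }
      if (stall >= tc$early_stop_patience) break
    }
    if (!is.null(best_snap)) net_restore(network, best_snap)
    history <- do.call(rbind, history)
    out <- structure(list(network = network, net_config = net,
                          train_config = tc, prep = prep, history = history,
                          best_val_dice = best_dice, best_epoch = best_epoch),
                     class = "gravseg_segmenter")
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(history, file.path(out_dir, "history.csv"),
                       row.names = FALSE)
      saveRDS(list(snapshot = net_snapshot(network),
                   net_config = net, train_config = tc, prep = prep,
                   history = history, best_val_dice = best_dice,
                   best_epoch = best_epoch),
              file.path(out_dir, "checkpoint.rds"))
    }
    out
  })
}

# evaluation-mode forward in chunks (bounded memory)
predict_prob <- function(network, x, chunk = 16L) {
  n <- dim(x)[4]
  out <- NULL
  for (b in seq(1, n, by = chunk)) {
    idx <- b:min(b + chunk - 1, n)
    pr <- net_forward(network, x[, , , idx, drop = FALSE], training = FALSE)$output
    if (is.null(out)) {
      out <- array(0, dim = c(dim(pr)[1:3], n))
    }
    out[, , , idx] <- pr
  }
  out
}

# rebuild a segmenter from a checkpoint file
load_segmenter <- function(path) {
  ck <- readRDS(path)
  network <- build_network(ck$net_config, seed = ck$train_config$seed)
  net_restore(network, ck$snapshot)
  structure(list(network = network, net_config = ck$net_config,
                 train_config = ck$train_config, prep = ck$prep,
                 history = ck$history, best_val_dice = ck$best_val_dice,
                 best_epoch = ck$best_epoch),
            class = "gravseg_segmenter")
}

#' Segment manifest rows with a trained model
#'
#' @param model a `gravseg_segmenter`.
#' @param manifest manifest data.frame.
#' @param rows row indices to segment (default all).
#' @param threshold binarization threshold.
#' @return list with `prob` (list of probability matrices, tumor
#'   channel), `mask` (list of binary matrices), `ids`.
#' @export
segment_rows <- function(model, manifest, rows = seq_len(nrow(manifest)),
                         threshold = 0.5) {
  samples <- load_samples(manifest, rows)
  ba <- samples_to_batch(samples, model$prep, model$net_config$out_channels)
  prob <- predict_prob(model$network, ba$x)
  ch <- dim(prob)[3]
  list(prob = lapply(seq_along(rows), function(i) prob[, , ch, i]),
       mask = lapply(seq_along(rows), function(i) (prob[, , ch, i] >= threshold) * 1),
       target = lapply(seq_along(rows), function(i) ba$y[, , ch, i]),
       ids = manifest$id[rows])
}

#' K-fold cross-validation harness
#'
#' Partitions the manifest into `k` near-equal folds (stratified on
#' `has_tumor`), invokes `runner(train_manifest, val_manifest, fold)`
#' once per fold, and aggregates each returned metric with mean, sd,
#' min, 5%, 50%, 75% and max.
#'
#' @param manifest manifest data.frame.
#' @param k number of folds (2 <= k <= n).
#' @param runner function returning a named numeric vector of metrics.
#' @param seed fold-assignment seed.
#' @return list of class `fold_report`: `fold_metrics` (data.frame),
#'   `stats` (data.frame of aggregate statistics), `assignment`
#'   (integer fold id per row).
#' @export
kfold <- function(manifest, k = 10, runner, seed = 1L) {
  n <- nrow(manifest)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k must not exceed the number of samples", call. = FALSE)
  strat <- if ("has_tumor" %in% names(manifest)) manifest$has_tumor else rep(1, n)
  assignment <- with_seed(seed, stratified_folds(as.numeric(strat), k))
  fold_metrics <- list()
  for (f in seq_len(k)) {
    tr_man <- manifest[assignment != f, , drop = FALSE]
    va_man <- manifest[assignment == f, , drop = FALSE]
    attr(tr_man, "root") <- attr(manifest, "root")
    attr(va_man, "root") <- attr(manifest, "root")
    m <- runner(tr_man, va_man, f)
    fold_metrics[[f]] <- data.frame(fold = f, t(as.matrix(m)))
  }
  fm <- do.call(rbind, fold_metrics)
  metric_cols <- setdiff(names(fm), "fold")
  stats <- do.call(rbind, lapply(metric_cols, function(mc) {
    v <- fm[[mc]]
    data.frame(metric = mc, mean = mean(v), std = stats::sd(v), min = min(v),
               q05 = unname(stats::quantile(v, 0.05)),
               q50 = unname(stats::quantile(v, 0.50)),
               q75 = unname(stats::quantile(v, 0.75)), max = max(v))
  }))
  structure(list(fold_metrics = fm, stats = stats, assignment = assignment),
            class = "fold_report")
}

mask_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  interior <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  m & !interior
}

#' Render a qualitative overlay
#'
#' Writes a PNG showing the grayscale slice, the truth tumor contour
#' (green), predicted tumor shading (red), and a yellow bounding box per
#' predicted tumor component.
#'
#' @param image intensity matrix.
#' @param pred predicted label map or binary tumor mask.
#' @param truth ground-truth label map or binary tumor mask.
#' @param path output PNG path.
#' @return `path`, invisibly; the drawn boxes are attached as the
#'   `boxes` attribute (one row per component: min_row, min_col,
#'   max_row, max_col, half-open 0-based).
#' @export
overlay <- function(image, pred, truth, path) {
  if (!identical(dim(image), dim(pred)) || !identical(dim(image), dim(truth))) {
    stop("shape mismatch", call. = FALSE)
  }
  as_tumor <- function(m) if (any(m == 2)) m == 2 else m == 1
  pm <- as_tumor(pred)
  tm <- as_tumor(truth)
  base <- min_max_normalize(image)
  rgb <- array(rep(base, 3), dim = c(dim(base), 3))
  rgb[, , 1][pm] <- 0.6 * rgb[, , 1][pm] + 0.4
  tb <- mask_boundary(tm)
  rgb[, , 1][tb] <- 0; rgb[, , 2][tb] <- 1; rgb[, , 3][tb] <- 0
  lab <- cpp_label8(pm * 1)
  boxes <- NULL
  for (comp in seq_len(max(lab))) {
    idx <- which(lab == comp, arr.ind = TRUE)
    b <- c(min_row = min(idx[, 1]) - 1L, min_col = min(idx[, 2]) - 1L,
           max_row = max(idx[, 1]), max_col = max(idx[, 2]))
    boxes <- rbind(boxes, b)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    for (ch in 1:2) { # yellow frame
      rgb[r0, c0:c1, ch] <- 1; rgb[r1, c0:c1, ch] <- 1
      rgb[r0:r1, c0, ch] <- 1; rgb[r0:r1, c1, ch] <- 1
    }
    rgb[r0, c0:c1, 3] <- 0; rgb[r1, c0:c1, 3] <- 0
    rgb[r0:r1, c0, 3] <- 0; rgb[r0:r1, c1, 3] <- 0
  }
  write_slice(rgb, path)
  invisible(structure(path, boxes = boxes))
}
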