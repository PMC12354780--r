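# End-to-end runner: forge -> split -> train segmenter -> predict masks
# -> region features -> gravitational feature selection -> boosted
# classifier -> evaluation summary. Every stage leaves an artifact and
# is skipped on re-run when its artifact already exists, so a run is
# resumable stage by stage.

#' Default pipeline configuration
#'
#' Returns the desk-scale configuration: 64 x 64 phantoms, a small
#' 2-level network, and short training. All fields can be overridden by
#' a YAML file or a nested list passed to [run_pipeline()].
#'
#' @param seed master seed.
#' @param out_dir artifacts directory.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L, out_dir = "gravseg_run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    forge = list(n = 200, height = 64, width = 64),
    prep = list(bilateral = TRUE, sigma_s = 1.0, sigma_r = 0.15,
                blur_sigma = 0, split = c(0.7, 0.2, 0.1)),
    model = list(input_size = 64, levels = 2, base_filters = 8,
                 inception_modules = 1, bottleneck_ratio = 0.5,
                 dropout = 0.3, use_residual = TRUE,
                 use_pyramid_pool = FALSE, use_stamps = TRUE,
                 out_channels = 1),
    train = list(learning_rate = 0.001, batch_size = 8, epochs = 12,
                 early_stop_patience = 15),
    loss = list(w_focal = 0.27, w_dice = 0.69, w_hausdorff = 0.04,
                alpha = 0.25, gamma = 2),
    go = list(population = 15, iterations = 25, lambda = 0.02),
    classifier = list(learning_rate = 0.05, max_depth = 6, num_leaves = 40,
                      feature_fraction = 0.9, bagging_fraction = 0.8,
                      n_rounds = 60)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration
#'
#' @param x a YAML file path, a nested list of overrides, or `NULL`.
#' @param seed,out_dir defaults used when `x` does not set them.
#' @return full configuration list.
#' @export
load_config <- function(x = NULL, seed = 1L, out_dir = "gravseg_run") {
  cfg <- default_config(seed = seed, out_dir = out_dir)
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (is.list(x)) cfg <- merge_config(cfg, x)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

log_stage <- function(verbose, stage, msg) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full two-stage pipeline
#'
#' Executes all stages against `cfg$out_dir`. Each stage writes its
#' artifact (dataset + manifest, segmenter checkpoint, predicted masks,
#' feature table, selected-feature mask, classifier report) and a final
#' `summary.json` with every segmentation and classification metric.
#' Re-running skips stages whose artifacts exist.
#'
#' @param config a YAML path, nested override list, or full config from
#'   [load_config()].
#' @param seed master seed (used when the config does not carry one).
#' @param verbose print stage progress.
#' @return the summary list, invisibly; artifacts under `cfg$out_dir`.
#' @export
run_pipeline <- function(config = NULL, seed = 1L, verbose = FALSE) {
  cfg <- load_config(config, seed = seed)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # stage 1: data
  man_path <- file.path(out, "data", "manifest.csv")
  if (!file.exists(man_path)) {
    log_stage(verbose, "data", "forging phantom dataset")
    spec <- phantom_spec(height = cfg$forge$height, width = cfg$forge$width,
                         seed = cfg$seed)
    manifest <- forge_dataset(spec, cfg$forge$n, file.path(out, "data"))
    sp <- cfg$prep$split
    manifest <- assign_splits(manifest, split_ratios(sp[1], sp[2], sp[3]),
                              seed = cfg$seed + 1L)
    save_manifest(manifest, man_path)
  }
  manifest <- load_manifest(man_path)

  # stage 2: segmenter
  seg_dir <- file.path(out, "segmenter")
  ck_path <- file.path(seg_dir, "checkpoint.rds")
  prep <- prep_options(bilateral = cfg$prep$bilateral, sigma_s = cfg$prep$sigma_s,
                       sigma_r = cfg$prep$sigma_r, blur_sigma = cfg$prep$blur_sigma)
  if (!file.exists(ck_path)) {
    log_stage(verbose, "segmenter", "training")
    netc <- do.call(net_config, cfg$model)
    tc <- train_config(learning_rate = cfg$train$learning_rate,
                       batch_size = cfg$train$batch_size,
                       epochs = cfg$train$epochs,
                       early_stop_patience = cfg$train$early_stop_patience,
                       seed = cfg$seed + 2L)
    lw <- loss_weights(cfg$loss$w_focal, cfg$loss$w_dice, cfg$loss$w_hausdorff)
    fp <- focal_params(cfg$loss$alpha, cfg$loss$gamma)
    train_segmenter(manifest, netc, tc, lw, fp, prep, out_dir = seg_dir,
                    verbose = verbose)
  }
  model <- load_segmenter(ck_path)

  # stage 3: predicted masks
  pred_dir <- file.path(out, "pred")
  pred_done <- file.path(pred_dir, "done.txt")
  if (!file.exists(pred_done)) {
    log_stage(verbose, "predict", "segmenting all slices")
    seg <- segment_rows(model, manifest)
    dir.create(pred_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      write_label_map(seg$mask[[i]], file.path(pred_dir, paste0(manifest$id[i], ".png")))
    }
    writeLines(manifest$id, pred_done)
  }

  # stage 4: features
  feat_path <- file.path(out, "features", "sample_features.csv")
  if (!file.exists(feat_path)) {
    log_stage(verbose, "features", "extracting region features")
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      img <- prep_slice(read_slice(manifest_path(manifest, manifest$image_path[i])),
                        prep)
      mask <- read_label_map(file.path(pred_dir, paste0(manifest$id[i], ".png")))
      comp <- extract_features(img, (mask > 0) * 1, sample_id = manifest$id[i])
      sample_feature_row(comp, sample_id = manifest$id[i])
    })
    feats <- do.call(rbind, rows)
    dir.create(dirname(feat_path), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(feats, feat_path, row.names = FALSE)
  }
  feats <- utils::read.csv(feat_path, stringsAsFactors = FALSE)
  stopifnot(identical(feats$sample_id, manifest$id))
  X <- stage2_feature_matrix(feats)
  y <- as.numeric(manifest$has_tumor)
  fit_rows <- manifest$split %in% c("train", "val")
  test_rows <- manifest$split == "test"

  # stage 5: feature selection
  mask_path <- file.path(out, "features", "feature_mask.json")
  if (!file.exists(mask_path)) {
    log_stage(verbose, "select", "gravitational feature selection")
    scorer <- make_cv_scorer(X[fit_rows, , drop = FALSE], y[fit_rows],
                             lambda = cfg$go$lambda, seed = cfg$seed + 3L)
    sel <- go_select_features(X[fit_rows, , drop = FALSE], y[fit_rows], scorer,
                              go_config(population = cfg$go$population,
                                        iterations = cfg$go$iterations,
                                        seed = cfg$seed + 4L))
    jsonlite::write_json(sel$selected, mask_path)
  }
  selected <- unlist(jsonlite::read_json(mask_path, simplifyVector = TRUE))

  # stage 6: classifier + evaluation summary
  summary_path <- file.path(out, "summary.json")
  if (!file.exists(summary_path)) {
    log_stage(verbose, "classifier", "training boosted classifier")
    bc <- booster_config(learning_rate = cfg$classifier$learning_rate,
                         max_depth = cfg$classifier$max_depth,
                         num_leaves = cfg$classifier$num_leaves,
                         feature_fraction = cfg$classifier$feature_fraction,
                         bagging_fraction = cfg$classifier$bagging_fraction,
                         n_rounds = cfg$classifier$n_rounds,
                         seed = cfg$seed + 5L)
    clf <- train_classifier(X[fit_rows, , drop = FALSE], y[fit_rows], bc,
                            feature_mask = selected)
    p_test <- predict(clf, X[test_rows, , drop = FALSE])[, "p_present"]
    yhat <- as.numeric(p_test >= 0.5)
    cm <- scalar_metrics(confusion(yhat, y[test_rows]))
    clf_auc <- if (length(unique(y[test_rows])) == 2) {
      auc_score(p_test, y[test_rows])
    } else NA_real_

    log_stage(verbose, "evaluate", "segmentation metrics on the test split")
    seg <- segment_rows(model, manifest, which(test_rows))
    n_te <- sum(test_rows)
    dice <- iou <- hd <- numeric(n_te)
    for (i in seq_len(n_te)) {
      di <- dice_iou(seg$mask[[i]], seg$target[[i]])
      dice[i] <- di["dice"]; iou[i] <- di["iou"]
      hd[i] <- as.numeric(hausdorff_distance(seg$mask[[i]], seg$target[[i]]))
    }
    summary <- list(
      seed = cfg$seed,
      n_samples = nrow(manifest),
      splits = as.list(table(manifest$split)),
      segmentation = list(
        best_val_dice = model$best_val_dice,
        best_epoch = model$best_epoch,
        test_dice = mean(dice), test_iou = mean(iou),
        test_hausdorff = mean(hd)),
      feature_selection = list(selected = as.list(selected),
                               n_selected = length(selected)),
      classification = list(
        cv = as.list(clf$cv_mean),
        test_accuracy = cm$accuracy, test_sensitivity = cm$sensitivity,
        test_specificity = cm$specificity, test_f1 = cm$f1,
        test_mcc = cm$mcc, test_auc = clf_auc))
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(jsonlite::read_json(summary_path, simplifyVector = TRUE))
}
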