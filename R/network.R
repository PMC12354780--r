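# Inception-augmented U-Net builder. A NetConfig is compiled once into a
# linear op plan (a tiny IR); parameter initialization, the forward
# pass, and the graph summary all walk that same plan, so the counted
# architecture is exactly the executed one.
#
# Encoder level k (nominal width w_k = base_filters * 2^(k-1)):
#   inception_modules x [parallel conv branches (inception_kernels),
#   each conv + BN + ReLU + dropout, channel-concatenated to w_k,
#   optional residual add (1x1 conv + BN projection when widths differ)],
#   then a 1x1 "levelled bottleneck" compressing to
#   round(w_k * bottleneck_ratio) channels, then 2x max-pool.
# Bridge: inception modules at w_{L+1}, optional pyramid pooling
#   (average pools at factors 1/2/4, 1x1 conv each, upsample, concat,
#   1x1 fuse).
# Decoder level k: 2x nearest upsampling + 3x3 conv to w_k, concat with
#   the level-k skip (and, when enabled, a "historical stamp": the
#   pre-bottleneck encoder feature projected by 1x1 conv to w_k), then
#   inception modules back to w_k.
# Head: 1x1 conv + sigmoid.

#' Segmentation network configuration
#'
#' @param input_size square input size in pixels, a power of 2.
#' @param levels number of 2x down-sampling stages; `input_size / 2^levels`
#'   must be at least 4 (512 with 4 levels gives the 32 x 32 bottleneck).
#' @param base_filters channel width of the first level.
#' @param in_channels input image channels (1 after grayscale prep).
#' @param inception_kernels kernel sizes of the parallel branches.
#' @param inception_modules inception blocks per level.
#' @param bottleneck_ratio channel-compression fraction of the levelled
#'   1x1 bottlenecks.
#' @param dropout dropout rate after each conv (default 0.3).
#' @param use_residual add residual shortcuts around inception blocks.
#' @param use_pyramid_pool enable bridge-level pyramid pooling.
#' @param use_stamps enable historical-stamp bypasses into the decoder.
#' @param out_channels 1 (tumor mask) or 2 (liver + tumor).
#' @return list of class `net_config`.
#' @export
net_config <- function(input_size = 64, levels = 2, base_filters = 8,
                       in_channels = 1, inception_kernels = c(1, 3, 5),
                       inception_modules = 1, bottleneck_ratio = 0.5,
                       dropout = 0.3, use_residual = TRUE,
                       use_pyramid_pool = FALSE, use_stamps = TRUE,
                       out_channels = 1) {
  cfg <- list(input_size = as.integer(input_size), levels = as.integer(levels),
              base_filters = as.integer(base_filters),
              in_channels = as.integer(in_channels),
              inception_kernels = as.integer(inception_kernels),
              inception_modules = as.integer(inception_modules),
              bottleneck_ratio = bottleneck_ratio, dropout = dropout,
              use_residual = isTRUE(use_residual),
              use_pyramid_pool = isTRUE(use_pyramid_pool),
              use_stamps = isTRUE(use_stamps),
              out_channels = as.integer(out_channels))
  if (log2(cfg$input_size) %% 1 != 0) {
    stop("input_size must be a power of 2", call. = FALSE)
  }
  for (k in seq_len(cfg$levels)) {
    if (cfg$input_size / 2^k < 4) {
      stop(sprintf("encoder level %d would underflow: %d / 2^%d = %g < 4",
                   k, cfg$input_size, k, cfg$input_size / 2^k), call. = FALSE)
    }
  }
  if (any(cfg$inception_kernels %% 2 == 0)) {
    stop("inception kernel sizes must be odd", call. = FALSE)
  }
  if (cfg$base_filters < length(cfg$inception_kernels)) {
    stop("base_filters must be >= number of inception branches", call. = FALSE)
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0,1)", call. = FALSE)
  if (!cfg$out_channels %in% 1:2) stop("out_channels must be 1 or 2", call. = FALSE)
  class(cfg) <- "net_config"
  cfg
}

# channel split across branches: equal shares, remainder to the 3x3
# branch (or the largest kernel if no 3x3 branch is present)
branch_splits <- function(width, kernels) {
  nb <- length(kernels)
  base <- width %/% nb
  splits <- rep(base, nb)
  j <- if (3 %in% kernels) which(kernels == 3)[1] else which.max(kernels)
  splits[j] <- splits[j] + width - base * nb
  splits
}

# Compile a config into the linear op plan.
net_plan <- function(cfg) {
  steps <- list()
  emit <- function(st) {
    steps[[length(steps) + 1L]] <<- st
    st$out
  }
  conv_unit <- function(in_name, base, k, cin, cout, act = TRUE, drop = TRUE) {
    cur <- emit(list(out = paste0(base, ".conv"), op = "conv", ins = in_name,
                     k = k, cin = cin, cout = cout, param = paste0(base, ".conv")))
    cur <- emit(list(out = paste0(base, ".bn"), op = "bn", ins = cur,
                     c = cout, param = paste0(base, ".bn")))
    if (act) cur <- emit(list(out = paste0(base, ".relu"), op = "relu", ins = cur))
    if (drop && cfg$dropout > 0) {
      cur <- emit(list(out = paste0(base, ".drop"), op = "dropout", ins = cur,
                       p = cfg$dropout))
    }
    cur
  }
  inception_block <- function(in_name, base, cin, width) {
    splits <- branch_splits(width, cfg$inception_kernels)
    bouts <- character(length(cfg$inception_kernels))
    for (j in seq_along(cfg$inception_kernels)) {
      kj <- cfg$inception_kernels[j]
      bouts[j] <- conv_unit(in_name, sprintf("%s.b%d", base, kj), kj, cin, splits[j])
    }
    cur <- emit(list(out = paste0(base, ".cat"), op = "concat", ins = bouts))
    if (cfg$use_residual) {
      res <- in_name
      if (cin != width) {
        res <- conv_unit(in_name, paste0(base, ".proj"), 1L, cin, width,
                         act = FALSE, drop = FALSE)
      }
      cur <- emit(list(out = paste0(base, ".add"), op = "add", ins = c(cur, res)))
    }
    cur
  }

  L <- cfg$levels; M <- cfg$inception_modules
  widths <- cfg$base_filters * 2^(0:L)
  skip <- character(L); skip_ch <- integer(L); stamp_src <- character(L)
  cur <- "x"; cin <- cfg$in_channels
  for (k in seq_len(L)) {
    w_k <- widths[k]
    for (m in seq_len(M)) {
      cur <- inception_block(cur, sprintf("enc%d.m%d", k, m), cin, w_k)
      cin <- w_k
    }
    stamp_src[k] <- cur
    s_k <- max(1L, as.integer(round(w_k * cfg$bottleneck_ratio)))
    cur <- conv_unit(cur, sprintf("enc%d.bott", k), 1L, w_k, s_k)
    skip[k] <- cur; skip_ch[k] <- s_k
    cur <- emit(list(out = sprintf("enc%d.pool", k), op = "maxpool", ins = cur, f = 2L))
    cin <- s_k
  }
  wB <- widths[L + 1]
  for (m in seq_len(M)) {
    cur <- inception_block(cur, sprintf("bridge.m%d", m), cin, wB)
    cin <- wB
  }
  if (cfg$use_pyramid_pool) {
    pc <- max(1L, wB %/% 4L)
    b_outs <- cur
    for (g in c(1L, 2L, 4L)) {
      nm <- sprintf("pyr.g%d", g)
      if (g == 1L) {
        br <- conv_unit(cur, nm, 1L, wB, pc)
      } else {
        pooled <- emit(list(out = paste0(nm, ".pool"), op = "avgpool", ins = cur, f = g))
        br <- conv_unit(pooled, nm, 1L, wB, pc)
        br <- emit(list(out = paste0(nm, ".up"), op = "upnn", ins = br, f = g))
      }
      b_outs <- c(b_outs, br)
    }
    cur <- emit(list(out = "pyr.cat", op = "concat", ins = b_outs))
    cur <- conv_unit(cur, "pyr.fuse", 1L, wB + 3L * pc, wB)
    cin <- wB
  }
  for (k in rev(seq_len(L))) {
    w_k <- widths[k]
    cur <- emit(list(out = sprintf("dec%d.up", k), op = "upnn", ins = cur, f = 2L))
    cur <- conv_unit(cur, sprintf("dec%d.upconv", k), 3L, cin, w_k)
    cat_ins <- c(cur, skip[k]); ccat <- w_k + skip_ch[k]
    if (cfg$use_stamps) {
      st <- conv_unit(stamp_src[k], sprintf("dec%d.stamp", k), 1L, w_k, w_k)
      cat_ins <- c(cat_ins, st); ccat <- ccat + w_k
    }
    cur <- emit(list(out = sprintf("dec%d.cat", k), op = "concat", ins = cat_ins))
    cin <- ccat
    for (m in seq_len(M)) {
      cur <- inception_block(cur, sprintf("dec%d.m%d", k, m), cin, w_k)
      cin <- w_k
    }
  }
  emit(list(out = "head.conv", op = "conv", ins = cur, k = 1L,
            cin = cin, cout = cfg$out_channels, param = "head.conv"))
  emit(list(out = "head.sigmoid", op = "sigmoid", ins = "head.conv"))
  list(steps = steps, widths = widths, skip_channels = skip_ch,
       out = "head.sigmoid")
}

#' Build a segmentation network
#'
#' Compiles the configuration into an op plan and initializes all
#' parameters (He-uniform conv weights, unit/zero batch-norm scales)
#' under `seed`.
#'
#' @param config a [net_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `gravseg_net` with fields `config`, `plan`,
#'   `params`, `bn_states`, and `summary` (see [net_summary()]).
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  plan <- net_plan(config)
  params <- list(); bn_states <- list()
  with_seed(seed, {
    for (st in plan$steps) {
      if (st$op == "conv") {
        fan_in <- st$k^2 * st$cin
        lim <- sqrt(6 / fan_in)
        w <- array(runif(st$k^2 * st$cin * st$cout, -lim, lim),
                   dim = c(st$k, st$k, st$cin, st$cout))
        params[[paste0(st$param, ".w")]] <- param_new(w, paste0(st$param, ".w"))
        params[[paste0(st$param, ".bias")]] <- param_new(numeric(st$cout),
                                                         paste0(st$param, ".bias"))
      } else if (st$op == "bn") {
        params[[paste0(st$param, ".gamma")]] <- param_new(rep(1, st$c),
                                                          paste0(st$param, ".gamma"))
        params[[paste0(st$param, ".beta")]] <- param_new(numeric(st$c),
                                                         paste0(st$param, ".beta"))
        state <- new.env(parent = emptyenv())
        state$mean <- numeric(st$c); state$var <- rep(1, st$c)
        bn_states[[st$param]] <- state
      }
    }
  })
  net <- structure(list(config = config, plan = plan, params = params,
                        bn_states = bn_states), class = "gravseg_net")
  net$summary <- net_summary(net)
  net
}

#' Network graph summary
#'
#' Per-level spatial sizes and channel widths, skip/bottleneck channel
#' counts, total trainable parameter count, and the output shape.
#'
#' @param net a `gravseg_net` (or a [net_config()]).
#' @return list of class `graph_summary`.
#' @export
net_summary <- function(net) {
  cfg <- if (inherits(net, "gravseg_net")) net$config else net
  plan <- if (inherits(net, "gravseg_net")) net$plan else net_plan(cfg)
  n_par <- 0
  for (st in plan$steps) {
    if (st$op == "conv") n_par <- n_par + st$k^2 * st$cin * st$cout + st$cout
    if (st$op == "bn") n_par <- n_par + 2 * st$c
  }
  L <- cfg$levels
  lv <- data.frame(level = seq_len(L),
                   spatial = cfg$input_size / 2^(seq_len(L) - 1),
                   width = plan$widths[seq_len(L)],
                   skip_channels = plan$skip_channels)
  structure(list(levels = lv,
                 bottleneck_spatial = cfg$input_size / 2^L,
                 bridge_width = plan$widths[L + 1],
                 n_params = n_par,
                 output_shape = c(cfg$input_size, cfg$input_size, cfg$out_channels)),
            class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat("Inception U-Net graph\n")
  print(x$levels, row.names = FALSE)
  cat(sprintf("bottleneck: %d x %d (width %d) | params: %d | output: %s\n",
              x$bottleneck_spatial, x$bottleneck_spatial, x$bridge_width,
              x$n_params, paste(x$output_shape, collapse = " x ")))
  invisible(x)
}

#' Forward pass
#'
#' Runs a batch through the network. In training mode dropout is active
#' (driven by R's RNG) and batch-norm uses batch statistics; in
#' evaluation mode the pass is deterministic and mutates no state.
#'
#' @param net a `gravseg_net`.
#' @param x input array `(H, W, C, N)` (a single `(H, W)` matrix or
#'   `(H, W, C)` array is promoted).
#' @param training logical.
#' @return list with `output` (probability array `(H, W, out_channels,
#'   N)`), `out_node`, and `tape` (for backprop).
#' @export
net_forward <- function(net, x, training = FALSE) {
  cfg <- net$config
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size) {
    stop(sprintf("input spatial size %dx%d != configured %d",
                 d[1], d[2], cfg$input_size), call. = FALSE)
  }
  if (d[3] != cfg$in_channels) {
    stop(sprintf("input has %d channels, configured %d", d[3], cfg$in_channels),
         call. = FALSE)
  }
  tp <- tape_new()
  nodes <- new.env(parent = emptyenv())
  nodes[["x"]] <- op_input(tp, x)
  get_node <- function(nm) get(nm, envir = nodes, inherits = FALSE)
  for (st in net$plan$steps) {
    nd <- switch(st$op,
      conv = op_conv(tp, get_node(st$ins),
                     op_param(tp, net$params[[paste0(st$param, ".w")]]),
                     op_param(tp, net$params[[paste0(st$param, ".bias")]])),
      bn = op_bn(tp, get_node(st$ins),
                 op_param(tp, net$params[[paste0(st$param, ".gamma")]]),
                 op_param(tp, net$params[[paste0(st$param, ".beta")]]),
                 net$bn_states[[st$param]], training),
      relu = op_relu(tp, get_node(st$ins)),
      dropout = op_dropout(tp, get_node(st$ins), st$p, training),
      maxpool = op_maxpool(tp, get_node(st$ins), st$f),
      avgpool = op_avgpool(tp, get_node(st$ins), st$f),
      upnn = op_upnn(tp, get_node(st$ins), st$f),
      concat = op_concat(tp, lapply(st$ins, get_node)),
      add = op_add(tp, get_node(st$ins[1]), get_node(st$ins[2])),
      sigmoid = op_sigmoid(tp, get_node(st$ins)),
      stop("unknown op: ", st$op)
    )
    assign(st$out, nd, envir = nodes)
  }
  out <- get_node(net$plan$out)
  list(output = out$value, out_node = out, tape = tp)
}

# Snapshot / restore of the full inference state: parameter values plus
# batch-norm running statistics. Both must be captured at the same epoch
# or a restored checkpoint would pair weights with mismatched statistics.
net_snapshot <- function(net) {
  list(params = lapply(net$params, function(p) p$value),
       bn = lapply(net$bn_states, function(s) list(mean = s$mean, var = s$var)))
}

net_restore <- function(net, snap) {
  for (nm in names(snap$params)) net$params[[nm]]$value <- snap$params[[nm]]
  for (nm in names(snap$bn)) {
    net$bn_states[[nm]]$mean <- snap$bn[[nm]]$mean
    net$bn_states[[nm]]$var <- snap$bn[[nm]]$var
  }
  invisible(net)
}
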