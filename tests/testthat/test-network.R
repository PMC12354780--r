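test_that("encoder/decoder shape algebra holds for all valid configs", {
  for (lv in 1:3) {
    for (inp in c(32, 64)) {
      if (inp / 2^lv < 4) next
      s <- net_summary(net_config(input_size = inp, levels = lv,
                                  base_filters = 8))
      expect_equal(s$levels$spatial, inp / 2^(seq_len(lv) - 1))
      expect_equal(s$bottleneck_spatial, inp / 2^lv)
    }
  }
  # the full-scale geometry: 512 input, 4 levels -> 32 x 32 bottleneck
  s <- net_summary(net_config(input_size = 512, levels = 4, base_filters = 32))
  expect_equal(s$bottleneck_spatial, 32)
  expect_equal(s$output_shape, c(512, 512, 1))
  expect_error(net_config(input_size = 32, levels = 4), "level 4")
})

test_that("parameter count matches the closed-form layer tally", {
  # hand tally for input 16, 1 level, base 4, kernels {1,3}, ratio 0.5,
  # residual + stamps on, pyramid off, 1 -> 1 channels:
  # encoder inception (cin 1, width 4, splits 2/2):
  #   1x1 conv 1->2: 2+2, bn 4;  3x3 conv 1->2: 18+2, bn 4; proj 1->4: 4+4, bn 8
  #   bottleneck 1x1 4->2: 8+2, bn 4
  # bridge inception (cin 2, width 8, splits 4/4):
  #   1x1 2->4: 8+4, bn 8;  3x3 2->4: 72+4, bn 8;  proj 2->8: 16+8, bn 16
  # decoder: upconv 3x3 8->4: 288+4, bn 8; stamp 1x1 4->4: 16+4, bn 8
  #   concat channels 4+2+4 = 10
  #   inception (cin 10, width 4): 1x1 10->2: 20+2, bn 4; 3x3 10->2: 180+2,
  #   bn 4; proj 10->4: 40+4, bn 8
  # head 1x1 4->1: 4+1
  want <- (2 + 2 + 4) + (18 + 2 + 4) + (4 + 4 + 8) + (8 + 2 + 4) +
    (8 + 4 + 8) + (72 + 4 + 8) + (16 + 8 + 16) +
    (288 + 4 + 8) + (16 + 4 + 8) +
    (20 + 2 + 4) + (180 + 2 + 4) + (40 + 4 + 8) + (4 + 1)
  cfg <- net_config(input_size = 16, levels = 1, base_filters = 4,
                    inception_kernels = c(1, 3), bottleneck_ratio = 0.5)
  expect_equal(net_summary(cfg)$n_params, want)
  net <- build_network(cfg, seed = 1)
  expect_equal(sum(vapply(net$params, function(p) length(p$value), numeric(1))),
               want)
})

test_that("historical stamps account for exactly their projected channels", {
  base <- list(input_size = 32, levels = 2, base_filters = 8,
               inception_kernels = c(1, 3, 5))
  with_st <- do.call(net_config, c(base, use_stamps = TRUE))
  no_st <- do.call(net_config, c(base, use_stamps = FALSE))
  cat_cin <- function(cfg, lvl) {
    steps <- gravseg:::net_plan(cfg)$steps
    ins <- steps[[which(vapply(steps, `[[`, "", "out") ==
                          sprintf("dec%d.cat", lvl))]]$ins
    length(ins)
  }
  # decoder concat gains exactly one extra (projected) input per level
  expect_equal(cat_cin(with_st, 1), cat_cin(no_st, 1) + 1)
  # channel bookkeeping: concat width = upconv w_k + skip s_k (+ stamp w_k)
  s <- net_summary(with_st)
  steps <- gravseg:::net_plan(with_st)$steps
  dec1_m1_cin <- steps[[which(vapply(steps, `[[`, "", "out") ==
                                "dec1.m1.b1.conv")]]$cin
  expect_equal(dec1_m1_cin,
               s$levels$width[1] * 2 + s$levels$skip_channels[1])
  # stamps off + residual off leaves a plain inception U-Net plan
  plain <- do.call(net_config, c(base, use_stamps = FALSE, use_residual = FALSE))
  outs <- vapply(gravseg:::net_plan(plain)$steps, `[[`, "", "out")
  expect_false(any(grepl("stamp|proj|add", outs)))
})

test_that("forward pass is shape-preserving, bounded, and pure in eval mode", {
  cfg <- net_config(input_size = 32, levels = 2, base_filters = 8,
                    use_pyramid_pool = TRUE)
  net <- build_network(cfg, seed = 3)
  x <- array(0, c(32, 32, 1, 2))
  f1 <- net_forward(net, x, training = FALSE)$output
  f2 <- net_forward(net, x, training = FALSE)$output
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(32, 32, 1, 2))
  expect_true(all(f1 > 0 & f1 < 1))
  # eval mode must not mutate batch-norm state
  st_before <- lapply(net$bn_states, function(s) list(m = s$mean, v = s$var))
  invisible(net_forward(net, x, training = FALSE))
  st_after <- lapply(net$bn_states, function(s) list(m = s$mean, v = s$var))
  expect_identical(st_before, st_after)
  expect_error(net_forward(net, array(0, c(16, 16, 1, 1))), "spatial")
})

test_that("composite-loss gradients through the network are finite", {
  cfg <- net_config(input_size = 16, levels = 1, base_filters = 4,
                    inception_kernels = c(1, 3))
  net <- build_network(cfg, seed = 4)
  s <- forge_sample(tiny_spec(16, seed = 5, n_tumors = 1L))
  x <- array(zscore(min_max_normalize(s$image)), c(16, 16, 1, 1))
  y <- array((s$label_map == 2L) * 1, c(16, 16, 1, 1))
  set.seed(6)
  fwd <- net_forward(net, x, training = TRUE)
  g <- gravseg:::composite_grad(fwd$output, y)
  gravseg:::zero_grads(net$params)
  gravseg:::tape_backward(fwd$tape, fwd$out_node, g)
  for (p in net$params) expect_true(all(is.finite(p$grad)))
})

test_that("training-mode loss decreases over 50 optimizer steps", {
  cfg <- net_config(input_size = 16, levels = 1, base_filters = 4,
                    inception_kernels = c(1, 3), dropout = 0)
  net <- build_network(cfg, seed = 7)
  xs <- ys <- list()
  for (i in 1:4) {
    s <- forge_sample(tiny_spec(16, seed = 30 + i, n_tumors = 1L))
    xs[[i]] <- zscore(min_max_normalize(s$image))
    ys[[i]] <- (s$label_map == 2L) * 1
  }
  x <- array(unlist(xs), c(16, 16, 1, 4))
  y <- array(unlist(ys), c(16, 16, 1, 4))
  opt <- gravseg:::adam_new(net$params, lr = 1e-3)
  set.seed(8)
  losses <- numeric(50)
  for (step in 1:50) {
    fwd <- net_forward(net, x, training = TRUE)
    losses[step] <- as.numeric(composite_loss(fwd$output, y))
    g <- gravseg:::composite_grad(fwd$output, y)
    gravseg:::tape_backward(fwd$tape, fwd$out_node, g)
    opt <- gravseg:::adam_step(opt)
  }
  non_decreasing <- sum(diff(losses) >= 0)
  expect_lte(non_decreasing, 5)
  expect_lt(losses[50], losses[1])
})
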