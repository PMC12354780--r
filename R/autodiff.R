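# Minimal reverse-mode tape for the segmentation network. Tensors are
# plain R arrays in (H, W, C, N) layout; each op appends a node holding
# the value and a backward closure. This is deliberately a micro engine:
# only the ops the U-Net needs, all single-threaded and seeded through
# R's own RNG so runs are bit-reproducible.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp
}

node_new <- function(tp, value, parents = list(), backfn = NULL, param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$param <- param
  tp$nodes[[length(tp$nodes) + 1L]] <- nd
  nd
}

accumulate <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# Reverse sweep from `out` seeded with `grad`; parameter-leaf gradients
# are accumulated into their parameter environments.
tape_backward <- function(tp, out, grad) {
  out$grad <- grad
  for (i in rev(seq_along(tp$nodes))) {
    nd <- tp$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$param)) {
      nd$param$grad <- nd$param$grad + nd$grad
    }
    if (is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) accumulate(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

param_new <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- array(0, dim = dim(value) %||% length(value))
  p$m <- p$grad
  p$v <- p$grad
  p$name <- name
  p
}

op_input <- function(tp, arr) node_new(tp, arr)

op_param <- function(tp, par) node_new(tp, par$value, param = par)

op_conv <- function(tp, x, wn, bn) {
  xv <- x$value; wv <- wn$value
  y <- cpp_conv2d_fw(xv, wv, bn$value)
  node_new(tp, y, parents = list(x, wn, bn), backfn = function(g) {
    r <- cpp_conv2d_bw(xv, wv, g)
    list(r$gx, r$gw, r$gb)
  })
}

# Batch normalization over (H, W, N) per channel. `state` carries the
# running statistics used in evaluation mode (momentum 0.1).
op_bn <- function(tp, x, gn, bn, state, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x$value)
  C <- d[3]
  perm <- aperm(x$value, c(1, 2, 4, 3))
  m <- matrix(perm, ncol = C)
  if (training) {
    mu <- colMeans(m)
    va <- colMeans(m^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(m, 2, mu, "-"), 2, istd, "*")
  y <- sweep(sweep(xhat, 2, gn$value, "*"), 2, bn$value, "+")
  ya <- aperm(array(y, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  node_new(tp, ya, parents = list(x, gn, bn), backfn = function(g) {
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    if (training) {
      nrm <- nrow(gm)
      t1 <- sweep(gm, 2, colMeans(gm), "-")
      t2 <- sweep(xhat, 2, colMeans(gm * xhat), "*")
      dx <- sweep(t1 - t2, 2, gn$value * istd, "*")
    } else {
      dx <- sweep(gm, 2, gn$value * istd, "*")
    }
    dxa <- aperm(array(dx, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
    list(dxa, dgamma, dbeta)
  })
}

op_relu <- function(tp, x) {
  mask <- x$value > 0
  node_new(tp, x$value * mask, parents = list(x),
           backfn = function(g) list(g * mask))
}

op_dropout <- function(tp, x, p, training) {
  if (!training || p <= 0) return(x)
  mask <- array((runif(length(x$value)) >= p) / (1 - p), dim = dim(x$value))
  node_new(tp, x$value * mask, parents = list(x),
           backfn = function(g) list(g * mask))
}

op_sigmoid <- function(tp, x) {
  y <- 1 / (1 + exp(-x$value))
  node_new(tp, y, parents = list(x), backfn = function(g) list(g * y * (1 - y)))
}

op_add <- function(tp, a, b) {
  node_new(tp, a$value + b$value, parents = list(a, b),
           backfn = function(g) list(g, g))
}

op_concat <- function(tp, xs) {
  ds <- lapply(xs, function(x) dim(x$value))
  cs <- vapply(ds, function(d) d[3], numeric(1))
  d0 <- ds[[1]]
  out <- array(0, dim = c(d0[1], d0[2], sum(cs), d0[4]))
  off <- 0L
  for (x in xs) {
    ci <- dim(x$value)[3]
    out[, , off + seq_len(ci), ] <- x$value
    off <- off + ci
  }
  node_new(tp, out, parents = xs, backfn = function(g) {
    res <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      ci <- cs[i]
      res[[i]] <- g[, , off + seq_len(ci), , drop = FALSE]
      off <- off + ci
    }
    res
  })
}

# reshape (H, W, C, N) -> (Ho*Wo*C*N, f*f) where each row is one pooling
# window, in a layout shared by the pooling ops below
pool_window_matrix <- function(a, f) {
  d <- dim(a)
  ho <- d[1] %/% f; wo <- d[2] %/% f
  dim(a) <- c(f, ho, f, wo, d[3], d[4])
  pm <- aperm(a, c(2, 4, 5, 6, 1, 3))
  dim(pm) <- c(ho * wo * d[3] * d[4], f * f)
  pm
}

pool_window_unmatrix <- function(m, d, f) {
  ho <- d[1] %/% f; wo <- d[2] %/% f
  dim(m) <- c(ho, wo, d[3], d[4], f, f)
  a <- aperm(m, c(5, 1, 6, 2, 3, 4))
  dim(a) <- d
  a
}

op_maxpool <- function(tp, x, f = 2L) {
  d <- dim(x$value)
  if (d[1] %% f != 0 || d[2] %% f != 0) {
    stop(sprintf("maxpool: spatial size %dx%d not divisible by %d",
                 d[1], d[2], f), call. = FALSE)
  }
  pm <- pool_window_matrix(x$value, f)
  am <- max.col(pm, ties.method = "first")
  val <- pm[cbind(seq_len(nrow(pm)), am)]
  y <- array(val, dim = c(d[1] %/% f, d[2] %/% f, d[3], d[4]))
  node_new(tp, y, parents = list(x), backfn = function(g) {
    gm <- matrix(0, nrow(pm), f * f)
    gm[cbind(seq_len(nrow(pm)), am)] <- as.numeric(g)
    list(pool_window_unmatrix(gm, d, f))
  })
}

op_avgpool <- function(tp, x, f) {
  d <- dim(x$value)
  pm <- pool_window_matrix(x$value, f)
  y <- array(rowMeans(pm), dim = c(d[1] %/% f, d[2] %/% f, d[3], d[4]))
  node_new(tp, y, parents = list(x), backfn = function(g) {
    gm <- matrix(as.numeric(g) / (f * f), nrow(pm), f * f)
    list(pool_window_unmatrix(gm, d, f))
  })
}

op_upnn <- function(tp, x, f = 2L) {
  d <- dim(x$value)
  y <- x$value[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), , ,
               drop = FALSE]
  node_new(tp, y, parents = list(x), backfn = function(g) {
    pm <- pool_window_matrix(g, f)
    list(array(rowSums(pm), dim = d))
  })
}

# --- Adam optimizer -----------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  structure(list(params = params, lr = lr, beta1 = beta1, beta2 = beta2,
                 eps = eps, t = 0L), class = "adam_state")
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (p in opt$params) {
    p$m <- opt$beta1 * p$m + (1 - opt$beta1) * p$grad
    p$v <- opt$beta2 * p$v + (1 - opt$beta2) * p$grad^2
    p$value <- p$value - opt$lr * (p$m / bc1) / (sqrt(p$v / bc2) + opt$eps)
    p$grad[] <- 0
  }
  opt
}

zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}
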