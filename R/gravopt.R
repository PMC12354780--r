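# Gravitational-search metaheuristic: continuous variant for
# hyperparameter tuning, binary variant for wrapper feature selection.
# Candidate solutions are masses; fitness-proportional masses attract
# each other, the gravitational constant decays exponentially, and the
# attractor set (Kbest) shrinks linearly, moving the swarm from
# exploration to exploitation. Minimization convention throughout.

#' Gravitational-search configuration
#'
#' @param population swarm size (default 25).
#' @param iterations number of generations (default 100).
#' @param g0 initial gravitational constant (default 100).
#' @param beta decay rate of `G(t) = g0 exp(-beta t / iterations)`
#'   (default 20).
#' @param kbest_final fraction of attractors retained at the final
#'   iteration (Kbest shrinks linearly from the whole population).
#' @param bounds d x 2 matrix (or list of `(low, high)`) of per-dimension
#'   box bounds; ignored in binary mode.
#' @param mode `"continuous"` or `"binary"`.
#' @param seed integer seed; runs are bit-reproducible.
#' @param patience early-stop after this many iterations without
#'   improvement of the best-ever fitness (`Inf` disables).
#' @return list of class `go_config`.
#' @export
go_config <- function(population = 25, iterations = 100, g0 = 100, beta = 20,
                      kbest_final = 0.05, bounds = NULL,
                      mode = c("continuous", "binary"), seed = 1L,
                      patience = Inf) {
  mode <- match.arg(mode)
  if (population < 2) stop("population must be >= 2", call. = FALSE)
  if (kbest_final <= 0 || kbest_final > 1) {
    stop("kbest_final must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(bounds) && is.list(bounds)) {
    bounds <- do.call(rbind, lapply(bounds, as.numeric))
  }
  structure(list(population = as.integer(population),
                 iterations = as.integer(iterations), g0 = g0, beta = beta,
                 kbest_final = kbest_final, bounds = bounds, mode = mode,
                 seed = as.integer(seed), patience = patience),
            class = "go_config")
}

#' Run the gravitational-search optimizer
#'
#' Minimizes `fitness` over the box defined by `cfg$bounds`
#' (continuous mode) or over bit vectors of length `nrow(cfg$bounds)`
#' (binary mode; bounds supply only the dimension). Per iteration:
#' masses are `(worst - fit) / (worst - best)` normalized to sum 1;
#' particle `i` receives acceleration
#' `sum_{j in Kbest} rand * G(t) * M_j * (x_j - x_i) / (||x_j - x_i|| + eps)`
#' (the particle's own mass cancels from force / mass);
#' `velocity = rand * velocity + acceleration`; positions move by the
#' velocity and are clamped to the bounds. In binary mode a bit flips
#' with probability `|tanh(velocity)|`.
#'
#' @param fitness function mapping a position vector to a finite scalar.
#' @param cfg a [go_config()].
#' @return list of class `go_result`: `best_position`, `best_fitness`,
#'   `history` (per-iteration best-so-far, monotone non-increasing),
#'   `mean_history`, `evaluations`, `converged_at` (iteration where
#'   patience triggered, `NA` otherwise).
#' @export
go_optimize <- function(fitness, cfg) {
  stopifnot(inherits(cfg, "go_config"))
  if (is.null(cfg$bounds)) stop("cfg$bounds must be set", call. = FALSE)
  d <- nrow(cfg$bounds)
  lo <- cfg$bounds[, 1]; hi <- cfg$bounds[, 2]
  if (any(hi <= lo) && cfg$mode == "continuous") {
    stop("bounds must satisfy low < high", call. = FALSE)
  }
  binary <- cfg$mode == "binary"
  with_seed(cfg$seed, {
    P <- cfg$population; Tmax <- cfg$iterations
    pos <- if (binary) {
      matrix(runif(P * d) < 0.5, P, d) * 1
    } else {
      matrix(runif(P * d, rep(lo, each = P), rep(hi, each = P)), P, d)
    }
    vel <- matrix(0, P, d)
    eval_all <- function(pos) apply(pos, 1, fitness)
    evals <- 0L
    best_pos <- NULL; best_fit <- Inf
    history <- numeric(Tmax); mean_hist <- numeric(Tmax)
    converged_at <- NA_integer_; stall <- 0L
    eps <- 1e-12
    for (t in seq_len(Tmax)) {
      fit <- eval_all(pos)
      if (t == 1 && any(!is.finite(fit))) {
        bad <- which(!is.finite(fit))[1]
        stop("non-finite fitness at initial position: ",
             paste(signif(pos[bad, ], 4), collapse = ", "), call. = FALSE)
      }
      if (any(!is.finite(fit))) fit[!is.finite(fit)] <- max(fit[is.finite(fit)])
      evals <- evals + P
      it_best <- which.min(fit)
      if (fit[it_best] < best_fit) {
        best_fit <- fit[it_best]; best_pos <- pos[it_best, ]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      history[t] <- best_fit
      mean_hist[t] <- mean(fit)
      if (stall >= cfg$patience) {
        converged_at <- t
        history <- history[seq_len(t)]
        mean_hist <- mean_hist[seq_len(t)]
        break
      }
      worst <- max(fit); bst <- min(fit)
      m <- if (worst > bst) (worst - fit) / (worst - bst) else rep(1, P)
      M <- m / sum(m)
      G <- cfg$g0 * exp(-cfg$beta * t / Tmax)
      kb_final <- max(1L, round(cfg$kbest_final * P))
      kbest_n <- if (Tmax > 1) {
        as.integer(round(P - (P - kb_final) * (t - 1) / (Tmax - 1)))
      } else kb_final
      kbest <- order(M, decreasing = TRUE)[seq_len(kbest_n)]
      acc <- matrix(0, P, d)
      for (j in kbest) {
        diff <- sweep(-pos, 2, pos[j, ], "+")     # x_j - x_i for all i
        dist <- sqrt(rowSums(diff^2))
        w <- G * M[j] / (dist + eps)
        w[j] <- 0
        acc <- acc + matrix(runif(P * d), P, d) * (w * diff)
      }
      vel <- matrix(runif(P * d), P, d) * vel + acc
      if (binary) {
        flip <- matrix(runif(P * d), P, d) < abs(tanh(vel))
        pos[flip] <- 1 - pos[flip]
      } else {
        pos <- pos + vel
        pos <- pmin(pmax(pos, rep(lo, each = P)), rep(hi, each = P))
      }
    }
    structure(list(best_position = best_pos, best_fitness = best_fit,
                   history = history, mean_history = mean_hist,
                   evaluations = evals, converged_at = converged_at),
              class = "go_result")
  })
}

#' Cross-validated scorer for wrapper feature selection
#'
#' Builds the fitness used by [go_select_features()]: k-fold
#' cross-validated logistic log-loss of the masked feature columns plus
#' a sparsity penalty `lambda * (subset size / d)`.
#'
#' @param features numeric matrix or data.frame of features.
#' @param labels binary labels (0/1).
#' @param lambda sparsity penalty weight (default 0.02).
#' @param nfolds CV folds (default 3, stratified).
#' @param seed fold-assignment seed.
#' @return function mapping a 0/1 mask to a scalar loss.
#' @export
make_cv_scorer <- function(features, labels, lambda = 0.02, nfolds = 3,
                           seed = 1L) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  d <- ncol(X)
  folds <- with_seed(seed, stratified_folds(y, nfolds))
  cache <- new.env(parent = emptyenv())
  function(mask) {
    mask <- as.numeric(mask)
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    sel <- which(mask > 0.5)
    if (length(sel) == 0) return(Inf)
    ll <- 0
    for (f in seq_len(nfolds)) {
      tr <- folds != f; te <- !tr
      df_tr <- data.frame(y = y[tr], X[tr, sel, drop = FALSE])
      fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr,
                                         family = stats::binomial()))
      p <- suppressWarnings(stats::predict(fit,
             newdata = data.frame(X[te, sel, drop = FALSE]), type = "response"))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll <- ll + mean(-(y[te] * log(p) + (1 - y[te]) * log(1 - p)))
    }
    out <- ll / nfolds + lambda * length(sel) / d
    cache[[key]] <- out
    out
  }
}

# stratified fold ids (uses the current RNG state)
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Wrapper feature selection by binary gravitational search
#'
#' Runs the binary-mode optimizer over feature-subset bit vectors; an
#' empty subset is repaired to the single feature with the strongest
#' univariate class separation (absolute two-sample t statistic).
#'
#' @param features feature matrix or data.frame (>= 2 columns).
#' @param labels binary labels.
#' @param scorer fitness over masks, e.g. from [make_cv_scorer()]; a
#'   scorer failure on a subset is assigned the worst fitness seen so
#'   far.
#' @param cfg a [go_config()] (mode is forced to binary; bounds are
#'   derived from the feature count).
#' @return list with `mask` (0/1 vector named by feature columns),
#'   `selected` (column names), and `result` (the [go_optimize()]
#'   output).
#' @export
go_select_features <- function(features, labels, scorer, cfg = go_config()) {
  X <- as.matrix(features)
  d <- ncol(X)
  if (d < 2) stop("need at least 2 features", call. = FALSE)
  y <- as.numeric(labels)
  # univariate fallback feature for empty-subset repair
  tstat <- vapply(seq_len(d), function(j) {
    a <- X[y == 1, j]; b <- X[y == 0, j]
    s <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    if (!is.finite(s) || s == 0) 0 else abs(mean(a) - mean(b)) / s
  }, numeric(1))
  best_single <- which.max(tstat)
  worst_seen <- -Inf
  wrapped <- function(mask) {
    mask <- round(mask)
    if (sum(mask) == 0) {
      mask[best_single] <- 1
    }
    val <- tryCatch(scorer(mask), error = function(e) NA_real_)
    if (!is.finite(val)) {
      val <- if (is.finite(worst_seen)) worst_seen else 1e12
    }
    worst_seen <<- max(worst_seen, val)
    val
  }
  cfg$mode <- "binary"
  cfg$bounds <- cbind(rep(0, d), rep(1, d))
  res <- go_optimize(wrapped, cfg)
  mask <- round(res$best_position)
  if (sum(mask) == 0) mask[best_single] <- 1
  cn <- colnames(X) %||% paste0("f", seq_len(d))
  names(mask) <- cn
  list(mask = mask, selected = cn[mask == 1], result = res)
}

#' Hyperparameter tuning by gravitational search
#'
#' Wraps [go_optimize()] over a named parameter space. Log-scaled
#' dimensions are searched in log10 space; integer dimensions are
#' rounded on decoding. A `train_fn` exception yields the worst fitness
#' seen so far and the search continues.
#'
#' @param train_fn function taking a named list of decoded parameters
#'   and returning a validation loss to minimize.
#' @param space named list; each element is a list with `low`, `high`,
#'   and optional flags `log` and `integer`.
#' @param cfg a [go_config()] (bounds are derived from `space`).
#' @return list with `best_params` (named, decoded), `best_fitness`,
#'   and `result`.
#' @export
go_tune <- function(train_fn, space, cfg = go_config()) {
  enc <- function(s) if (isTRUE(s$log)) log10(c(s$low, s$high)) else c(s$low, s$high)
  bounds <- t(vapply(space, enc, numeric(2)))
  decode <- function(x) go_decode(space, x)
  worst_seen <- -Inf
  fitness <- function(x) {
    val <- tryCatch(train_fn(decode(x)), error = function(e) NA_real_)
    if (!is.finite(val)) val <- if (is.finite(worst_seen)) worst_seen else 1e12
    worst_seen <<- max(worst_seen, val)
    val
  }
  cfg$mode <- "continuous"
  cfg$bounds <- bounds
  res <- go_optimize(fitness, cfg)
  list(best_params = decode(res$best_position),
       best_fitness = res$best_fitness, result = res)
}

# decode an encoded search-space position into named parameter values:
# log dimensions back-transform from log10, integer dimensions round
go_decode <- function(space, x) {
  out <- vector("list", length(space))
  names(out) <- names(space)
  for (i in seq_along(space)) {
    v <- x[i]
    if (isTRUE(space[[i]]$log)) v <- 10^v
    if (isTRUE(space[[i]]$integer)) v <- as.integer(round(v))
    out[[i]] <- v
  }
  out
}
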