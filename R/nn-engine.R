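# Hand-rolled 1-D CNN engine. No deep-learning framework ships with this
# stack, so forward/backward passes are implemented here directly: dense
# algebra through BLAS, the sliding-window gather/scatter and max-pooling
# through the compiled kernels in src/nn_ops.cpp. Batches of B windows of
# length L are stored as (B*L) x C matrices, rows ordered sample-major
# (see encoding.R).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9
ADAM_BETA1 <- 0.9
ADAM_BETA2 <- 0.999
ADAM_EPS <- 1e-8

glorot <- function(nin, nout, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build a trainable model from an architecture specification
#'
#' Lays out the layer stack, verifies that the input window survives every
#' pooling step (erroring with the offending block otherwise), and
#' initializes all weights (Glorot-uniform, deterministic given `seed`).
#'
#' @param spec A [model_spec].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `splice_model`: list with `spec`, flat `params`
#'   (trainable tensors), `state` (batch-norm running statistics), and `dims`
#'   (per-block sequence lengths).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  L <- spec$input_window$window_length
  C <- 4L
  params <- list()
  state <- list()
  dims <- list(L_in = integer(), L_out = integer(), C_in = integer())
  for (k in seq_along(spec$blocks)) {
    b <- spec$blocks[[k]]
    dims$L_in[k] <- L
    dims$C_in[k] <- C
    bn_ch <- if (spec$bn_before_activation) C else b$n_filters
    params[[sprintf("blk%d.bn.gamma", k)]] <- rep(1, bn_ch)
    params[[sprintf("blk%d.bn.beta", k)]] <- rep(0, bn_ch)
    state[[sprintf("blk%d.run_mean", k)]] <- rep(0, bn_ch)
    state[[sprintf("blk%d.run_var", k)]] <- rep(1, bn_ch)
    fan_in <- b$filter_width * C
    fan_out <- b$filter_width * b$n_filters
    params[[sprintf("blk%d.conv.W", k)]] <-
      glorot(b$filter_width * C, b$n_filters, fan_in, fan_out)
    params[[sprintf("blk%d.conv.b", k)]] <- rep(0, b$n_filters)
    Lp <- (L - b$pool_window) %/% b$pool_stride + 1L
    if (Lp < 1L) {
      stop("build_model: block ", k, " pools a length-", L,
           " sequence below 1 (pool window ", b$pool_window,
           "); window too short for the stack")
    }
    L <- Lp
    C <- b$n_filters
    dims$L_out[k] <- L
  }
  dims$L_final <- L
  dims$C_final <- C
  if (spec$flatten_first) {
    d_in <- L * C
    for (j in seq_along(spec$dense_units)) {
      u <- spec$dense_units[j]
      params[[sprintf("dense%d.W", j)]] <- glorot(d_in, u, d_in, u)
      params[[sprintf("dense%d.b", j)]] <- rep(0, u)
      d_in <- u
    }
    flat_dim <- d_in
  } else {
    d_in <- C
    for (j in seq_along(spec$dense_units)) {
      u <- spec$dense_units[j]
      params[[sprintf("dense%d.W", j)]] <- glorot(d_in, u, d_in, u)
      params[[sprintf("dense%d.b", j)]] <- rep(0, u)
      d_in <- u
    }
    flat_dim <- L * d_in
  }
  dims$flat_dim <- flat_dim
  params[["out.W"]] <- glorot(flat_dim, spec$output_classes,
                              flat_dim, spec$output_classes)
  params[["out.b"]] <- rep(0, spec$output_classes)
  structure(list(spec = spec, params = params, state = state, dims = dims,
                 init_seed = as.integer(seed)),
            class = "splice_model")
}

#' @export
print.splice_model <- function(x, ...) {
  cat(sprintf("<splice_model> %d trainable parameters\n", count_params(x)))
  print(x$spec)
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `splice_model`.
#' @return Integer count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

add_bias <- function(Z, b) sweep(Z, 2L, b, "+")

bn_forward <- function(X, gamma, beta, run_mean, run_var, training) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu)
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2L, inv, "*")
    out <- add_bias(sweep(xhat, 2L, gamma, "*"), beta)
    list(out = out, xhat = xhat, inv = inv,
         new_mean = BN_MOMENTUM * run_mean + (1 - BN_MOMENTUM) * mu,
         new_var = BN_MOMENTUM * run_var + (1 - BN_MOMENTUM) * v)
  } else {
    inv <- 1 / sqrt(run_var + BN_EPS)
    xhat <- sweep(sweep(X, 2L, run_mean), 2L, inv, "*")
    list(out = add_bias(sweep(xhat, 2L, gamma, "*"), beta))
  }
}

bn_backward <- function(dY, xhat, inv, gamma) {
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  # dX = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  dX <- sweep(dxhat, 2L, m1) - sweep(xhat, 2L, m2, "*")
  dX <- sweep(dX, 2L, inv, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

stack_to_flat <- function(X, B, L) {
  C <- ncol(X)
  t(matrix(aperm(array(X, dim = c(L, B, C)), c(1L, 3L, 2L)), nrow = L * C))
}

flat_to_stack <- function(F, B, L, C) {
  matrix(aperm(array(t(F), dim = c(L, C, B)), c(1L, 3L, 2L)),
         nrow = B * L, ncol = C)
}

# Forward pass. X is the stacked (B*L) x 4 batch. Returns probabilities and,
# when keep_cache, every intermediate needed by nn_backward. In training mode
# batch statistics are used and the updated running statistics returned.
nn_forward <- function(model, X, B, training = FALSE, keep_cache = training) {
  spec <- model$spec
  p <- model$params
  st <- model$state
  cache <- list(B = B, blocks = vector("list", length(spec$blocks)))
  new_state <- st
  for (k in seq_along(spec$blocks)) {
    bspec <- spec$blocks[[k]]
    L <- model$dims$L_in[k]
    ck <- list(X_in = if (keep_cache) X else NULL)
    if (spec$bn_before_activation) {
      bn <- bn_forward(X, p[[sprintf("blk%d.bn.gamma", k)]],
                       p[[sprintf("blk%d.bn.beta", k)]],
                       st[[sprintf("blk%d.run_mean", k)]],
                       st[[sprintf("blk%d.run_var", k)]], training)
      A <- bn$out
      A[A < 0] <- 0
      ck$bn <- if (keep_cache) bn else NULL
      ck$A <- if (keep_cache) A else NULL
      Xcol <- im2col_1d(A, B, L, bspec$filter_width)
      Z <- add_bias(Xcol %*% p[[sprintf("blk%d.conv.W", k)]],
                    p[[sprintf("blk%d.conv.b", k)]])
      ck$Xcol <- if (keep_cache) Xcol else NULL
      pool <- maxpool_1d(Z, B, L, bspec$pool_window, bspec$pool_stride)
    } else {
      Xcol <- im2col_1d(X, B, L, bspec$filter_width)
      Z <- add_bias(Xcol %*% p[[sprintf("blk%d.conv.W", k)]],
                    p[[sprintf("blk%d.conv.b", k)]])
      ck$Xcol <- if (keep_cache) Xcol else NULL
      bn <- bn_forward(Z, p[[sprintf("blk%d.bn.gamma", k)]],
                       p[[sprintf("blk%d.bn.beta", k)]],
                       st[[sprintf("blk%d.run_mean", k)]],
                       st[[sprintf("blk%d.run_var", k)]], training)
      A <- bn$out
      A[A < 0] <- 0
      ck$bn <- if (keep_cache) bn else NULL
      ck$A <- if (keep_cache) A else NULL
      pool <- maxpool_1d(A, B, L, bspec$pool_window, bspec$pool_stride)
    }
    if (training) {
      new_state[[sprintf("blk%d.run_mean", k)]] <- bn$new_mean
      new_state[[sprintf("blk%d.run_var", k)]] <- bn$new_var
    }
    ck$argmax <- if (keep_cache) pool$argmax else NULL
    ck$L <- L
    X <- pool$out
    if (keep_cache) cache$blocks[[k]] <- ck
  }
  Lf <- model$dims$L_final
  if (spec$flatten_first) {
    H <- stack_to_flat(X, B, Lf)
    cache$pre_dense <- if (keep_cache) H else NULL
    dense_in <- H
  } else {
    dense_in <- X
  }
  cache$dense <- vector("list", length(spec$dense_units))
  H <- dense_in
  for (j in seq_along(spec$dense_units)) {
    Zj <- add_bias(H %*% p[[sprintf("dense%d.W", j)]],
                   p[[sprintf("dense%d.b", j)]])
    Aj <- Zj
    Aj[Aj < 0] <- 0
    if (keep_cache) cache$dense[[j]] <- list(H_in = H, Z = Zj, A = Aj)
    H <- Aj
  }
  if (spec$flatten_first) {
    Fm <- H
  } else {
    Fm <- stack_to_flat(H, B, Lf)
    cache$pre_flat <- if (keep_cache) H else NULL
  }
  cache$Fm <- if (keep_cache) Fm else NULL
  logits <- add_bias(Fm %*% p[["out.W"]], p[["out.b"]])
  probs <- softmax_rows(logits)
  list(probs = probs, cache = if (keep_cache) cache else NULL,
       new_state = if (training) new_state else NULL)
}

# Backward pass for categorical cross-entropy; returns the gradient of the
# mean loss (plus the L1 penalty on convolution kernels) for every trainable
# tensor, keyed like model$params.
nn_backward <- function(model, cache, probs, Y) {
  spec <- model$spec
  p <- model$params
  B <- cache$B
  grads <- list()
  dlogits <- (probs - Y) / B
  grads[["out.W"]] <- crossprod(cache$Fm, dlogits)
  grads[["out.b"]] <- colSums(dlogits)
  dF <- tcrossprod(dlogits, p[["out.W"]])
  Lf <- model$dims$L_final
  if (spec$flatten_first) {
    dH <- dF
  } else {
    nd <- length(spec$dense_units)
    Cd <- if (nd > 0L) spec$dense_units[nd] else model$dims$C_final
    dH <- flat_to_stack(dF, B, Lf, Cd)
  }
  for (j in rev(seq_along(spec$dense_units))) {
    ck <- cache$dense[[j]]
    dZ <- dH * (ck$Z > 0)
    grads[[sprintf("dense%d.W", j)]] <- crossprod(ck$H_in, dZ)
    grads[[sprintf("dense%d.b", j)]] <- colSums(dZ)
    dH <- tcrossprod(dZ, p[[sprintf("dense%d.W", j)]])
  }
  if (spec$flatten_first) {
    dX <- flat_to_stack(dH, B, Lf, model$dims$C_final)
  } else {
    dX <- dH
  }
  l1 <- spec$l1_strength
  for (k in rev(seq_along(spec$blocks))) {
    bspec <- spec$blocks[[k]]
    ck <- cache$blocks[[k]]
    L <- ck$L
    Wk <- p[[sprintf("blk%d.conv.W", k)]]
    if (spec$bn_before_activation) {
      # pool <- conv <- relu <- bn
      dZ <- maxpool_1d_backward(dX, ck$argmax, B * L)
      grads[[sprintf("blk%d.conv.W", k)]] <-
        crossprod(ck$Xcol, dZ) + l1 * sign(Wk)
      grads[[sprintf("blk%d.conv.b", k)]] <- colSums(dZ)
      dXcol <- tcrossprod(dZ, Wk)
      dA <- col2im_1d(dXcol, B, L, bspec$filter_width, ncol(ck$A))
      dBN <- dA * (ck$A > 0)
      bb <- bn_backward(dBN, ck$bn$xhat, ck$bn$inv,
                        p[[sprintf("blk%d.bn.gamma", k)]])
      grads[[sprintf("blk%d.bn.gamma", k)]] <- bb$dgamma
      grads[[sprintf("blk%d.bn.beta", k)]] <- bb$dbeta
      dX <- bb$dX
    } else {
      # pool <- relu <- bn <- conv
      dA <- maxpool_1d_backward(dX, ck$argmax, B * L)
      dBN <- dA * (ck$A > 0)
      bb <- bn_backward(dBN, ck$bn$xhat, ck$bn$inv,
                        p[[sprintf("blk%d.bn.gamma", k)]])
      grads[[sprintf("blk%d.bn.gamma", k)]] <- bb$dgamma
      grads[[sprintf("blk%d.bn.beta", k)]] <- bb$dbeta
      dZ <- bb$dX
      grads[[sprintf("blk%d.conv.W", k)]] <-
        crossprod(ck$Xcol, dZ) + l1 * sign(Wk)
      grads[[sprintf("blk%d.conv.b", k)]] <- colSums(dZ)
      dXcol <- tcrossprod(dZ, Wk)
      dX <- col2im_1d(dXcol, B, L, bspec$filter_width,
                      model$dims$C_in[k])
    }
  }
  grads
}

nn_loss <- function(model, probs, Y) {
  ce <- -mean(rowSums(Y * log(probs + 1e-12)))
  l1 <- model$spec$l1_strength
  if (l1 > 0) {
    for (k in seq_along(model$spec$blocks)) {
      ce <- ce + l1 * sum(abs(model$params[[sprintf("blk%d.conv.W", k)]]))
    }
  }
  ce
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0))
}

adam_step <- function(params, grads, opt, lr) {
  opt$t <- opt$t + 1L
  c1 <- 1 - ADAM_BETA1^opt$t
  c2 <- 1 - ADAM_BETA2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- ADAM_BETA1 * opt$m[[nm]] + (1 - ADAM_BETA1) * g
    opt$v[[nm]] <- ADAM_BETA2 * opt$v[[nm]] + (1 - ADAM_BETA2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + ADAM_EPS)
  }
  list(params = params, opt = opt)
}

#' Predict class probabilities for encoded windows
#'
#' Runs the network in inference mode (batch-norm running statistics) over
#' batches; results are independent of `batch_size`.
#'
#' @param model A `splice_model`.
#' @param xrows N x (window_length * 4) matrix of flat encoded windows (the
#'   dataset layout).
#' @param batch_size Windows per forward pass, default 256.
#' @return N x 3 matrix of probabilities, columns donor/acceptor/other.
#' @export
predict_probs <- function(model, xrows, batch_size = 256L) {
  L <- model$spec$input_window$window_length
  stopifnot(ncol(xrows) == L * 4L)
  n <- nrow(xrows)
  out <- matrix(NA_real_, n, 3L, dimnames = list(NULL, LABELS))
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    X <- rows_to_stack(xrows[i:j, , drop = FALSE], L)
    out[i:j, ] <- nn_forward(model, X, j - i + 1L, training = FALSE)$probs
    i <- j + 1L
  }
  out
}

#' Train a model on a labeled dataset
#'
#' Minibatch Adam with categorical cross-entropy and the step learning-rate
#' schedule of the [train_spec]. With `tspec$repetitions > 1`, the model is
#' re-initialized and trained that many times from different seeds and the
#' per-epoch histories are averaged; the returned `model` is the repetition
#' with the best final validation accuracy.
#'
#' @param model A `splice_model` (its spec is reused to re-initialize
#'   repetitions), or a [model_spec].
#' @param ds A `labeled_dataset` that has been through [split_dataset]
#'   (training uses the "train" split, per-epoch evaluation the
#'   "validation" split).
#' @param tspec A [train_spec].
#' @param verbose Print one line per epoch.
#' @return An object of class `splice_fit`: `model`, `history` (averaged
#'   over repetitions), `runs` (list of per-repetition model + history).
#' @export
train <- function(model, ds, tspec = train_spec(), verbose = FALSE) {
  spec <- if (inherits(model, "model_spec")) model else model$spec
  stopifnot(inherits(ds, "labeled_dataset"), inherits(tspec, "train_spec"))
  if (ds$spec$window_length != spec$input_window$window_length) {
    stop("train: dataset window length ", ds$spec$window_length,
         " does not match model input ", spec$input_window$window_length)
  }
  if (!identical(tspec$optimizer, "adam")) {
    stop("train: only the Adam optimizer is implemented (got '",
         tspec$optimizer, "')")
  }
  if (all(is.na(ds$split))) {
    stop("train: dataset has no split assignment; call split_dataset() first")
  }
  runs <- vector("list", tspec$repetitions)
  for (r in seq_len(tspec$repetitions)) {
    init_seed <- (tspec$seed + 7919L * (r - 1L)) %% .Machine$integer.max
    m <- build_model(spec, seed = init_seed)
    runs[[r]] <- fit_one(m, ds, tspec,
                         run_seed = (tspec$seed + 104729L * (r - 1L)) %%
                           .Machine$integer.max,
                         verbose = verbose)
  }
  hist_avg <- runs[[1L]]$history
  if (tspec$repetitions > 1L) {
    num <- sapply(runs, function(r) as.matrix(r$history), simplify = "array")
    hist_avg <- as.data.frame(apply(num, c(1L, 2L), mean))
  }
  final_val <- vapply(runs, function(r) {
    v <- r$history$val_accuracy
    if (all(is.na(v))) r$history$train_accuracy[length(v)] else v[length(v)]
  }, 0)
  best <- which.max(final_val)
  structure(list(model = runs[[best]]$model, history = hist_avg,
                 runs = runs, tspec = tspec, best_run = best),
            class = "splice_fit")
}

fit_one <- function(model, ds, tspec, run_seed, verbose = FALSE) {
  tr <- subset_dataset(ds, "train")
  va <- subset_dataset(ds, "validation")
  n <- nrow(tr$x)
  if (n == 0L) stop("train: empty training split")
  L <- model$spec$input_window$window_length
  opt <- adam_init(model$params)
  set.seed(run_seed)
  history <- data.frame(epoch = seq_len(tspec$epochs), lr = NA_real_,
                        train_loss = NA_real_, train_accuracy = NA_real_,
                        val_loss = NA_real_, val_accuracy = NA_real_)
  y_idx <- max.col(tr$y)
  for (epoch in seq_len(tspec$epochs)) {
    lr <- learning_rate_at(tspec, epoch)
    perm <- sample.int(n)
    tot_loss <- 0; tot_hit <- 0
    for (start in seq(1L, n, by = tspec$batch_size)) {
      idx <- perm[start:min(start + tspec$batch_size - 1L, n)]
      B <- length(idx)
      X <- rows_to_stack(tr$x[idx, , drop = FALSE], L)
      Y <- tr$y[idx, , drop = FALSE]
      fw <- nn_forward(model, X, B, training = TRUE)
      loss <- nn_loss(model, fw$probs, Y)
      if (!is.finite(loss)) {
        stop("train: non-finite loss at epoch ", epoch,
             " (batch starting ", start, "); try a lower learning rate")
      }
      grads <- nn_backward(model, fw$cache, fw$probs, Y)
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params
      opt <- upd$opt
      model$state <- fw$new_state
      tot_loss <- tot_loss + loss * B
      tot_hit <- tot_hit + sum(max.col(fw$probs) == y_idx[idx])
    }
    history$lr[epoch] <- lr
    history$train_loss[epoch] <- tot_loss / n
    history$train_accuracy[epoch] <- tot_hit / n
    if (nrow(va$x) > 0L) {
      pv <- predict_probs(model, va$x)
      history$val_loss[epoch] <- -mean(rowSums(va$y * log(pv + 1e-12)))
      history$val_accuracy[epoch] <- mean(max.col(pv) == max.col(va$y))
    }
    if (verbose) {
      message(sprintf(
        "epoch %d: lr=%.5f loss=%.4f acc=%.4f val_loss=%.4f val_acc=%.4f",
        epoch, lr, history$train_loss[epoch], history$train_accuracy[epoch],
        history$val_loss[epoch], history$val_accuracy[epoch]))
    }
  }
  list(model = model, history = history)
}

#' @export
print.splice_fit <- function(x, ...) {
  h <- x$history
  last <- nrow(h)
  cat(sprintf(
    "<splice_fit> %d epochs x %d repetition(s); final train acc %.4f, val acc %.4f\n",
    last, length(x$runs), h$train_accuracy[last], h$val_accuracy[last]))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Weights, batch-norm state and the full architecture specification are
#' stored together in a single RDS file (no HDF5 bindings are assumed to be
#' installed).
#'
#' @param model A `splice_model`.
#' @param path File path.
#' @return `load_model` returns the restored `splice_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "splice_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "splice_model"))
  m
}
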