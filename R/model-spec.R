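#' Convolutional block specification
#'
#' One block applies, in order, batch normalization, ReLU, a 1-D convolution
#' (`n_filters` filters of odd width `filter_width`, "same" zero padding,
#' L1 penalty on the kernel), and 1-D max pooling.
#'
#' @param n_filters Positive integer.
#' @param filter_width Positive odd integer.
#' @param pool_window Pooling window, default 2.
#' @param pool_stride Pooling stride; `NULL` (default) means equal to
#'   `pool_window`, the common framework default for "no stride given".
#' @return An object of class `cb_spec`.
#' @export
cb_spec <- function(n_filters, filter_width, pool_window = 2L,
                    pool_stride = NULL) {
  stopifnot(n_filters >= 1L, filter_width >= 1L, filter_width %% 2L == 1L,
            pool_window >= 1L)
  if (is.null(pool_stride)) pool_stride <- pool_window
  structure(list(n_filters = as.integer(n_filters),
                 filter_width = as.integer(filter_width),
                 pool_window = as.integer(pool_window),
                 pool_stride = as.integer(pool_stride)),
            class = "cb_spec")
}

#' Model architecture specification
#'
#' The default reproduces the published architecture: four convolutional
#' blocks with 16, 32, 64 and 64 filters of widths 11, 11, 21 and 41, two
#' position-wise dense layers of 32 and 16 units, a flattening layer, and a
#' 3-unit softmax output. The dense layers act on the channel axis *before*
#' flattening, exactly as the architecture diagram orders them; set
#' `flatten_first = TRUE` for the conventional flatten-then-dense variant.
#'
#' @param blocks List of [cb_spec].
#' @param dense_units Integer vector, default c(32, 16).
#' @param l1_strength Non-negative L1 penalty on convolution kernels,
#'   default 7e-5.
#' @param input_window A [window_spec] (default flanking 200, window 401).
#' @param flatten_first Logical, default FALSE (see above).
#' @param bn_before_activation Logical; TRUE (default) follows the block
#'   listing order batch-norm -> ReLU -> conv. FALSE applies the batch norm
#'   after the convolution instead (conv -> batch-norm -> ReLU), the wiring
#'   some frameworks default to; the diagram alone cannot settle it.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(blocks = list(cb_spec(16L, 11L), cb_spec(32L, 11L),
                                     cb_spec(64L, 21L), cb_spec(64L, 41L)),
                       dense_units = c(32L, 16L),
                       l1_strength = 7e-5,
                       input_window = window_spec(200L),
                       flatten_first = FALSE,
                       bn_before_activation = TRUE) {
  stopifnot(length(blocks) >= 1L,
            all(vapply(blocks, inherits, TRUE, "cb_spec")),
            l1_strength >= 0,
            inherits(input_window, "window_spec"))
  structure(list(blocks = blocks,
                 dense_units = as.integer(dense_units),
                 output_classes = 3L,
                 l1_strength = l1_strength,
                 input_window = input_window,
                 flatten_first = isTRUE(flatten_first),
                 bn_before_activation = isTRUE(bn_before_activation)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> window %d x 4; %d conv blocks (filters %s, widths %s); dense %s; L1 %g\n",
              x$input_window$window_length, length(x$blocks),
              paste(vapply(x$blocks, `[[`, 0L, "n_filters"), collapse = "/"),
              paste(vapply(x$blocks, `[[`, 0L, "filter_width"), collapse = "/"),
              paste(x$dense_units, collapse = "/"), x$l1_strength))
  invisible(x)
}

#' Training schedule specification
#'
#' Categorical cross-entropy loss and Adam optimization, with a single-step
#' learning-rate schedule: `initial_lr` for epochs before `lr_drop_epoch`,
#' then `initial_lr / lr_drop_factor` for every later epoch (the default,
#' drop at epoch 7, keeps 0.001 for the first six epochs and 0.0005
#' thereafter). Set `lr_halve_each_epoch = TRUE` to instead keep halving
#' every epoch from `lr_drop_epoch` on.
#'
#' @param initial_lr Initial learning rate, default 0.001.
#' @param lr_drop_epoch First epoch (1-based) at the reduced rate, default 7.
#' @param lr_drop_factor Division factor, default 2.
#' @param epochs Number of epochs, default 10.
#' @param batch_size Minibatch size, default 32.
#' @param repetitions Independent training repetitions to average, default 3.
#' @param seed Integer seed.
#' @param lr_halve_each_epoch Logical, default FALSE.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(initial_lr = 0.001, lr_drop_epoch = 7L,
                       lr_drop_factor = 2, epochs = 10L, batch_size = 32L,
                       repetitions = 3L, seed = 1L,
                       lr_halve_each_epoch = FALSE) {
  stopifnot(initial_lr > 0, epochs >= 1L, batch_size >= 1L,
            repetitions >= 1L, lr_drop_factor > 0)
  structure(list(loss = "categorical_crossentropy", optimizer = "adam",
                 initial_lr = initial_lr,
                 lr_drop_epoch = as.integer(lr_drop_epoch),
                 lr_drop_factor = lr_drop_factor,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed),
                 lr_halve_each_epoch = isTRUE(lr_halve_each_epoch)),
            class = "train_spec")
}

#' Per-epoch learning rate under a train spec
#'
#' @param tspec A [train_spec].
#' @param epoch 1-based epoch index (vectorized).
#' @return Numeric vector of learning rates.
#' @export
learning_rate_at <- function(tspec, epoch) {
  if (tspec$lr_halve_each_epoch) {
    k <- pmax(0L, epoch - tspec$lr_drop_epoch + 1L)
    tspec$initial_lr / tspec$lr_drop_factor^k
  } else {
    ifelse(epoch >= tspec$lr_drop_epoch,
           tspec$initial_lr / tspec$lr_drop_factor,
           tspec$initial_lr)
  }
}

#' Hyperparameter search space
#'
#' Enumerations for random architecture/schedule search. The defaults are
#' the published tuning grid: optimizers Adam/Nadam/SGD; initial learning
#' rates 0.01 and 0.001; 3-6 convolutional blocks; filter counts
#' 8/16/32/48/64/80/96; filter widths 5 to 65 in steps of 2; batch sizes
#' 16/32/64; 8/10/12/14 epochs; dropout or L1 or L2 regularization. Every
#' default [model_spec]/[train_spec] value is a member of its enumeration.
#'
#' @param optimizers,initial_lrs,n_blocks,filter_counts,filter_widths,batch_sizes,epoch_counts
#'   Enumeration vectors.
#' @param regularizers Named list of regularizer kinds mapping to their
#'   strength enumerations.
#' @return An object of class `search_space`.
#' @export
search_space <- function(optimizers = c("adam", "nadam", "sgd"),
                         initial_lrs = c(0.01, 0.001),
                         n_blocks = 3:6,
                         filter_counts = c(8L, 16L, 32L, 48L, 64L, 80L, 96L),
                         filter_widths = seq(5L, 65L, by = 2L),
                         batch_sizes = c(16L, 32L, 64L),
                         epoch_counts = c(8L, 10L, 12L, 14L),
                         regularizers = list(
                           dropout = c(0.1, 0.2),
                           l1 = c(4e-5, 7e-5, 1e-4),
                           l2 = c(4e-5, 7e-5, 1e-4))) {
  stopifnot(length(optimizers) > 0, length(initial_lrs) > 0,
            length(n_blocks) > 0, length(filter_counts) > 0,
            length(filter_widths) > 0, length(batch_sizes) > 0,
            length(epoch_counts) > 0, length(regularizers) > 0)
  structure(list(optimizers = optimizers, initial_lrs = initial_lrs,
                 n_blocks = as.integer(n_blocks),
                 filter_counts = as.integer(filter_counts),
                 filter_widths = as.integer(filter_widths),
                 batch_sizes = as.integer(batch_sizes),
                 epoch_counts = as.integer(epoch_counts),
                 regularizers = regularizers),
            class = "search_space")
}

#' Sample architecture/schedule configurations from a search space
#'
#' `n` independent uniform draws, deterministic given `seed`. Each draw picks
#' a block count, then per-block filter counts and widths, plus an optimizer,
#' learning rate, batch size, epoch count and one regularizer setting.
#'
#' @param space A [search_space].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param input_window [window_spec] attached to each sampled model.
#' @return List of length `n`; each element has `model` ([model_spec]) and
#'   `train` ([train_spec]) plus `regularizer` (kind and strength).
#' @export
sample_search_space <- function(space, n, seed = 1L,
                                input_window = window_spec(200L)) {
  stopifnot(inherits(space, "search_space"), n >= 1L)
  set.seed(seed)
  draw <- function(x) x[[sample.int(length(x), 1L)]]  # safe for length 1
  lapply(seq_len(n), function(i) {
    nb <- draw(space$n_blocks)
    blocks <- lapply(seq_len(nb), function(b) {
      cb_spec(draw(space$filter_counts), draw(space$filter_widths))
    })
    reg_kind <- draw(names(space$regularizers))
    reg_val <- draw(space$regularizers[[reg_kind]])
    ms <- model_spec(blocks = blocks,
                     l1_strength = if (reg_kind == "l1") reg_val else 0,
                     input_window = input_window)
    ts <- train_spec(initial_lr = draw(space$initial_lrs),
                     epochs = draw(space$epoch_counts),
                     batch_size = draw(space$batch_sizes))
    ts$optimizer <- draw(space$optimizers)
    list(model = ms, train = ts,
         regularizer = list(kind = reg_kind, value = reg_val))
  })
}
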