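test_that("default architecture matches the published layout", {
  spec <- model_spec()
  expect_identical(vapply(spec$blocks, `[[`, 0L, "n_filters"),
                   c(16L, 32L, 64L, 64L))
  expect_identical(vapply(spec$blocks, `[[`, 0L, "filter_width"),
                   c(11L, 11L, 21L, 41L))
  expect_identical(spec$dense_units, c(32L, 16L))
  expect_identical(spec$output_classes, 3L)
  expect_equal(spec$l1_strength, 7e-5)
  expect_identical(vapply(spec$blocks, `[[`, 0L, "pool_window"),
                   rep(2L, 4L))
})

test_that("parameter count equals an independent shape tally (window 261)", {
  m <- build_model(model_spec(input_window = window_spec(130L)), seed = 1L)
  # hand tally: lengths 261 -> 130 -> 65 -> 32 -> 16 under width-2 pools
  bn <- 2 * (4 + 16 + 32 + 64)                       # gamma+beta per channel
  conv <- (11 * 4 * 16 + 16) + (11 * 16 * 32 + 32) +
          (21 * 32 * 64 + 64) + (41 * 64 * 64 + 64)
  dense <- (64 * 32 + 32) + (32 * 16 + 16)           # position-wise
  out <- 16 * 16 * 3 + 3                             # flatten 16 pos x 16 ch
  expect_identical(count_params(m), as.integer(bn + conv + dense + out))
  expect_identical(m$dims$L_final, 16L)
})

test_that("softmax output rows sum to 1 for arbitrary inputs", {
  m <- build_model(tiny_model_spec(), seed = 4L)
  set.seed(4)
  X <- matrix(rnorm(8L * 13L * 4L), 8L * 13L, 4L)
  p <- splicecnn:::nn_forward(m, X, 8L, training = FALSE)$probs
  expect_equal(rowSums(p), rep(1, 8L), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("too-short windows are rejected naming the offending block", {
  spec <- model_spec(input_window = window_spec(3L))  # window 7
  expect_error(build_model(spec), "block 3")
})

test_that("learning-rate schedule steps exactly once, 0.001 -> 0.0005", {
  ts <- train_spec()
  expect_equal(learning_rate_at(ts, 3L), 0.001)
  expect_equal(learning_rate_at(ts, 6L), 0.001)
  expect_equal(learning_rate_at(ts, 8L), 0.0005)
  lrs <- learning_rate_at(ts, 1:10)
  expect_identical(sum(diff(lrs) != 0), 1L)
  # per-epoch halving variant
  ts2 <- train_spec(lr_halve_each_epoch = TRUE)
  expect_equal(learning_rate_at(ts2, 7:9), 0.001 / c(2, 4, 8))
})

test_that("backpropagation matches finite differences (all layer kinds)", {
  for (variant in list(list(flat = FALSE, bn_pre = TRUE),
                       list(flat = TRUE, bn_pre = TRUE),
                       list(flat = FALSE, bn_pre = FALSE))) {
    spec <- model_spec(blocks = list(cb_spec(3L, 3L), cb_spec(4L, 5L)),
                       dense_units = c(5L, 4L), l1_strength = 1e-4,
                       input_window = window_spec(6L),
                       flatten_first = variant$flat,
                       bn_before_activation = variant$bn_pre)
    m <- build_model(spec, seed = 2L)
    set.seed(31)
    # jitter away from ReLU/zero-bias boundaries where the subgradient and
    # a two-sided difference legitimately disagree
    m$params <- lapply(m$params, function(p) p + rnorm(length(p), 0, 0.05))
    B <- 4L; L <- 13L
    X <- matrix(rnorm(B * L * 4L), B * L, 4L)
    Y <- matrix(0, B, 3L); Y[cbind(seq_len(B), sample(3L, B, TRUE))] <- 1
    loss_fn <- function(mm) {
      fw <- splicecnn:::nn_forward(mm, X, B, training = TRUE)
      splicecnn:::nn_loss(mm, fw$probs, Y)
    }
    fw <- splicecnn:::nn_forward(m, X, B, training = TRUE)
    gr <- splicecnn:::nn_backward(m, fw$cache, fw$probs, Y)
    eps <- 1e-6
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      for (i in sample(length(p), min(4L, length(p)))) {
        m2 <- m; m2$params[[nm]][i] <- p[i] + eps
        m3 <- m; m3$params[[nm]][i] <- p[i] - eps
        num <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                     label = sprintf("grad %s[%d] (flat=%s bn_pre=%s)",
                                     nm, i, variant$flat, variant$bn_pre))
      }
    }
  }
})

test_that("training runs, records history, and is seed-reproducible", {
  gen <- unit_fixture()
  ds <- build_dataset(gen$genes, window_spec(6L), negatives_per_site = 1,
                      seed = 2L)
  ds <- split_dataset(ds, c(0.7, 0.15, 0.15), "window", seed = 2L)
  tspec <- train_spec(epochs = 1L, batch_size = 8L, repetitions = 1L,
                      seed = 99L)
  fit1 <- train(tiny_model_spec(), ds, tspec)
  expect_identical(nrow(fit1$history), 1L)
  expect_true(is.finite(fit1$history$train_loss))
  fit2 <- train(tiny_model_spec(), ds, tspec)
  expect_identical(fit1$model$params, fit2$model$params)
  # repetitions: averaged history plus one run per repetition
  tspec3 <- train_spec(epochs = 1L, batch_size = 8L, repetitions = 2L,
                       seed = 99L)
  fit3 <- train(tiny_model_spec(), ds, tspec3)
  expect_length(fit3$runs, 2L)
  expect_false(identical(fit3$runs[[1L]]$model$params,
                         fit3$runs[[2L]]$model$params))
  expect_equal(fit3$history$train_loss,
               mean(c(fit3$runs[[1L]]$history$train_loss,
                      fit3$runs[[2L]]$history$train_loss)))
})

test_that("train validates inputs", {
  gen <- unit_fixture()
  ds <- build_dataset(gen$genes, window_spec(6L), seed = 2L)
  expect_error(train(tiny_model_spec(), ds, train_spec()), "split_dataset")
  ds <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 1L)
  expect_error(train(model_spec(input_window = window_spec(10L)), ds),
               "window length")
  ts <- train_spec(); ts$optimizer <- "sgd"
  expect_error(train(tiny_model_spec(), ds, ts), "Adam")
})

test_that("model checkpoints round-trip with spec metadata", {
  m <- build_model(tiny_model_spec(), seed = 5L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$params, m$params)
  expect_identical(back$spec$l1_strength, m$spec$l1_strength)
})

test_that("search-space draws are members, deterministic, and cover widths", {
  sp <- search_space()
  draws1 <- sample_search_space(sp, 5L, seed = 8L)
  draws2 <- sample_search_space(sp, 5L, seed = 8L)
  expect_identical(draws1, draws2)
  draws <- sample_search_space(sp, 40L, seed = 9L)
  for (d in draws) {
    # brute-force containment of every sampled field in its enumeration
    expect_true(length(d$model$blocks) %in% sp$n_blocks)
    for (b in d$model$blocks) {
      expect_true(b$n_filters %in% sp$filter_counts)
      expect_true(b$filter_width %in% seq(5L, 65L, by = 2L))
    }
    expect_true(d$train$initial_lr %in% sp$initial_lrs)
    expect_true(d$train$batch_size %in% sp$batch_sizes)
    expect_true(d$train$epochs %in% sp$epoch_counts)
    expect_true(d$train$optimizer %in% sp$optimizers)
    expect_true(d$regularizer$value %in%
                  sp$regularizers[[d$regularizer$kind]])
  }
  # the published winning configuration is inside the space
  expect_true(all(c(16L, 32L, 64L) %in% sp$filter_counts))
  expect_true(all(c(11L, 21L, 41L) %in% sp$filter_widths))
  expect_true(7e-5 %in% sp$regularizers$l1)
  expect_true(0.001 %in% sp$initial_lrs)
})
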