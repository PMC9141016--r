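# Shared fixtures, built in code. The unit fixture is memoized per session.

unit_fixture <- local({
  cache <- NULL
  function(seed = 101L) {
    if (is.null(cache)) cache <<- make_fixture("unit", seed = seed)
    cache
  }
})

# deterministic stub "model": probabilities are a fixed smooth function of
# the window's one-hot content, so scan() can be tested without training.
stub_model <- function(X, B) {
  L <- nrow(X) / B
  xr <- matrix(0, B, 3L)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    s <- colSums(X[rows, , drop = FALSE])          # A, C, G, T counts
    z <- c(s[3L] - s[1L], s[4L] - s[2L], sum(s) / L) / 5
    e <- exp(z - max(z))
    xr[b, ] <- e / sum(e)
  }
  xr
}

# brute-force one-window encoder: pad with N, slice, encode (independent of
# extract_window's index arithmetic)
brute_window <- function(sequence, center0, flanking) {
  padded <- paste0(strrep("N", flanking), toupper(sequence),
                   strrep("N", flanking))
  sub <- substr(padded, center0 + 1L, center0 + 2L * flanking + 1L)
  encode_sequence(sub)
}

tiny_model_spec <- function(flanking = 6L) {
  model_spec(blocks = list(cb_spec(3L, 3L), cb_spec(4L, 5L)),
             dense_units = c(5L, 4L), l1_strength = 1e-4,
             input_window = window_spec(flanking))
}

random_track <- function(len, seed) {
  set.seed(seed)
  p <- matrix(stats::runif(len * 3L), len, 3L)
  p <- p / rowSums(p)
  splicecnn:::new_prediction_track("toy", p)
}
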