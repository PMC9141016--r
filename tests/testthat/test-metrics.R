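# independent brute-force oracles, deliberately naive
brute_roc_auc <- function(is_pos, score) {
  pos <- score[is_pos]; neg <- score[!is_pos]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

brute_rank <- function(track, site_type) {
  p <- track$probabilities[, site_type]
  order(-p, seq_along(p))
}

test_that("perfect predictions give perfect window-level metrics", {
  labels <- rep(c("donor", "acceptor", "other"), c(5L, 4L, 11L))
  probs <- splicecnn:::label_onehot(labels) * 0.98 + 0.02 / 3
  rep <- classification_report(labels, probs)
  expect_equal(rep$accuracy, 1)
  for (cl in c("donor", "acceptor", "other")) {
    pc <- rep$per_class[[cl]]
    expect_equal(pc$recall, 1)
    expect_equal(pc$precision, 1)
    expect_equal(pc$specificity, 1)
    expect_equal(pc$f1, 1)
  }
  expect_equal(rep$roc_auc, 1)
  expect_equal(rep$pr_auc, 1)
})

test_that("confusion matrix and per-class metrics match a hand count", {
  # 12 windows: donor truth 4 (3 right, 1 -> other); acceptor truth 3
  # (2 right, 1 -> donor); other truth 5 (4 right, 1 -> acceptor)
  truth <- c(rep("donor", 4L), rep("acceptor", 3L), rep("other", 5L))
  pred <- c("donor", "donor", "donor", "other",
            "acceptor", "acceptor", "donor",
            "other", "other", "other", "other", "acceptor")
  probs <- splicecnn:::label_onehot(pred) * 0.9 + 0.1 / 3
  rep <- classification_report(truth, probs)
  expect_equal(rep$accuracy, 9 / 12)
  expect_equal(unname(rep$confusion["donor", "donor"]), 3L)
  expect_equal(unname(rep$confusion["acceptor", "donor"]), 1L)
  expect_equal(unname(rep$confusion["other", "acceptor"]), 1L)
  # donor one-vs-rest: TP=3 FN=1 FP=1 TN=7
  expect_equal(rep$per_class$donor$recall, 3 / 4)
  expect_equal(rep$per_class$donor$precision, 3 / 4)
  expect_equal(rep$per_class$donor$specificity, 7 / 8)
  expect_equal(rep$per_class$donor$f1, 0.75)
  # row sums equal per-class support
  expect_equal(unname(rowSums(rep$confusion)), c(4L, 3L, 5L))
})

test_that("AUCs match brute-force pair counting; absent class is NA not 0", {
  set.seed(12)
  labels <- sample(c("donor", "acceptor", "other"), 60L, replace = TRUE)
  probs <- matrix(runif(180L), 60L, 3L); probs <- probs / rowSums(probs)
  colnames(probs) <- c("donor", "acceptor", "other")
  rep <- classification_report(labels, probs)
  for (cl in c("donor", "acceptor", "other")) {
    expect_equal(rep$per_class[[cl]]$roc_auc,
                 brute_roc_auc(labels == cl, probs[, cl]))
  }
  # macro ROC-AUC of a random classifier on balanced data ~ 0.5
  set.seed(13)
  labs <- rep(c("donor", "acceptor", "other"), each = 400L)
  p <- matrix(runif(3600L), 1200L, 3L); p <- p / rowSums(p)
  expect_lt(abs(classification_report(labs, p)$roc_auc - 0.5), 0.03)
  # class absent from truth
  rep2 <- classification_report(rep("other", 10L), p[1:10, ])
  expect_true(is.na(rep2$per_class$donor$roc_auc))
  expect_true(is.na(rep2$per_class$donor$pr_auc))
})

test_that("top-k accuracy: exact cases and brute-force re-ranking", {
  tr <- random_track(200L, seed = 21L)
  true_sites <- c(3L, 50L, 120L, 180L)
  rk <- brute_rank(tr, "donor")
  expect_equal(top_k_accuracy(tr, true_sites, "donor"),
               length(intersect(rk[1:4] - 1L, true_sites)) / 4)
  # all true sites ranked first -> 1
  p <- matrix(0.2, 20L, 3L); p[, 3L] <- 0.6
  p[c(2L, 5L), ] <- rep(c(0.9, 0.05, 0.05), each = 2L)
  tr2 <- splicecnn:::new_prediction_track("t", p)
  expect_equal(top_k_accuracy(tr2, c(1L, 4L), "donor"), 1)
  # 6 of 7 in top 7 -> 0.857..., printed 86%
  got <- 6 / 7
  expect_equal(round(100 * got), 86)
  expect_true(is.na(top_k_accuracy(tr, integer(), "donor")))
})

test_that("random-uniform top-k expectation matches the hypergeometric mean", {
  # k true sites among N positions, random ranking: E[hits]/k = k/N
  N <- 1000L; k <- 10L
  accs <- vapply(1:300, function(i) {
    tr <- random_track(N, seed = 3000L + i)
    top_k_accuracy(tr, seq(0L, by = 97L, length.out = k), "donor")
  }, numeric(1L))
  expect_lt(abs(mean(accs) - k / N), 0.01)
})

test_that("top-percent accuracy: bounds, monotonicity, brute force", {
  tr <- random_track(200L, seed = 33L)
  true_sites <- c(0L, 10L, 77L, 150L, 199L)
  expect_equal(top_percent_accuracy(tr, true_sites, "donor", 100), 1)
  pcts <- c(10, 25, 50, 65, 75, 85, 95)
  vals <- vapply(pcts, function(pc) {
    top_percent_accuracy(tr, true_sites, "donor", pc)
  }, numeric(1L))
  expect_true(all(diff(vals) >= 0))
  # brute force at 25%
  m <- floor(0.25 * 200)
  rk <- brute_rank(tr, "donor")[1:m] - 1L
  expect_equal(vals[2L], length(intersect(rk, true_sites)) / 5)
  expect_true(is.na(top_percent_accuracy(tr, integer(), "donor", 50)))
})

test_that("false-positive percentage reproduces published row arithmetic", {
  # 7 true donors all recovered, 43 donor calls on 31,816 nt -> 0.11%
  rec <- reconstruct_track(31816L, 7L, 7L, 43L, 6L, 7L, "donor")
  expect_equal(round(100 * false_positive_pct(rec$track, rec$true_sites,
                                              "donor"), 2), 0.11)
  expect_equal((43 - 7) / 31816, false_positive_pct(rec$track,
                                                    rec$true_sites, "donor"))
  # 26 true donors, 25 recovered, 86 calls on 94,761 nt -> 0.06%
  rec2 <- reconstruct_track(94761L, 26L, 25L, 86L, 19L, 23L, "donor")
  expect_equal(round(100 * false_positive_pct(rec2$track, rec2$true_sites,
                                              "donor"), 2), 0.06)
  expect_equal(site_level_accuracy(rec2$track, rec2$true_sites, "donor"),
               25 / 26)
  expect_equal(round(100 * 25 / 26, 2), 96.15)
  # zero calls -> 0
  p <- matrix(rep(c(0.1, 0.1, 0.8), 50L), ncol = 3L, byrow = TRUE)
  tr0 <- splicecnn:::new_prediction_track("z", p)
  expect_equal(false_positive_pct(tr0, c(3L, 7L), "donor"), 0)
  # bounded by P / length
  tr <- random_track(400L, seed = 44L)
  fp <- false_positive_pct(tr, c(1L, 2L), "donor")
  expect_lte(fp, sum(tr$called_class == "donor") / 400)
})

test_that("site-level accuracy equals brute-force membership counting", {
  tr <- random_track(300L, seed = 55L)
  ts <- c(5L, 9L, 100L, 250L, 299L)
  called <- which(tr$called_class == "donor") - 1L
  expect_equal(site_level_accuracy(tr, ts, "donor"),
               sum(ts %in% called) / length(ts))
  expect_true(is.na(site_level_accuracy(tr, integer(), "donor")))
})

test_that("evaluate_gene collates both site types consistently", {
  gen <- unit_fixture()
  g <- gen$genes[[1L]]
  tr <- scan(g, stub_model, window_spec(5L))
  rows <- evaluate_gene(tr, g$donor_sites, g$acceptor_sites)
  expect_identical(rows$site, c("donor", "acceptor"))
  expect_equal(rows$n_predicted[1L], nrow(call_sites(tr, "donor")))
  expect_equal(rows$fp[1L], false_positive_pct(tr, g$donor_sites, "donor"))
  expect_equal(rows$accuracy_pct, round(100 * rows$accuracy, 2))
})
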