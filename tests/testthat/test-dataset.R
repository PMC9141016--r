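test_that("build_dataset yields one window per site plus the negative quota", {
  g <- gene_record("g", strrep("ACGT", 50L),
                   donor_sites = c(20L, 60L), acceptor_sites = c(40L, 80L))
  ds <- build_dataset(list(g), window_spec(5L), negatives_per_site = 1.0,
                      seed = 3L)
  expect_identical(sum(ds$labels == "donor"), 2L)
  expect_identical(sum(ds$labels == "acceptor"), 2L)
  expect_identical(sum(ds$labels == "other"), 4L)
  expect_equal(unname(ds$y[ds$labels == "donor", ][1L, ]), c(1, 0, 0))
  expect_equal(unname(ds$y[ds$labels == "acceptor", ][1L, ]), c(0, 1, 0))
  expect_equal(unname(ds$y[ds$labels == "other", ][1L, ]), c(0, 0, 1))
})

test_that("negative centers never hit annotated sites (brute force, seed 7)", {
  gen <- unit_fixture()
  ds <- build_dataset(gen$genes, window_spec(10L), seed = 7L)
  for (g in gen$genes) {
    neg <- ds$center[ds$labels == "other" & ds$gene_id == g$id]
    sites <- c(g$donor_sites, g$acceptor_sites)
    expect_length(intersect(neg, sites), 0L)
    expect_true(all(neg >= 0L & neg < nchar(g$sequence)))
  }
  # class-count property: other = round(ratio * positives)
  n_pos <- sum(ds$labels != "other")
  expect_identical(sum(ds$labels == "other"), as.integer(round(1.571 * n_pos)))
})

test_that("exclusion radius keeps negatives away from sites", {
  gen <- unit_fixture()
  ds <- build_dataset(gen$genes, window_spec(10L), seed = 7L,
                      exclusion_radius = 5L)
  for (g in gen$genes) {
    neg <- ds$center[ds$labels == "other" & ds$gene_id == g$id]
    for (s in c(g$donor_sites, g$acceptor_sites)) {
      expect_true(all(abs(neg - s) > 5L))
    }
  }
})

test_that("datasets are deterministic given the seed", {
  gen <- unit_fixture()
  d1 <- build_dataset(gen$genes, window_spec(8L), seed = 42L)
  d2 <- build_dataset(gen$genes, window_spec(8L), seed = 42L)
  expect_identical(d1, d2)
  d3 <- build_dataset(gen$genes, window_spec(8L), seed = 43L)
  expect_false(identical(d1$center, d3$center))
})

test_that("genes shorter than the window build via zero-padding, no error", {
  g <- gene_record("short", strrep("ACGTGTAG", 6L),   # 48 nt
                   donor_sites = 10L, acceptor_sites = 30L)
  ds <- build_dataset(list(g), window_spec(100L), negatives_per_site = 1,
                      seed = 1L)                       # window 201 > gene
  expect_identical(length(ds$labels), 4L)
  expect_identical(ncol(ds$x), 201L * 4L)
  # rows beyond the sequence are zero
  w <- extract_window(g, 0L, window_spec(100L))
  expect_true(all(w$matrix[1:100, ] == 0))
})

test_that("site-free genes are skipped; infeasible negatives error", {
  g1 <- gene_record("with", strrep("ACGT", 30L), donor_sites = 10L)
  g0 <- gene_record("without", strrep("ACGT", 30L))
  expect_message(ds <- build_dataset(list(g1, g0), window_spec(3L), seed = 1L),
                 "skipping 1")
  expect_true(all(ds$gene_id == "with"))
  expect_error(build_dataset(list(g1), window_spec(3L),
                             negatives_per_site = 1000, seed = 1L),
               "available")
})

test_that("window-mode split hits the 80/10/10 sizes", {
  gen <- unit_fixture()
  ds <- build_dataset(gen$genes, window_spec(5L), negatives_per_site = 4,
                      seed = 5L)
  n <- length(ds$labels)
  ds <- split_dataset(ds, c(0.8, 0.1, 0.1), "window", seed = 2L)
  sizes <- table(ds$split)
  expect_identical(as.integer(sizes[["train"]]), as.integer(round(0.8 * n)))
  expect_identical(as.integer(sizes[["validation"]]), as.integer(round(0.1 * n)))
  expect_identical(sum(sizes), n)
  expect_error(split_dataset(ds, c(0.8, 0.1, 0.2)), "sum to 1")
})

test_that("published-scale split arithmetic: 812,188 windows -> 81,219 test", {
  sizes <- splicecnn:::split_sizes(812188L, c(0.8, 0.1, 0.1))
  expect_equal(unname(sizes["test"]), 81219)
  expect_equal(unname(sizes["train"] + sizes["validation"] + sizes["test"]),
               812188)
})

test_that("gene-mode split never leaks a gene across splits (property)", {
  gen <- unit_fixture()
  ds <- build_dataset(gen$genes, window_spec(5L), negatives_per_site = 2,
                      seed = 5L)
  for (seed in 1:5) {
    dss <- split_dataset(ds, c(0.6, 0.2, 0.2), "gene", seed = seed)
    tab <- table(dss$gene_id, dss$split)
    expect_true(all(rowSums(tab > 0L) == 1L))
  }
})

test_that("dataset serialization round-trips", {
  gen <- unit_fixture()
  ds <- build_dataset(gen$genes, window_spec(5L), seed = 9L)
  ds <- split_dataset(ds, c(0.8, 0.1, 0.1), "window", seed = 9L)
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  back <- read_dataset(d)
  expect_equal(back$x, ds$x)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$split, ds$split)
  expect_identical(back$spec$flanking_length, ds$spec$flanking_length)
})
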