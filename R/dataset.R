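LABELS <- c("donor", "acceptor", "other")

# donor -> (1,0,0), acceptor -> (0,1,0), other -> (0,0,1)
label_onehot <- function(labels) {
  idx <- match(labels, LABELS)
  stopifnot(!anyNA(idx))
  m <- matrix(0, nrow = length(labels), ncol = 3L,
              dimnames = list(NULL, LABELS))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# split sizes under (train, validation, test) fractions: train and validation
# rounded to nearest, test takes the remainder.
split_sizes <- function(n, fractions) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("split fractions must sum to 1")
  n_train <- round(fractions[1L] * n)
  n_val <- round(fractions[2L] * n)
  c(train = n_train, validation = n_val, test = n - n_train - n_val)
}

#' Build the three-class labeled window dataset
#'
#' One window per annotated donor and acceptor site, plus
#' `round(negatives_per_site * total_sites)` "other" windows whose centers
#' are drawn uniformly at random, without replacement, from non-site
#' positions (optionally excluding positions within `exclusion_radius` of a
#' site). Genes without any annotated site are skipped with a message.
#' Deterministic given `seed`.
#'
#' The default `negatives_per_site = 1.571` mirrors the published
#' generic-to-positive ratio of roughly 496k generic to 316k site windows.
#'
#' @param genes List of [gene_record].
#' @param spec A [window_spec]. Genes shorter than the window are still used;
#'   windows are zero-padded.
#' @param negatives_per_site Positive ratio of "other" windows to total site
#'   windows.
#' @param seed Integer seed.
#' @param exclusion_radius Non-negative integer; negative centers must be
#'   farther than this from any annotated site (default 0: only the site
#'   positions themselves are excluded).
#' @return An object of class `labeled_dataset`: list with `x` (N x
#'   (window_length * 4) encoded windows, layout of one window per row),
#'   `labels`, `y` (N x 3 one-hot), `gene_id`, `center`, `spec`, `seed`,
#'   and `split` (NA until [split_dataset] is called).
#' @export
build_dataset <- function(genes, spec, negatives_per_site = 1.571,
                          seed = 1L, exclusion_radius = 0L) {
  stopifnot(inherits(spec, "window_spec"), negatives_per_site > 0)
  has_sites <- vapply(genes, function(g) {
    length(g$donor_sites) + length(g$acceptor_sites) > 0L
  }, logical(1L))
  if (any(!has_sites)) {
    message("build_dataset: skipping ", sum(!has_sites),
            " gene(s) with no annotated sites")
  }
  genes <- genes[has_sites]
  if (!length(genes)) stop("build_dataset: no genes with annotated sites")

  total_sites <- sum(vapply(genes, function(g) {
    length(g$donor_sites) + length(g$acceptor_sites)
  }, 0L))
  n_neg_total <- round(negatives_per_site * total_sites)

  set.seed(seed)
  # apportion negatives across genes proportionally to available positions
  avail <- vapply(genes, function(g) {
    n <- nchar(g$sequence)
    excl <- excluded_positions(g, exclusion_radius)
    n - length(excl)
  }, 0L)
  if (n_neg_total > sum(avail)) {
    stop("build_dataset: requested ", n_neg_total,
         " negatives but only ", sum(avail), " non-site positions available")
  }
  n_neg <- floor(n_neg_total * avail / sum(avail))
  # distribute the rounding remainder to the genes with most headroom
  rem <- n_neg_total - sum(n_neg)
  if (rem > 0L) {
    ord <- order(avail - n_neg, decreasing = TRUE)
    bump <- ord[seq_len(rem)]
    n_neg[bump] <- n_neg[bump] + 1L
  }

  pieces <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    pos_centers <- c(g$donor_sites, g$acceptor_sites)
    labels <- rep(c("donor", "acceptor"),
                  c(length(g$donor_sites), length(g$acceptor_sites)))
    excl <- excluded_positions(g, exclusion_radius)
    candidates <- setdiff(0:(nchar(g$sequence) - 1L), excl)
    neg_centers <- if (n_neg[i] > 0L) {
      sort(sample(candidates, n_neg[i], replace = FALSE))
    } else integer()
    centers <- c(pos_centers, neg_centers)
    pieces[[i]] <- list(
      x = encode_window_rows(g, centers, spec),
      labels = c(labels, rep("other", length(neg_centers))),
      gene_id = rep(g$id, length(centers)),
      center = centers)
  }
  x <- do.call(rbind, lapply(pieces, `[[`, "x"))
  labels <- unlist(lapply(pieces, `[[`, "labels"))
  ds <- structure(list(
    x = x,
    labels = labels,
    y = label_onehot(labels),
    gene_id = unlist(lapply(pieces, `[[`, "gene_id")),
    center = unlist(lapply(pieces, `[[`, "center")),
    spec = spec,
    seed = as.integer(seed),
    negatives_per_site = negatives_per_site,
    split = rep(NA_character_, length(labels))),
    class = "labeled_dataset")
  ds
}

excluded_positions <- function(g, radius) {
  sites <- c(g$donor_sites, g$acceptor_sites)
  if (radius <= 0L) return(sites)
  n <- nchar(g$sequence)
  unique(unlist(lapply(sites, function(s) {
    max(0L, s - radius):min(n - 1L, s + radius)
  })))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = LABELS))
  cat(sprintf("<labeled_dataset> %d windows (flanking %d): %s\n",
              length(x$labels), x$spec$flanking_length,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  if (!all(is.na(x$split))) {
    st <- table(x$split)
    cat("  split: ", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assign train / validation / test splits
#'
#' `stratify_by = "window"` shuffles windows independently (the published
#' protocol pools all windows before splitting). `stratify_by = "gene"`
#' keeps every window of a gene in one split, which avoids leakage of
#' near-duplicate overlapping windows across splits; genes are assigned
#' greedily, in shuffled order, to the split with the largest remaining
#' deficit. Deterministic given `seed`.
#'
#' @param ds A `labeled_dataset`.
#' @param fractions Numeric length-3 (train, validation, test), summing to 1.
#' @param stratify_by "window" or "gene".
#' @param seed Integer seed.
#' @return The dataset with its `split` field populated.
#' @export
split_dataset <- function(ds, fractions = c(0.8, 0.1, 0.1),
                          stratify_by = c("window", "gene"), seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"), length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-9) stop("split fractions must sum to 1")
  stratify_by <- match.arg(stratify_by)
  n <- length(ds$labels)
  set.seed(seed)
  if (stratify_by == "window") {
    sizes <- split_sizes(n, fractions)
    perm <- sample.int(n)
    ds$split <- rep(NA_character_, n)
    ds$split[perm] <- rep(c("train", "validation", "test"), sizes)
  } else {
    gene_ids <- unique(ds$gene_id)
    gene_ids <- sample(gene_ids)
    counts <- table(ds$gene_id)[gene_ids]
    target <- fractions * n
    got <- c(train = 0, validation = 0, test = 0)
    gene_split <- character(length(gene_ids))
    names(gene_split) <- gene_ids
    for (g in gene_ids) {
      deficit <- target - got
      pick <- names(which.max(deficit))
      gene_split[g] <- pick
      got[pick] <- got[pick] + counts[[g]]
    }
    ds$split <- unname(gene_split[ds$gene_id])
  }
  ds$split_fractions <- fractions
  ds$split_seed <- as.integer(seed)
  ds$stratify_by <- stratify_by
  ds
}

subset_dataset <- function(ds, which_split) {
  keep <- ds$split == which_split
  list(x = ds$x[keep, , drop = FALSE],
       y = ds$y[keep, , drop = FALSE],
       labels = ds$labels[keep],
       gene_id = ds$gene_id[keep],
       center = ds$center[keep])
}

#' Serialize / restore a labeled dataset
#'
#' The window array is written as an RDS file alongside a JSON manifest
#' (ids, centers, labels, split, seed, window spec) for provenance.
#'
#' @param ds A `labeled_dataset`.
#' @param dir Output directory.
#' @return `write_dataset`: invisibly, the directory. `read_dataset`: the
#'   restored dataset.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(ds$x, file.path(dir, "windows.rds"), compress = "xz")
  manifest <- list(
    n_windows = length(ds$labels),
    flanking_length = ds$spec$flanking_length,
    seed = ds$seed,
    negatives_per_site = ds$negatives_per_site,
    gene_id = ds$gene_id, center = ds$center,
    labels = ds$labels, split = ds$split)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  x <- readRDS(file.path(dir, "windows.rds"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  labels <- man$labels
  structure(list(
    x = x, labels = labels, y = label_onehot(labels),
    gene_id = man$gene_id, center = as.integer(man$center),
    spec = window_spec(man$flanking_length),
    seed = as.integer(man$seed),
    negatives_per_site = man$negatives_per_site,
    split = if (is.null(man$split)) rep(NA_character_, length(labels))
            else man$split),
    class = "labeled_dataset")
}
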