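#' Gene record: a sequence with annotated splice sites
#'
#' Bundles one gene-scale DNA sequence with its annotated donor and acceptor
#' splice-site positions. Positions are 0-based indices into `sequence`.
#' By the canonical dinucleotide convention a donor site is the first intron
#' base (the G of GT) and an acceptor site is the last intron base (the G of
#' AG); readers of annotation formats apply a configurable offset if another
#' convention is wanted.
#'
#' @param id Character scalar, the gene identifier.
#' @param sequence DNA string over A/C/G/T/N (lower case accepted, upper-cased
#'   on ingest).
#' @param donor_sites Integer vector of 0-based donor positions.
#' @param acceptor_sites Integer vector of 0-based acceptor positions.
#' @param source Free-text provenance string.
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(id, sequence, donor_sites = integer(),
                        acceptor_sites = integer(), source = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("gene_record: sequence for '", id, "' is empty")
  donor_sites <- as.integer(sort(unique(donor_sites)))
  acceptor_sites <- as.integer(sort(unique(acceptor_sites)))
  bad <- c(donor_sites, acceptor_sites)
  bad <- bad[bad < 0L | bad >= n]
  if (length(bad)) {
    stop("gene_record: site position(s) ", paste(bad, collapse = ", "),
         " outside [0, ", n, ") for gene '", id, "'")
  }
  if (length(intersect(donor_sites, acceptor_sites))) {
    stop("gene_record: donor and acceptor sites overlap for gene '", id, "'")
  }
  structure(list(id = id, sequence = sequence,
                 donor_sites = donor_sites,
                 acceptor_sites = acceptor_sites,
                 source = source),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s: %d nt, %d donor / %d acceptor sites\n",
              x$id, nchar(x$sequence),
              length(x$donor_sites), length(x$acceptor_sites)))
  invisible(x)
}

#' Window specification
#'
#' Fixes the flanking length f: a window is the center nucleotide plus f
#' neighbors on each side, 2f + 1 nucleotides in total. The published
#' flanking lengths are 130, 200, 500 and 1000 (window lengths 261, 401,
#' 1001, 2001); 130 is the smallest input the default architecture was
#' designed around. Smaller values are accepted so that toy examples and
#' unit tests remain cheap -- the model constructor independently verifies
#' that a window survives its pooling stack.
#'
#' @param flanking_length Positive integer, neighbors per side.
#' @return An object of class `window_spec` with fields `flanking_length`
#'   and `window_length`.
#' @export
window_spec <- function(flanking_length = 200L) {
  flanking_length <- as.integer(flanking_length)
  stopifnot(length(flanking_length) == 1L, flanking_length >= 1L)
  structure(list(flanking_length = flanking_length,
                 window_length = 2L * flanking_length + 1L),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> flanking %d, window length %d\n",
              x$flanking_length, x$window_length))
  invisible(x)
}

# fixed column order of the one-hot alphabet
DNA_BASES <- c("A", "C", "G", "T")

#' One-hot encode a single base
#'
#' A, C, G, T map to the four unit vectors in that column order; every other
#' character (N, IUPAC ambiguity codes, gaps, the out-of-bounds sentinel)
#' maps to the zero vector. Total function: never errors.
#'
#' @param base Single character.
#' @return Numeric 4-vector.
#' @export
encode_base <- function(base) {
  v <- numeric(4L)
  i <- match(toupper(base), DNA_BASES)
  if (!is.na(i)) v[i] <- 1
  v
}

#' One-hot encode a DNA string
#'
#' @param seq Character scalar.
#' @return Numeric matrix, nchar(seq) x 4; rows of unknown bases are zero.
#' @export
encode_sequence <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  idx <- match(chars, DNA_BASES)
  m <- matrix(0, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, DNA_BASES))
  keep <- which(!is.na(idx))
  m[cbind(keep, idx[keep])] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' Zero rows decode to "N".
#'
#' @param mat Numeric matrix with 4 columns.
#' @return Character scalar.
#' @export
decode_onehot <- function(mat) {
  stopifnot(ncol(mat) == 4L)
  hit <- max.col(mat, ties.method = "first")
  hit[rowSums(mat) == 0] <- NA_integer_
  out <- DNA_BASES[hit]
  out[is.na(out)] <- "N"
  paste0(out, collapse = "")
}

window_label <- function(gene, center) {
  if (center %in% gene$donor_sites) "donor"
  else if (center %in% gene$acceptor_sites) "acceptor"
  else "other"
}

#' Extract and encode the window centered on a position
#'
#' Row i (1-based) of the returned matrix encodes sequence position
#' center - flanking_length + (i - 1); positions outside the sequence
#' contribute zero rows, so windows at the sequence edges are zero-padded
#' rather than truncated.
#'
#' @param gene A `gene_record`.
#' @param center 0-based position in the gene sequence.
#' @param spec A `window_spec`.
#' @return An object of class `encoded_window`: list with `matrix`
#'   (window_length x 4), `center_position`, and `label` in
#'   donor/acceptor/other.
#' @export
extract_window <- function(gene, center, spec) {
  stopifnot(inherits(gene, "gene_record"), inherits(spec, "window_spec"))
  center <- as.integer(center)
  n <- nchar(gene$sequence)
  if (center < 0L || center >= n) {
    stop("extract_window: center ", center, " outside [0, ", n,
         ") for gene '", gene$id, "'")
  }
  f <- spec$flanking_length
  lo <- center - f          # 0-based, may be negative
  hi <- center + f          # may exceed n - 1
  m <- matrix(0, nrow = spec$window_length, ncol = 4L,
              dimnames = list(NULL, DNA_BASES))
  in_lo <- max(lo, 0L)
  in_hi <- min(hi, n - 1L)
  if (in_lo <= in_hi) {
    sub <- substr(gene$sequence, in_lo + 1L, in_hi + 1L)
    m[(in_lo - lo + 1L):(in_hi - lo + 1L), ] <- encode_sequence(sub)
  }
  structure(list(matrix = m, center_position = center,
                 label = window_label(gene, center)),
            class = "encoded_window")
}

# Encode many windows of one gene into the flat row layout used by the
# network: one row per window, the window_length x 4 one-hot matrix stored
# column-major (positions fastest within each base channel). Much faster
# than repeated extract_window() because the padded sequence is encoded once
# and windows are gathered by index.
encode_window_rows <- function(gene, centers, spec) {
  f <- spec$flanking_length
  L <- spec$window_length
  n <- nchar(gene$sequence)
  padded <- rbind(matrix(0, f, 4L), encode_sequence(gene$sequence),
                  matrix(0, f, 4L))
  # window for center p covers padded rows (p+1) .. (p+L) (1-based)
  idx <- outer(seq_len(L), as.integer(centers), `+`)  # L x B
  B <- length(centers)
  gathered <- padded[as.vector(idx), , drop = FALSE]  # (L*B) x 4, b-major? no:
  # as.vector(idx) runs l fastest within each center, so rows are
  # (center-major, position-fastest) blocks -- exactly one window per block.
  arr <- array(gathered, dim = c(L, B, 4L))
  # per-window flat vector: positions fastest, then channels
  matrix(aperm(arr, c(1L, 3L, 2L)), nrow = B, ncol = L * 4L, byrow = TRUE)
}

# Convert flat window rows (B x (L*4), layout of encode_window_rows) into the
# (B*L) x 4 stacked form consumed by the network layers, rows ordered
# (window-major, position-fastest).
rows_to_stack <- function(xrows, L) {
  B <- nrow(xrows)
  arr <- array(t(xrows), dim = c(L, 4L, B))
  matrix(aperm(arr, c(1L, 3L, 2L)), nrow = B * L, ncol = 4L)
}
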