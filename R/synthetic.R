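#' Configuration for the synthetic gene generator
#'
#' Describes a population of single-gene sequences built as alternating
#' exon/intron segments over an i.i.d. background with GC fraction
#' `background_gc`. Each intron boundary carries a position-weight-matrix
#' (PWM) sampled context centered on the canonical dinucleotides: GT starting
#' the intron (donor) and AG ending it (acceptor). The context spans
#' `context_width` bases per side of the dinucleotide anchor.
#'
#' `motif_information_content` (ic, in [0, 1]) interpolates the PWM between
#' pure background (ic = 0: planted "sites" are statistically invisible,
#' including the GT/AG core) and a sharp consensus (ic = 1: core dinucleotide
#' probability 1, context consensus probability 0.9). Only at ic = 1 is the
#' invariant "every donor reads GT, every acceptor reads AG" guaranteed.
#' Decoy GT/AG dinucleotides arise naturally from the background and are not
#' suppressed; their expected per-position rate is reported in the result as
#' `decoy_dinucleotide_rate`.
#'
#' @param n_genes Number of genes.
#' @param gene_length_range Length-2 integer vector; genes whose sampled
#'   segment lengths fall outside are resampled.
#' @param exons_per_gene_range Length-2 integer vector, at least c(1, 1).
#' @param exon_length_range,intron_length_range Segment length ranges;
#'   introns must be at least 2 * context_width + 2 so donor and acceptor
#'   contexts never overlap.
#' @param context_width PWM context width per side of the core dinucleotide
#'   (default 6).
#' @param motif_information_content Signal-strength dial in [0, 1], default 1.
#' @param background_gc Background GC fraction, default 0.42 (human-like).
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_genome_config`.
#' @export
synthetic_genome_config <- function(n_genes = 5L,
                                    gene_length_range = c(500L, 2000L),
                                    exons_per_gene_range = c(2L, 5L),
                                    exon_length_range = c(60L, 200L),
                                    intron_length_range = c(60L, 400L),
                                    context_width = 6L,
                                    motif_information_content = 1,
                                    background_gc = 0.42,
                                    seed = 1L) {
  stopifnot(n_genes >= 1L,
            length(gene_length_range) == 2L,
            gene_length_range[1L] <= gene_length_range[2L],
            exons_per_gene_range[1L] >= 1L,
            exons_per_gene_range[1L] <= exons_per_gene_range[2L],
            context_width >= 1L,
            motif_information_content >= 0, motif_information_content <= 1,
            background_gc > 0, background_gc < 1)
  if (intron_length_range[1L] < 2L * context_width + 2L) {
    stop("intron_length_range minimum must be >= 2 * context_width + 2")
  }
  if (exon_length_range[1L] < context_width) {
    stop("exon_length_range minimum must be >= context_width")
  }
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 exons_per_gene_range = as.integer(exons_per_gene_range),
                 exon_length_range = as.integer(exon_length_range),
                 intron_length_range = as.integer(intron_length_range),
                 context_width = as.integer(context_width),
                 motif_information_content = motif_information_content,
                 background_gc = background_gc,
                 seed = as.integer(seed)),
            class = "synthetic_genome_config")
}

background_probs <- function(gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  p
}

# Consensus context strings; the core dinucleotide sits at positions
# context_width + 1 and context_width + 2 of the donor consensus, and at
# context_width + (-1, 0) from the right for the acceptor. Loosely modeled
# on eukaryotic boundary consensus (exonic CAG | GTAAGT donor; pyrimidine
# tract TTTTCAG | G acceptor), truncated/recycled to the requested width.
donor_consensus <- function(w) {
  exonic <- rev(rep_len(rev(strsplit("AACAG", "")[[1L]]), w))
  intronic <- rep_len(strsplit("AAGTAT", "")[[1L]], w)
  c(exonic, "G", "T", intronic)
}

acceptor_consensus <- function(w) {
  intronic <- rev(rep_len(rev(strsplit("TTTTTCTTTCA", "")[[1L]]), w))
  exonic <- rep_len(strsplit("GTTGGA", "")[[1L]], w)
  c(intronic, "A", "G", exonic)
}

#' Position-weight matrix for a planted splice signal
#'
#' Column j is the base distribution at context position j. At information
#' content ic the consensus base has probability
#' `bg + ic * (target - bg)` where target is 1 for the two core positions and
#' 0.9 elsewhere; the remainder is spread over the other bases in proportion
#' to the background.
#'
#' @param site_type "donor" or "acceptor".
#' @param config A `synthetic_genome_config`.
#' @return 4 x (2 * context_width + 2) matrix, rows A/C/G/T, columns summing
#'   to 1.
#' @export
splice_pwm <- function(site_type = c("donor", "acceptor"), config) {
  site_type <- match.arg(site_type)
  w <- config$context_width
  cons <- if (site_type == "donor") donor_consensus(w) else acceptor_consensus(w)
  bg <- background_probs(config$background_gc)
  ic <- config$motif_information_content
  core <- w + c(1L, 2L)
  pwm <- vapply(seq_along(cons), function(j) {
    target <- if (j %in% core) 1 else 0.9
    b <- cons[j]
    p_cons <- bg[b] + ic * (target - bg[b])
    rest <- bg[setdiff(DNA_BASES, b)]
    p <- numeric(4L); names(p) <- DNA_BASES
    p[b] <- p_cons
    p[setdiff(DNA_BASES, b)] <- rest / sum(rest) * (1 - p_cons)
    p
  }, numeric(4L))
  rownames(pwm) <- DNA_BASES
  pwm
}

# uniform integer draw on [lo, hi], immune to sample()'s scalar expansion
sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

sample_pwm <- function(pwm, n = 1L) {
  # one sampled string per call column-wise
  vapply(seq_len(n), function(i) {
    paste0(apply(pwm, 2L, function(p) sample(DNA_BASES, 1L, prob = p)),
           collapse = "")
  }, character(1L))
}

#' Generate annotated synthetic genes
#'
#' Deterministic given `config$seed`. Each gene alternates exon and intron
#' segments (always starting and ending with an exon); every intron boundary
#' is overwritten with a PWM-sampled context so that, at full information
#' content, the intron starts with GT and ends with AG. Donor positions are
#' the first intron bases, acceptor positions the last.
#'
#' @param config A [synthetic_genome_config].
#' @return List with `genes` (list of [gene_record]), `structures` (per-gene
#'   data.frame of exon/intron segments), and `decoy_dinucleotide_rate`
#'   (expected background per-position rate of GT, equal to that of AG only
#'   when P(A)=P(T)).
#' @export
generate_synthetic_genes <- function(config) {
  stopifnot(inherits(config, "synthetic_genome_config"))
  set.seed(config$seed)
  bg <- background_probs(config$background_gc)
  pwm_d <- splice_pwm("donor", config)
  pwm_a <- splice_pwm("acceptor", config)
  w <- config$context_width

  genes <- vector("list", config$n_genes)
  structures <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    for (attempt in seq_len(1000L)) {
      n_ex <- sample_range(config$exons_per_gene_range[1L],
                           config$exons_per_gene_range[2L])
      ex_len <- sample_range(config$exon_length_range[1L],
                             config$exon_length_range[2L], n_ex)
      in_len <- if (n_ex > 1L) {
        sample_range(config$intron_length_range[1L],
                     config$intron_length_range[2L], n_ex - 1L)
      } else integer()
      total <- sum(ex_len) + sum(in_len)
      if (total >= config$gene_length_range[1L] &&
          total <= config$gene_length_range[2L]) break
      if (attempt == 1000L) {
        stop("generate_synthetic_genes: cannot fit ", n_ex,
             " exons into gene_length_range; geometry infeasible")
      }
    }
    seq_chars <- sample(DNA_BASES, total, replace = TRUE, prob = bg)
    # segment bookkeeping (0-based starts)
    kinds <- if (n_ex > 1L) {
      as.vector(rbind(rep("exon", n_ex), c(rep("intron", n_ex - 1L), NA)))
    } else "exon"
    kinds <- kinds[!is.na(kinds)]
    lens <- integer(length(kinds))
    lens[kinds == "exon"] <- ex_len
    lens[kinds == "intron"] <- in_len
    starts0 <- cumsum(c(0L, lens[-length(lens)]))
    donors <- integer(); acceptors <- integer()
    for (k in which(kinds == "intron")) {
      d <- starts0[k]                 # first intron base
      a <- starts0[k] + lens[k] - 1L  # last intron base
      donors <- c(donors, d)
      acceptors <- c(acceptors, a)
      dctx <- strsplit(sample_pwm(pwm_d), "")[[1L]]
      seq_chars[(d - w):(d + w + 1L) + 1L] <- dctx
      actx <- strsplit(sample_pwm(pwm_a), "")[[1L]]
      seq_chars[(a - w - 1L):(a + w) + 1L] <- actx
    }
    id <- sprintf("synthgene%03d", g)
    genes[[g]] <- gene_record(id, paste0(seq_chars, collapse = ""),
                              donor_sites = donors, acceptor_sites = acceptors,
                              source = "synthetic")
    structures[[g]] <- data.frame(gene_id = id, kind = kinds,
                                  start = starts0, length = lens,
                                  stringsAsFactors = FALSE)
  }
  list(genes = genes,
       structures = do.call(rbind, structures),
       decoy_dinucleotide_rate = unname(bg["G"] * bg["T"]))
}

#' Write a synthetic gene set to disk
#'
#' Emits FASTA, the tab-separated site table, and a truth GFF3 containing
#' exon and intron features (so the `gff3` dialect of [read_genes] can
#' re-derive the sites).
#'
#' @param gen Result of [generate_synthetic_genes].
#' @param dir Output directory, created if missing.
#' @return Named character vector of the three paths.
#' @export
write_synthetic_genes <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genes.fa")
  site_table <- file.path(dir, "sites.tsv")
  gff3 <- file.path(dir, "truth.gff3")
  write_genes(gen$genes, fasta, site_table, gff3_path = NULL)
  st <- gen$structures
  gr <- GenomicRanges::GRanges(
    seqnames = st$gene_id,
    ranges = IRanges::IRanges(start = st$start + 1L, width = st$length))
  gr$type <- st$kind
  gr$source <- "splicecnn"
  rtracklayer::export(gr, gff3, format = "gff3")
  c(fasta = fasta, site_table = site_table, gff3 = gff3)
}

#' Build a ready-made synthetic fixture
#'
#' `unit` is a 5-gene, <= 2 kb-per-gene set for fast tests. `training` is
#' sized so that, at flanking length 130 and the default negative ratio,
#' [build_dataset] yields at least ~20,000 windows (roughly 3,900 introns
#' across ~500 genes).
#'
#' @param scale "unit" or "training".
#' @param seed Integer seed.
#' @param motif_information_content Signal dial passed through, default 1.
#' @return As [generate_synthetic_genes].
#' @export
make_fixture <- function(scale = c("unit", "training"), seed = 1L,
                         motif_information_content = 1) {
  scale <- match.arg(scale)
  config <- switch(scale,
    unit = synthetic_genome_config(
      n_genes = 5L, gene_length_range = c(400L, 2000L),
      exons_per_gene_range = c(2L, 4L), seed = seed,
      motif_information_content = motif_information_content),
    training = synthetic_genome_config(
      n_genes = 500L, gene_length_range = c(1000L, 4000L),
      exons_per_gene_range = c(7L, 10L),
      exon_length_range = c(60L, 180L),
      intron_length_range = c(60L, 300L), seed = seed,
      motif_information_content = motif_information_content))
  generate_synthetic_genes(config)
}
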