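#' Read annotated genes from FASTA plus an annotation file
#'
#' Sequences come from a FASTA file (one gene per entry; the word before the
#' first whitespace in the header is the gene id). Splice-site annotations
#' come from one of three dialects:
#'
#' * `site_table`: tab-separated columns
#'   `gene_id, site_type, position, coordinate_base` where `site_type` is
#'   `donor` or `acceptor` and `coordinate_base` is 0 or 1. Positions are
#'   converted to the 0-based internal convention.
#' * `gff3` / `gtf`: splice sites are derived from `intron` features when
#'   present, otherwise from the gaps between consecutive `exon` features of
#'   the same parent/transcript. Coordinates are 1-based inclusive and
#'   relative to the FASTA entry named by the seqid column. The donor site is
#'   the first intron base and the acceptor the last intron base; `donor_offset`
#'   and `acceptor_offset` shift these if another convention is wanted.
#'
#' Annotations whose gene id matches no FASTA entry are reported with a
#' warning, never silently dropped.
#'
#' @param fasta_source Path to a FASTA file.
#' @param annotation_source Path to the annotation file.
#' @param dialect One of "site_table", "gff3", "gtf".
#' @param donor_offset,acceptor_offset Integers added to the derived donor /
#'   acceptor positions (default 0).
#' @return List of [gene_record] objects, one per FASTA entry, in file order.
#' @export
read_genes <- function(fasta_source, annotation_source,
                       dialect = c("site_table", "gff3", "gtf"),
                       donor_offset = 0L, acceptor_offset = 0L) {
  dialect <- match.arg(dialect)
  if (!file.exists(fasta_source)) stop("FASTA not found: ", fasta_source)
  if (!file.exists(annotation_source)) {
    stop("annotation file not found: ", annotation_source)
  }
  seqs <- Biostrings::readDNAStringSet(fasta_source)
  ids <- sub("\\s.*$", "", names(seqs))
  sites <- switch(dialect,
    site_table = read_site_table(annotation_source),
    gff3 = sites_from_gff(annotation_source, "gff3",
                          donor_offset, acceptor_offset),
    gtf = sites_from_gff(annotation_source, "gtf",
                         donor_offset, acceptor_offset))
  orphan <- setdiff(unique(sites$gene_id), ids)
  if (length(orphan)) {
    warning("annotations for ", length(orphan),
            " id(s) with no matching FASTA entry: ",
            paste(orphan, collapse = ", "))
  }
  lapply(seq_along(seqs), function(i) {
    s <- sites[sites$gene_id == ids[i], , drop = FALSE]
    gene_record(
      id = ids[i],
      sequence = as.character(seqs[[i]]),
      donor_sites = s$position[s$site_type == "donor"],
      acceptor_sites = s$position[s$site_type == "acceptor"],
      source = basename(fasta_source))
  })
}

# returns data.frame(gene_id, site_type, position) with 0-based positions
read_site_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "site_type", "position", "coordinate_base")
  if (!all(need %in% names(tab))) {
    stop("site table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  if (!all(tab$site_type %in% c("donor", "acceptor"))) {
    stop("site table ", path, ": site_type must be 'donor' or 'acceptor'")
  }
  if (!all(tab$coordinate_base %in% c(0L, 1L))) {
    stop("site table ", path, ": coordinate_base must be 0 or 1")
  }
  data.frame(gene_id = as.character(tab$gene_id),
             site_type = tab$site_type,
             position = as.integer(tab$position) - as.integer(tab$coordinate_base),
             stringsAsFactors = FALSE)
}

sites_from_gff <- function(path, format, donor_offset, acceptor_offset) {
  gr <- rtracklayer::import(path, format = format)
  introns <- gr[tolower(as.character(gr$type)) == "intron"]
  if (length(introns) == 0L) {
    exons <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(exons) == 0L) {
      stop("no intron or exon features in ", path)
    }
    grp <- gff_group_id(exons)
    pieces <- split(exons, paste(as.character(GenomicRanges::seqnames(exons)),
                                 grp, sep = "\r"))
    introns <- do.call(c, unname(lapply(pieces, function(ex) {
      ex <- sort(ex)
      if (length(ex) < 2L) return(GenomicRanges::GRanges())
      GenomicRanges::GRanges(
        seqnames = as.character(GenomicRanges::seqnames(ex))[1L],
        ranges = IRanges::IRanges(
          start = GenomicRanges::end(ex)[-length(ex)] + 1L,
          end = GenomicRanges::start(ex)[-1L] - 1L))
    })))
  }
  if (length(introns) == 0L) {
    return(data.frame(gene_id = character(), site_type = character(),
                      position = integer(), stringsAsFactors = FALSE))
  }
  # 1-based inclusive -> 0-based: donor = first intron base, acceptor = last
  gene_id <- as.character(GenomicRanges::seqnames(introns))
  donor <- GenomicRanges::start(introns) - 1L + as.integer(donor_offset)
  acceptor <- GenomicRanges::end(introns) - 1L + as.integer(acceptor_offset)
  rbind(
    data.frame(gene_id = gene_id, site_type = "donor", position = donor,
               stringsAsFactors = FALSE),
    data.frame(gene_id = gene_id, site_type = "acceptor", position = acceptor,
               stringsAsFactors = FALSE))
}

gff_group_id <- function(exons) {
  md <- S4Vectors::mcols(exons)
  for (col in c("Parent", "transcript_id", "gene_id", "ID")) {
    if (col %in% names(md)) {
      v <- md[[col]]
      if (methods::is(v, "List")) v <- vapply(v, function(z) {
        if (length(z)) as.character(z[[1L]]) else NA_character_
      }, character(1L))
      v <- as.character(v)
      if (!all(is.na(v))) return(v)
    }
  }
  rep("g", length(exons))
}

#' Write gene records to FASTA plus annotations
#'
#' Emits a FASTA file with one entry per gene, a 0-based `site_table`
#' (dialect documented in [read_genes]), and optionally a truth GFF3 whose
#' single-base `splice_donor_site` / `splice_acceptor_site` features carry the
#' annotated positions (1-based inclusive, per GFF3).
#'
#' @param genes List of [gene_record].
#' @param fasta_path,site_table_path,gff3_path Output paths; `gff3_path = NULL`
#'   skips the GFF3.
#' @return Invisibly, the paths written.
#' @export
write_genes <- function(genes, fasta_path, site_table_path, gff3_path = NULL) {
  seqs <- Biostrings::DNAStringSet(vapply(genes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genes, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)

  rows <- do.call(rbind, lapply(genes, function(g) {
    data.frame(
      gene_id = g$id,
      site_type = rep(c("donor", "acceptor"),
                      c(length(g$donor_sites), length(g$acceptor_sites))),
      position = c(g$donor_sites, g$acceptor_sites),
      coordinate_base = 0L, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(gene_id = character(), site_type = character(),
                       position = integer(), coordinate_base = integer())
  }
  utils::write.table(rows, site_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (!is.null(gff3_path)) {
    grs <- lapply(genes, function(g) {
      pos <- c(g$donor_sites, g$acceptor_sites)
      if (!length(pos)) return(GenomicRanges::GRanges())
      gr <- GenomicRanges::GRanges(
        seqnames = g$id,
        ranges = IRanges::IRanges(start = pos + 1L, width = 1L))
      gr$type <- rep(c("splice_donor_site", "splice_acceptor_site"),
                     c(length(g$donor_sites), length(g$acceptor_sites)))
      gr$source <- "splicecnn"
      gr
    })
    gr <- do.call(c, grs[vapply(grs, length, 0L) > 0L])
    rtracklayer::export(gr, gff3_path, format = "gff3")
  }
  invisible(c(fasta_path, site_table_path, gff3_path))
}
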