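#' Per-nucleotide sliding-window scan of a gene
#'
#' Classifies every position of the sequence: the window centered on each
#' nucleotide (zero-padded at the edges, never skipped) is encoded and
#' pushed through the model; windows are streamed in batches so the full
#' one-hot tensor for a gene never has to exist at once. Results are
#' independent of `batch_size`.
#'
#' The `model` argument may also be a plain R function taking the encoded
#' window stack ((B * window_length) x 4 matrix) plus the batch size and
#' returning a B x 3 probability matrix -- useful for stub models in tests.
#'
#' @param gene A [gene_record].
#' @param model A `splice_model`, or a stub function (see above).
#' @param spec A [window_spec]; must match the model input when a real model
#'   is given.
#' @param batch_size Windows per forward pass, default 512.
#' @return An object of class `prediction_track`: list with `gene_id`,
#'   `length`, `probabilities` (length x 3, columns donor/acceptor/other,
#'   rows summing to 1) and `called_class` (per-position argmax label).
#' @export
scan <- function(gene, model, spec, batch_size = 512L) {
  stopifnot(inherits(gene, "gene_record"), inherits(spec, "window_spec"))
  is_stub <- is.function(model)
  if (!is_stub) {
    stopifnot(inherits(model, "splice_model"))
    if (model$spec$input_window$window_length != spec$window_length) {
      stop("scan: window spec (length ", spec$window_length,
           ") does not match model input (",
           model$spec$input_window$window_length, ")")
    }
  }
  n <- nchar(gene$sequence)
  f <- spec$flanking_length
  L <- spec$window_length
  padded <- rbind(matrix(0, f, 4L), encode_sequence(gene$sequence),
                  matrix(0, f, 4L))
  probs <- matrix(NA_real_, n, 3L, dimnames = list(NULL, LABELS))
  i <- 0L
  while (i < n) {
    B <- min(batch_size, n - i)
    centers <- i:(i + B - 1L)
    idx <- as.vector(outer(seq_len(L), centers, `+`))
    X <- padded[idx, , drop = FALSE]
    probs[centers + 1L, ] <- if (is_stub) {
      model(X, B)
    } else {
      nn_forward(model, X, B, training = FALSE)$probs
    }
    i <- i + B
  }
  new_prediction_track(gene$id, probs)
}

new_prediction_track <- function(gene_id, probs) {
  colnames(probs) <- LABELS
  structure(list(gene_id = gene_id, length = nrow(probs),
                 probabilities = probs,
                 called_class = LABELS[max.col(probs, ties.method = "first")]),
            class = "prediction_track")
}

#' @export
print.prediction_track <- function(x, ...) {
  tab <- table(factor(x$called_class, levels = LABELS))
  cat(sprintf("<prediction_track> %s: %d positions (%s)\n", x$gene_id,
              x$length, paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Call splice sites from a probability track
#'
#' Positions whose argmax class equals `site_type` (optionally also clearing
#' a minimum-probability threshold), ordered by that class's probability
#' descending, ties broken by ascending position. A pure function of the
#' track: works identically for real and stub models.
#'
#' @param track A `prediction_track`.
#' @param site_type "donor" or "acceptor".
#' @param min_prob Optional minimum probability for a call (default 0: pure
#'   argmax semantics).
#' @return data.frame with 0-based `position` and `probability`, in call
#'   order.
#' @export
call_sites <- function(track, site_type = c("donor", "acceptor"),
                       min_prob = 0) {
  stopifnot(inherits(track, "prediction_track"))
  site_type <- match.arg(site_type)
  p <- track$probabilities[, site_type]
  hit <- which(track$called_class == site_type & p >= min_prob)
  if (!length(hit)) {
    return(data.frame(position = integer(), probability = numeric()))
  }
  ord <- hit[order(-p[hit], hit)]
  data.frame(position = ord - 1L, probability = unname(p[ord]))
}

#' Write a probability track as TSV
#'
#' Columns: `gene_id`, 0-based `position`, `p_donor`, `p_acceptor`,
#' `p_other`, `call`.
#'
#' @param track A `prediction_track`.
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  df <- data.frame(gene_id = track$gene_id,
                   position = seq_len(track$length) - 1L,
                   p_donor = track$probabilities[, "donor"],
                   p_acceptor = track$probabilities[, "acceptor"],
                   p_other = track$probabilities[, "other"],
                   call = track$called_class)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probability track written by [write_track]
#' @param path TSV path.
#' @return A `prediction_track`.
#' @export
read_track <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  probs <- as.matrix(df[, c("p_donor", "p_acceptor", "p_other")])
  new_prediction_track(df$gene_id[1L], unname(probs))
}

#' Write called sites as BED or GFF3
#'
#' BED intervals are 0-based half-open single-base records with score
#' `round(probability * 1000)` clamped to [0, 1000]; GFF3 features are
#' 1-based single-base `splice_donor_site`/`splice_acceptor_site` records
#' with the probability as score.
#'
#' @param calls data.frame from [call_sites].
#' @param gene_id Sequence name for the output records.
#' @param site_type "donor" or "acceptor".
#' @param path Output path.
#' @param format "bed" or "gff3".
#' @export
write_calls <- function(calls, gene_id, site_type, path,
                        format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- data.frame(chrom = gene_id,
                     start = calls$position,
                     end = calls$position + 1L,
                     name = paste0(site_type, "_", calls$position),
                     score = pmin(1000L, pmax(0L, round(calls$probability * 1000))),
                     strand = "+")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    df <- data.frame(seqid = gene_id, source = "splicecnn",
                     type = paste0("splice_", site_type, "_site"),
                     start = calls$position + 1L,
                     end = calls$position + 1L,
                     score = sprintf("%.4f", calls$probability),
                     strand = "+", phase = ".", attributes = ".")
    writeLines(c("##gff-version 3",
                 apply(df, 1L, paste, collapse = "\t")), path)
  }
  invisible(path)
}
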