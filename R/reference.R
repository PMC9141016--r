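#' Bundled reference per-gene evaluation rows
#'
#' A small table of independently published per-gene splice-site scan
#' results (gene length, number of true sites, site-level accuracy, top-k
#' and top-50% accuracies, number of predicted sites, false-positive
#' percentage) for human and non-human genes. The integer counts are used as
#' inputs to validate this package's metric arithmetic: see
#' [recompute_reference_rows].
#'
#' @return data.frame, one row per gene x site type.
#' @export
reference_gene_eval <- function() {
  utils::read.delim(system.file("extdata", "reference_gene_eval.tsv",
                                package = "splicecnn"),
                    stringsAsFactors = FALSE)
}

#' Recompute reference evaluation rows from their integer inputs
#'
#' For each reference row the printed percentages are reduced to the integer
#' counts they encode (sites recovered, ranking hits, sites predicted), a
#' deterministic probability track realizing those counts is built with
#' [reconstruct_track], and every percentage is then recomputed from the
#' track by the package's metric functions ([site_level_accuracy],
#' [top_k_accuracy], [top_percent_accuracy], [false_positive_pct],
#' [call_sites]). Agreement with the printed values validates the metric
#' definitions, not the model.
#'
#' @param rows data.frame in the layout of [reference_gene_eval] (default).
#' @return The input with recomputed columns `accuracy_pct`, `top_k_pct`,
#'   `top_half_pct`, `n_predicted`, `fp_pct` plus raw-fraction columns
#'   `accuracy`, `top_k`, `top_pct`, `fp`.
#' @export
recompute_reference_rows <- function(rows = reference_gene_eval()) {
  out <- rows
  out$accuracy <- out$top_k <- out$top_pct <- out$fp <- NA_real_
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    k <- r$n_sites
    rec <- reconstruct_track(
      len = r$length,
      n_true = k,
      n_recovered = round(r$accuracy_pct / 100 * k),
      n_predicted = r$n_predicted,
      hits_top_k = round(r$top_k_pct / 100 * k),
      hits_top_half = round(r$top_half_pct / 100 * k),
      site_type = r$site)
    tr <- rec$track
    ts <- rec$true_sites
    out$accuracy[i] <- site_level_accuracy(tr, ts, r$site)
    out$top_k[i] <- top_k_accuracy(tr, ts, r$site)
    out$top_pct[i] <- top_percent_accuracy(tr, ts, r$site, percent = 50)
    out$fp[i] <- false_positive_pct(tr, ts, r$site)
    out$n_predicted[i] <- nrow(call_sites(tr, r$site))
    out$accuracy_pct[i] <- round(100 * out$accuracy[i], 2)
    out$top_k_pct[i] <- round(100 * out$top_k[i])
    out$top_half_pct[i] <- round(100 * out$top_pct[i])
    out$fp_pct[i] <- round(100 * out$fp[i], 2)
  }
  out$top_pct_pct <- out$top_half_pct  # column alias matching evaluate_gene()
  out
}
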