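# Ranking convention used throughout: positions ordered by the probability
# of the site class, descending, ties broken by ascending position.
rank_positions <- function(track, site_type) {
  p <- track$probabilities[, site_type]
  order(-p, seq_along(p))  # 1-based indices in rank order
}

#' Window-level classification report
#'
#' Overall argmax accuracy, one-vs-rest specificity / recall / precision /
#' F1 per class, the 3 x 3 confusion matrix, and macro one-vs-rest ROC-AUC
#' and PR-AUC (average precision). A class absent from `true_labels` gets
#' `NA` per-class metrics and is excluded from the macro AUC averages
#' (undefined, never counted as 0).
#'
#' @param true_labels Character vector over donor/acceptor/other.
#' @param predicted_probabilities N x 3 matrix, columns donor/acceptor/other,
#'   rows summing to 1.
#' @return An object of class `metrics_report`.
#' @export
classification_report <- function(true_labels, predicted_probabilities) {
  stopifnot(length(true_labels) == nrow(predicted_probabilities),
            all(true_labels %in% LABELS))
  probs <- predicted_probabilities
  if (is.null(colnames(probs))) colnames(probs) <- LABELS
  pred <- LABELS[max.col(probs, ties.method = "first")]
  truth <- factor(true_labels, levels = LABELS)
  predf <- factor(pred, levels = LABELS)
  confusion <- table(truth = truth, predicted = predf)
  accuracy <- mean(pred == true_labels)
  per_class <- lapply(LABELS, function(cl) {
    pos <- truth == cl
    if (!any(pos)) {
      return(list(specificity = NA_real_, recall = NA_real_,
                  precision = NA_real_, f1 = NA_real_,
                  roc_auc = NA_real_, pr_auc = NA_real_))
    }
    tp <- sum(pos & predf == cl)
    fp <- sum(!pos & predf == cl)
    fn <- sum(pos & predf != cl)
    tn <- sum(!pos & predf != cl)
    recall <- tp / (tp + fn)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    list(specificity = tn / (tn + fp),
         recall = recall,
         precision = precision,
         f1 = if (is.na(precision) || precision + recall == 0) NA_real_
              else 2 * precision * recall / (precision + recall),
         roc_auc = roc_auc_binary(pos, probs[, cl]),
         pr_auc = pr_auc_binary(pos, probs[, cl]))
  })
  names(per_class) <- LABELS
  rocs <- vapply(per_class, `[[`, 0, "roc_auc")
  prs <- vapply(per_class, `[[`, 0, "pr_auc")
  structure(list(
    accuracy = accuracy,
    per_class = per_class,
    roc_auc = if (all(is.na(rocs))) NA_real_ else mean(rocs, na.rm = TRUE),
    pr_auc = if (all(is.na(prs))) NA_real_ else mean(prs, na.rm = TRUE),
    confusion = confusion,
    n = length(true_labels)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d accuracy=%.4f macro ROC-AUC=%.4f macro PR-AUC=%.4f\n",
              x$n, x$accuracy, x$roc_auc, x$pr_auc))
  for (cl in names(x$per_class)) {
    pc <- x$per_class[[cl]]
    cat(sprintf("  %-9s spec=%.4f recall=%.4f precision=%.4f F1=%.4f\n",
                cl, pc$specificity, pc$recall, pc$precision, pc$f1))
  }
  invisible(x)
}

# ROC-AUC via the rank (Mann-Whitney) statistic; ties get half credit.
roc_auc_binary <- function(is_pos, score) {
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# PR-AUC as average precision: precision accumulated at each recalled
# positive, descending score (ties by original order).
pr_auc_binary <- function(is_pos, score) {
  n_pos <- sum(is_pos)
  if (n_pos == 0L) return(NA_real_)
  ord <- order(-score)
  hits <- cumsum(is_pos[ord])
  prec <- hits / seq_along(hits)
  sum(prec[is_pos[ord]]) / n_pos
}

#' Top-k ranked-retrieval accuracy for one site type
#'
#' All positions of the track are ranked by the probability of `site_type`,
#' descending (ties: ascending position). With k defaulting to the number of
#' true sites, the value is |top-k positions intersected with true sites| / k.
#'
#' @param track A `prediction_track`.
#' @param true_sites Integer vector of 0-based true positions.
#' @param site_type "donor" or "acceptor".
#' @param k Cutoff; defaults to `length(true_sites)`. `k = 0` is undefined
#'   and returns NA.
#' @return Fraction in [0, 1], or NA.
#' @export
top_k_accuracy <- function(track, true_sites,
                           site_type = c("donor", "acceptor"), k = NULL) {
  stopifnot(inherits(track, "prediction_track"))
  site_type <- match.arg(site_type)
  if (is.null(k)) k <- length(true_sites)
  if (k == 0L) return(NA_real_)
  top <- rank_positions(track, site_type)[seq_len(min(k, track$length))] - 1L
  length(intersect(top, true_sites)) / k
}

#' Top-percent ranked-retrieval accuracy
#'
#' Fraction of true sites found within the top `floor(percent/100 * length)`
#' positions of the probability ranking. Non-decreasing in `percent`;
#' `percent = 100` is 1 whenever true sites exist.
#'
#' @inheritParams top_k_accuracy
#' @param percent In (0, 100].
#' @return Fraction in [0, 1]; NA when the cutoff rounds to zero positions
#'   or there are no true sites.
#' @export
top_percent_accuracy <- function(track, true_sites,
                                 site_type = c("donor", "acceptor"),
                                 percent = 50) {
  stopifnot(inherits(track, "prediction_track"),
            percent > 0, percent <= 100)
  site_type <- match.arg(site_type)
  if (!length(true_sites)) return(NA_real_)
  m <- floor(percent / 100 * track$length)
  if (m == 0L) return(NA_real_)
  top <- rank_positions(track, site_type)[seq_len(m)] - 1L
  length(intersect(top, true_sites)) / length(true_sites)
}

#' False-positive percentage over a scanned sequence
#'
#' With P the number of positions called as `site_type` (argmax) and TP the
#' number of those that are annotated sites, returns (P - TP) / length --
#' called sites that match no annotation, as a fraction of sequence length.
#' Bounded by P / length and invariant to call ordering.
#'
#' @inheritParams top_k_accuracy
#' @return Fraction in [0, 1] (multiply by 100 for the percentage display).
#' @export
false_positive_pct <- function(track, true_sites,
                               site_type = c("donor", "acceptor")) {
  stopifnot(inherits(track, "prediction_track"))
  site_type <- match.arg(site_type)
  called <- which(track$called_class == site_type) - 1L
  (length(called) - length(intersect(called, true_sites))) / track$length
}

#' Site-level accuracy (recall over annotated sites)
#'
#' Fraction of true sites whose position is called as `site_type` by argmax.
#'
#' @inheritParams top_k_accuracy
#' @return Fraction in [0, 1]; NA for empty `true_sites`.
#' @export
site_level_accuracy <- function(track, true_sites,
                                site_type = c("donor", "acceptor")) {
  stopifnot(inherits(track, "prediction_track"))
  site_type <- match.arg(site_type)
  if (!length(true_sites)) return(NA_real_)
  called <- which(track$called_class == site_type) - 1L
  length(intersect(called, true_sites)) / length(true_sites)
}

#' Per-gene evaluation rows for both site types
#'
#' One row per site type with the per-gene scan statistics: site-level
#' accuracy, top-k accuracy (k = number of true sites of that type), top-50%
#' accuracy, number of predicted sites, and false-positive percentage.
#' Raw fractions are returned; `*_pct` columns are on the 0-100 scale
#' rounded as displayed (percentages to 2 decimals, ranked accuracies to
#' integers).
#'
#' @param track A `prediction_track`.
#' @param donor_sites,acceptor_sites 0-based true positions.
#' @param top_percent Percent cutoff for the top-percent column, default 50.
#' @return data.frame with one row per site type.
#' @export
evaluate_gene <- function(track, donor_sites, acceptor_sites,
                          top_percent = 50) {
  rows <- lapply(c("donor", "acceptor"), function(st) {
    ts <- if (st == "donor") donor_sites else acceptor_sites
    acc <- site_level_accuracy(track, ts, st)
    tk <- top_k_accuracy(track, ts, st)
    tp <- top_percent_accuracy(track, ts, st, percent = top_percent)
    fp <- false_positive_pct(track, ts, st)
    np <- sum(track$called_class == st)
    data.frame(gene_id = track$gene_id, length = track$length,
               n_sites = length(ts), site = st,
               accuracy = acc, top_k = tk, top_pct = tp,
               n_predicted = np, fp = fp,
               accuracy_pct = round(100 * acc, 2),
               top_k_pct = round(100 * tk),
               top_pct_pct = round(100 * tp),
               fp_pct = round(100 * fp, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Column averages of per-gene evaluation rows
#'
#' Averages the accuracy, top-k, top-percent and false-positive columns over
#' all rows. `round_rows = FALSE` (default) averages the raw fractions;
#' `round_rows = TRUE` averages the display-rounded percentages instead
#' (integer-rounded ranked accuracies, 2-decimal percentages), which is what
#' a reader recomputing the means of a printed table obtains.
#'
#' @param rows data.frame as returned by (rbinding) [evaluate_gene].
#' @param round_rows Logical, see above.
#' @return Named numeric vector of means on the percentage (0-100) scale:
#'   `accuracy`, `top_k`, `top_pct`, `fp`.
#' @export
table_summary <- function(rows, round_rows = FALSE) {
  if (round_rows) {
    c(accuracy = mean(rows$accuracy_pct), top_k = mean(rows$top_k_pct),
      top_pct = mean(rows$top_pct_pct), fp = mean(rows$fp_pct))
  } else {
    c(accuracy = 100 * mean(rows$accuracy), top_k = 100 * mean(rows$top_k),
      top_pct = 100 * mean(rows$top_pct), fp = 100 * mean(rows$fp))
  }
}

#' Reconstruct a deterministic track realizing given evaluation counts
#'
#' Builds a `prediction_track` of length `len` on which the scan statistics
#' take exactly the requested values: `n_true` true sites of `site_type`, of
#' which `n_recovered` are called, `n_predicted` total argmax calls,
#' `hits_top_k` true sites inside the top-k ranking (k = n_true) and
#' `hits_top_half` inside the top 50%. Used to validate metric arithmetic
#' against independently published per-gene evaluation rows: the counts are
#' the inputs, all percentages are then recomputed by the metric functions.
#'
#' Requires `hits_top_k <= hits_top_half <= n_recovered <= n_true` and
#' `n_true <= n_predicted + (n_true - n_recovered)` head-room within `len`.
#'
#' @param len Sequence length.
#' @param n_true,n_recovered,n_predicted,hits_top_k,hits_top_half Counts.
#' @param site_type "donor" or "acceptor".
#' @return List with `track` and `true_sites` (0-based).
#' @export
reconstruct_track <- function(len, n_true, n_recovered, n_predicted,
                              hits_top_k = n_recovered,
                              hits_top_half = n_recovered,
                              site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  stopifnot(hits_top_k <= hits_top_half, hits_top_half <= n_recovered,
            n_recovered <= n_true, n_recovered <= n_predicted,
            n_predicted + n_true <= len %/% 2L)
  true_sites <- seq(10L, by = 7L, length.out = n_true)  # 0-based, spaced
  stopifnot(max(true_sites) < len)
  n_decoy <- n_predicted - n_recovered
  decoys <- setdiff(seq(max(true_sites) + 11L, by = 3L,
                        length.out = n_decoy + n_true), true_sites)[seq_len(n_decoy)]
  stopifnot(length(decoys) == n_decoy, max(decoys, 0L) < len)

  p_site <- rep(0.05, len)   # 0-based position i -> index i + 1
  # background: argmax "other" but ranked above low-probability calls
  p_site[] <- 0.40
  # decoys occupying the head of the ranking: k - hits_top_k of them (or all)
  k <- n_true
  n_decoy_top <- min(k - hits_top_k, n_decoy)
  ord_probs <- seq(0.99, 0.90, length.out = max(n_decoy_top, 1L))
  if (n_decoy_top > 0L) {
    p_site[decoys[seq_len(n_decoy_top)] + 1L] <- ord_probs[seq_len(n_decoy_top)]
  }
  # recovered true sites inside top-k
  rec <- true_sites[seq_len(n_recovered)]
  if (hits_top_k > 0L) {
    p_site[rec[seq_len(hits_top_k)] + 1L] <-
      seq(0.89, 0.85, length.out = hits_top_k)
  }
  # remaining decoys: below the top-k block, above background
  if (n_decoy > n_decoy_top) {
    extra <- decoys[(n_decoy_top + 1L):n_decoy]
    p_site[extra + 1L] <- seq(0.84, 0.75, length.out = length(extra))
  }
  # recovered sites inside the top half but outside top-k
  if (hits_top_half > hits_top_k) {
    mid <- rec[(hits_top_k + 1L):hits_top_half]
    p_site[mid + 1L] <- seq(0.70, 0.60, length.out = length(mid))
  }
  # recovered sites outside the top half: still argmax calls, but ranked
  # below the (len-scale) background mass
  if (n_recovered > hits_top_half) {
    low <- rec[(hits_top_half + 1L):n_recovered]
    p_site[low + 1L] <- 0.345
  }
  # unrecovered true sites: not calls, ranked below background
  if (n_true > n_recovered) {
    miss <- true_sites[(n_recovered + 1L):n_true]
    p_site[miss + 1L] <- 0.05
  }
  called <- sort(c(rec, decoys))
  is_call <- logical(len)
  is_call[called + 1L] <- TRUE
  # calls: remaining mass split so site_type is argmax; non-calls: "other"
  p_other <- ifelse(is_call, (1 - p_site) * 0.6, 1 - p_site)
  p_third <- 1 - p_site - p_other
  probs <- matrix(0, len, 3L, dimnames = list(NULL, LABELS))
  other_col <- "other"
  third_col <- setdiff(c("donor", "acceptor"), site_type)
  probs[, site_type] <- p_site
  probs[, other_col] <- p_other
  probs[, third_col] <- p_third
  # non-call positions must not argmax site_type: background 0.40 vs other
  # 0.60 and misses 0.05 vs 0.95 both satisfy it; calls have site prob >
  # both remainders (0.345 vs 0.393?) -- fix low calls explicitly
  low_call <- is_call & probs[, site_type] < 0.5
  if (any(low_call)) {
    probs[low_call, other_col] <- (1 - probs[low_call, site_type]) / 2
    probs[low_call, third_col] <- (1 - probs[low_call, site_type]) / 2
  }
  list(track = new_prediction_track("reconstructed", probs),
       true_sites = true_sites)
}
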