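#' Weighted GSEA enrichment score
#'
#' Running-sum statistic over the ranked list: hitting a tag gene adds its
#' weight `|r|^exponent` (normalised so the hit mass sums to one), missing
#' subtracts `1/(n - t)`. The enrichment score is the running-sum value of
#' maximum absolute deviation from zero, signed; a tie between the positive
#' and negative extremes takes the positive branch. `exponent = 0` gives
#' the classic unweighted statistic; `exponent = 1` (the default) weights
#' hits by the ranking statistic.
#'
#' @param ranked a [ranked_list()] with statistic values.
#' @param tags character vector of tag genes.
#' @param exponent non-negative weighting exponent (default 1).
#' @return the enrichment score in `[-1, 1]`.
#' @export
gsea_es <- function(ranked, tags, exponent = 1) {
  if (exponent < 0) stop_sigrev("exponent must be non-negative", "sigrev_config_error")
  hit <- ranked$gene %in% unique(tags)
  t <- sum(hit); n <- nrow(ranked)
  if (t < 1L) stop_sigrev("no tag gene present in the ranked list", "sigrev_scoring_error")
  if (t >= n) stop_sigrev("tag set covers the entire ranked list", "sigrev_degenerate_error")
  w <- abs(ranked$stat) ^ exponent
  wsum <- sum(w[hit])
  if (exponent > 0 && wsum == 0)
    stop_sigrev("all tag weights are zero", "sigrev_degenerate_weight_error")
  incr <- numeric(n)
  incr[hit] <- w[hit] / wsum
  incr[!hit] <- -1 / (n - t)
  s <- cumsum(incr)
  mx <- max(s); mn <- min(s)
  if (mx >= -mn) mx else mn
}

#' Permutation significance and NES for one gene set
#'
#' Gene-set permutation null: random sets of the same retained size drawn
#' from the list's gene universe and rescored with the same weights.
#' Two-sided p on `|ES|`; NES divides the observed ES by the mean `|ES|`
#' among null values sharing its sign (flagged `NA` when no null value
#' does). q equals p here (a single-set family); use
#' [signature_direction_panel()] for multi-set FDR.
#'
#' @param ranked a [ranked_list()].
#' @param tags character vector of tag genes.
#' @param exponent weighting exponent (default 1).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param q_threshold FDR threshold for the direction call (default 0.05).
#' @param set_id identifier recorded in the result.
#' @return one-row data.frame: set_id, es, nes, p, q, direction_call.
#' @export
gsea_significance <- function(ranked, tags, exponent = 1, n_perm = 1000L, seed,
                              q_threshold = 0.05, set_id = "set") {
  if (n_perm < 100L) stop_sigrev("n_perm must be at least 100", "sigrev_config_error")
  es <- gsea_es(ranked, tags, exponent)
  t <- sum(ranked$gene %in% unique(tags))
  set.seed(entity_seed(seed, 0L))
  null <- vapply(seq_len(n_perm), function(i) {
    gsea_es(ranked, ranked$gene[sample.int(nrow(ranked), t)], exponent)
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(es))) / (n_perm + 1)
  same_sign <- if (es > 0) null > 0 else if (es < 0) null < 0 else rep(FALSE, n_perm)
  nes <- if (es == 0 || !any(same_sign)) NA_real_ else es / mean(abs(null[same_sign]))
  call <- if (es == 0 || p >= q_threshold) "null" else if (es < 0) "inverse" else "concordant"
  data.frame(set_id = set_id, es = es, nes = nes, p = p, q = p,
             direction_call = call, stringsAsFactors = FALSE)
}

#' Directional enrichment panel of a drug signature across disease lists
#'
#' For each disease-ranked list the drug's up and down tag sets are scored;
#' the disease is called `inverse` when the up tags are depleted
#' (`es < 0`) and the down tags enriched (`es > 0`) with both FDRs below
#' the threshold, `concordant` for the sign-reversed configuration, and
#' `null` otherwise. q is Benjamini-Hochberg across all tests of the panel
#' (two per list, one family per call).
#'
#' @param drug_sets a [signature_gene_sets()] pair.
#' @param disease_ranked named list of [ranked_list()] objects.
#' @param exponent weighting exponent (default 1).
#' @param n_perm permutations per test (>= 100).
#' @param seed integer seed.
#' @param q_threshold FDR threshold for direction calls (default 0.05).
#' @return data.frame with one row per list: list_id, es_up, es_down,
#'   nes_up, nes_down, p_up, p_down, q_up, q_down, direction_call.
#' @export
signature_direction_panel <- function(drug_sets, disease_ranked, exponent = 1,
                                      n_perm = 1000L, seed, q_threshold = 0.05) {
  stopifnot(inherits(drug_sets, "gene_set_pair"))
  ids <- names(disease_ranked)
  if (is.null(ids)) stop_sigrev("disease_ranked must be named", "sigrev_input_error")
  res_up <- vector("list", length(ids)); res_dn <- res_up
  for (i in seq_along(ids)) {
    res_up[[i]] <- gsea_significance(disease_ranked[[i]], drug_sets$up, exponent,
                                     n_perm, entity_seed(seed, 2L * i),
                                     q_threshold, set_id = "up")
    res_dn[[i]] <- gsea_significance(disease_ranked[[i]], drug_sets$down, exponent,
                                     n_perm, entity_seed(seed, 2L * i + 1L),
                                     q_threshold, set_id = "down")
  }
  p_all <- c(vapply(res_up, `[[`, numeric(1), "p"),
             vapply(res_dn, `[[`, numeric(1), "p"))
  q_all <- stats::p.adjust(p_all, method = "BH")
  k <- length(ids)
  out <- data.frame(
    list_id = ids,
    es_up = vapply(res_up, `[[`, numeric(1), "es"),
    es_down = vapply(res_dn, `[[`, numeric(1), "es"),
    nes_up = vapply(res_up, `[[`, numeric(1), "nes"),
    nes_down = vapply(res_dn, `[[`, numeric(1), "nes"),
    p_up = p_all[seq_len(k)], p_down = p_all[k + seq_len(k)],
    q_up = q_all[seq_len(k)], q_down = q_all[k + seq_len(k)],
    stringsAsFactors = FALSE)
  out$direction_call <- ifelse(
    out$es_up < 0 & out$es_down > 0 & out$q_up < q_threshold & out$q_down < q_threshold,
    "inverse",
    ifelse(out$es_up > 0 & out$es_down < 0 &
             out$q_up < q_threshold & out$q_down < q_threshold,
           "concordant", "null"))
  out
}
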