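# Signed KS tag-set statistic on sorted 1-based positions.
# a = max_j(j/t - V_j/n), b = max_j(V_j/n - (j-1)/t); ES = a if a >= b else -b
# (the tie a == b takes the positive branch, fixed and documented).
ks_stat_positions <- function(pos_sorted, n) {
  t <- length(pos_sorted)
  j <- seq_len(t)
  a <- max(j / t - pos_sorted / n)
  b <- max(pos_sorted / n - (j - 1) / t)
  if (a >= b) a else -b
}

#' Signed Kolmogorov-Smirnov enrichment of a tag set in a ranked list
#'
#' The classic connectivity-mapping statistic: the maximum deviation of the
#' tag-position empirical distribution above (positive, tags near the top)
#' or below (negative, tags near the bottom) the uniform expectation.
#' Tag genes absent from the list are dropped; fewer than 25% retained is a
#' coverage error, and a tag set spanning the whole list is degenerate.
#'
#' @param tags character vector of gene identifiers.
#' @param ranked a [ranked_list()] (or data.frame with a `gene` column).
#' @return a single number in `[-1, 1]`.
#' @export
ks_enrichment <- function(tags, ranked) {
  pos <- tag_positions(tags, ranked)
  ks_stat_positions(pos, nrow(ranked))
}

tag_positions <- function(tags, ranked) {
  stopifnot(is.character(tags))
  if (anyDuplicated(tags)) tags <- unique(tags)
  pos <- match(tags, ranked$gene)
  pos <- sort(pos[!is.na(pos)])
  n <- nrow(ranked)
  if (length(pos) == 0L)
    stop_sigrev("no tag gene present in the ranked list", "sigrev_scoring_error")
  if (length(pos) < 0.25 * length(tags))
    stop_sigrev("fewer than 25% of tag genes retained in the ranked list",
                "sigrev_coverage_error")
  if (length(pos) >= n)
    stop_sigrev("tag set covers the entire ranked list", "sigrev_degenerate_error")
  pos
}

#' Connectivity score of a drug tag-set pair against a disease profile
#'
#' `es_up` and `es_down` are the KS enrichments of the up and down tags in
#' the disease-ranked list. When they disagree in sign the score is their
#' half-difference; when they agree (the drug moves both sets the same way
#' as the disease, an uninterpretable configuration) the score is zeroed.
#' Negative scores mean the drug signature opposes — is predicted to
#' "normalise" — the disease signature.
#'
#' @param drug_sets a [signature_gene_sets()] pair.
#' @param disease_ranked a [ranked_list()] for the disease contrast.
#' @return list with `es_up`, `es_down`, `score`, and `raw` (the un-zeroed
#'   half-difference used by the permutation machinery).
#' @export
connectivity_score <- function(drug_sets, disease_ranked) {
  stopifnot(inherits(drug_sets, "gene_set_pair"))
  es_up <- ks_enrichment(drug_sets$up, disease_ranked)
  es_down <- ks_enrichment(drug_sets$down, disease_ranked)
  raw <- (es_up - es_down) / 2
  # sign opposition required; either ES being exactly 0 also zeroes the score
  same_sign <- es_up == 0 || es_down == 0 || sign(es_up) == sign(es_down)
  list(es_up = es_up, es_down = es_down,
       score = if (same_sign) 0 else raw, raw = raw)
}

# Null draws of the un-zeroed half-difference statistic: up and down tag
# sets are redrawn jointly without replacement (disjoint, as in the data).
null_raw_scores <- function(n, t_up, t_down, n_draws) {
  d <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    pos <- sample.int(n, t_up + t_down)
    e_up <- ks_stat_positions(sort.int(pos[seq_len(t_up)]), n)
    e_dn <- ks_stat_positions(sort.int(pos[t_up + seq_len(t_down)]), n)
    d[i] <- (e_up - e_dn) / 2
  }
  d
}

#' Permutation significance of one drug/disease connectivity score
#'
#' The null redraws both tag sets as uniform random, mutually disjoint gene
#' sets of the same retained sizes and rescores. Significance is two-sided
#' on the magnitude of the un-zeroed half-difference statistic
#' `(es_up - es_down)/2` — the statistic is continuous under this null, so
#' the p-values are uniformly distributed when there is no signal (the
#' sign-zeroed score has an atom at zero and would not be).
#'
#' @param drug_sets a [signature_gene_sets()] pair.
#' @param disease_ranked a [ranked_list()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `p`, `observed` (raw statistic) and `null` (vector of
#'   `n_perm` null statistics); `p >= 1/(n_perm + 1)` by construction.
#' @export
permutation_significance <- function(drug_sets, disease_ranked, n_perm = 1000L, seed) {
  if (n_perm < 100L)
    stop_sigrev("n_perm must be at least 100", "sigrev_config_error")
  obs <- connectivity_score(drug_sets, disease_ranked)
  t_up <- length(tag_positions(drug_sets$up, disease_ranked))
  t_dn <- length(tag_positions(drug_sets$down, disease_ranked))
  set.seed(entity_seed(seed, 0L))
  null <- null_raw_scores(nrow(disease_ranked), t_up, t_dn, n_perm)
  p <- (1 + sum(abs(null) >= abs(obs$raw))) / (n_perm + 1)
  list(p = p, observed = obs$raw, null = null)
}

#' Score a drug signature library against a disease profile library
#'
#' One row per compound-condition/disease pair. Null statistics are pooled
#' across all pairs within strata of identical geometry (list length,
#' retained up/down tag sizes): each pair contributes `n_perm` draws, and
#' every pair in the stratum is referred to the pooled sample. Pooling
#' sharpens the attainable p resolution to roughly
#' `1/(n_perm x stratum size)`, which a per-pair null cannot reach and which
#' the downstream FDR threshold requires. q is Benjamini-Hochberg over all
#' scoreable rows of the run (one family); rows failing tag coverage are
#' flagged and excluded from the family.
#'
#' @param drug_sets named list of [signature_gene_sets()] pairs; names are
#'   `"<compound>|<condition>"` keys (or supply `origin` on each pair).
#' @param disease_ranked named list of [ranked_list()] objects.
#' @param n_perm null draws contributed per pair (>= 100).
#' @param seed integer seed.
#' @return data.frame of class `connectivity_table` with columns compound,
#'   condition, disease, es_up, es_down, score, p, q, n_perm (pooled null
#'   size used for the row), flag.
#' @export
score_library <- function(drug_sets, disease_ranked, n_perm = 1000L, seed) {
  if (n_perm < 100L)
    stop_sigrev("n_perm must be at least 100", "sigrev_config_error")
  if (length(drug_sets) < 1L || length(disease_ranked) < 1L)
    stop_sigrev("need at least one signature and one disease", "sigrev_input_error")
  keys <- names(drug_sets)
  if (is.null(keys)) stop_sigrev("drug_sets must be named", "sigrev_input_error")
  rows <- vector("list", length(drug_sets) * length(disease_ranked))
  r <- 0L
  for (i in seq_along(drug_sets)) {
    parts <- strsplit(keys[i], "|", fixed = TRUE)[[1]]
    cpd <- parts[1]
    cond <- if (length(parts) > 1L) paste(parts[-1], collapse = "|") else NA_character_
    for (jd in seq_along(disease_ranked)) {
      r <- r + 1L
      row <- list(compound = cpd, condition = cond,
                  disease = names(disease_ranked)[jd],
                  es_up = NA_real_, es_down = NA_real_, score = NA_real_,
                  raw = NA_real_, t_up = NA_integer_, t_down = NA_integer_,
                  n = nrow(disease_ranked[[jd]]),
                  p = NA_real_, q = NA_real_, n_perm = NA_integer_, flag = "")
      res <- tryCatch({
        ru <- tag_positions(drug_sets[[i]]$up, disease_ranked[[jd]])
        rd <- tag_positions(drug_sets[[i]]$down, disease_ranked[[jd]])
        sc <- connectivity_score(drug_sets[[i]], disease_ranked[[jd]])
        row[c("es_up", "es_down", "score", "raw")] <-
          sc[c("es_up", "es_down", "score", "raw")]
        row$t_up <- length(ru); row$t_down <- length(rd)
        row
      }, sigrev_error = function(e) { row$flag <- conditionMessage(e); row })
      rows[[r]] <- res
    }
  }
  tab <- do.call(rbind, lapply(rows, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
  ok <- tab$flag == ""
  # pooled null per stratum of identical (n, t_up, t_down)
  strata <- interaction(tab$n[ok], tab$t_up[ok], tab$t_down[ok], drop = TRUE)
  p <- rep(NA_real_, nrow(tab))
  npool <- rep(NA_integer_, nrow(tab))
  for (s in seq_along(levels(strata))) {
    idx <- which(ok)[strata == levels(strata)[s]]
    n <- tab$n[idx[1]]; tu <- tab$t_up[idx[1]]; td <- tab$t_down[idx[1]]
    total <- n_perm * length(idx)
    set.seed(entity_seed(seed, 40000L + s))
    null_abs <- sort(abs(null_raw_scores(n, tu, td, total)))
    p[idx] <- (1 + count_ge(abs(tab$raw[idx]), null_abs)) / (total + 1)
    npool[idx] <- total
  }
  tab$p <- p
  tab$n_perm <- npool
  tab$q[ok] <- stats::p.adjust(tab$p[ok], method = "BH")
  tab$raw <- NULL; tab$t_up <- NULL; tab$t_down <- NULL; tab$n <- NULL
  class(tab) <- c("connectivity_table", "data.frame")
  tab
}

#' Cross-condition inverse-concordance call for one compound/disease
#'
#' TRUE only when every expected condition is present with a strictly
#' negative score and q strictly below the threshold (q equal to the
#' threshold fails). A missing expected condition is incomplete evidence
#' and raises an error rather than returning FALSE.
#'
#' @param results a [score_library()] table (or subset).
#' @param compound,disease identifiers selecting the pair.
#' @param q_threshold FDR threshold (default 0.01).
#' @param expected_conditions required number of conditions (default 4).
#' @return list with `compound`, `disease`, `inverse_concordant`, and the
#'   per-condition rows.
#' @export
concordant_inverse <- function(results, compound, disease,
                               q_threshold = 0.01, expected_conditions = 4L) {
  sub <- results[results$compound == compound & results$disease == disease, , drop = FALSE]
  if (nrow(sub) < 1L)
    stop_sigrev("no conditions present for this compound/disease",
                "sigrev_incomplete_evidence_error")
  if (length(unique(sub$condition)) < expected_conditions)
    stop_sigrev(sprintf("expected %d conditions, found %d",
                        expected_conditions, length(unique(sub$condition))),
                "sigrev_incomplete_evidence_error")
  call <- all(!is.na(sub$score) & sub$score < 0 &
                !is.na(sub$q) & sub$q < q_threshold)
  list(compound = compound, disease = disease,
       inverse_concordant = call, conditions = sub)
}

#' Percentile rank of a connectivity score within a library
#'
#' Scores are ranked ascending (most negative = strongest predicted
#' reversal = rank 1); tied scores share the best rank. The percentile is
#' `100 * rank / library size`, so the single best of 50 scores sits at the
#' 2nd percentile.
#'
#' @param target_score score of the compound of interest; must be present
#'   in `library_scores`.
#' @param library_scores numeric vector of all compounds' scores.
#' @return percentile in `(0, 100]`.
#' @export
percentile_rank <- function(target_score, library_scores) {
  if (length(library_scores) == 0L || !any(library_scores == target_score))
    stop_sigrev("target score not present in the library", "sigrev_lookup_error")
  rank_best <- sum(library_scores < target_score) + 1L
  100 * rank_best / length(library_scores)
}

#' Aggregate compound-level scores against one disease
#'
#' The compound-level score is the mean connectivity score across the
#' compound's conditions for the given disease (the package's documented
#' aggregation for library percentile ranking).
#'
#' @param results a [score_library()] table.
#' @param disease disease identifier.
#' @return data.frame with columns compound, score, percentile, sorted by
#'   score ascending (strongest predicted reversal first).
#' @export
rank_compounds <- function(results, disease) {
  sub <- results[results$disease == disease & results$flag == "", , drop = FALSE]
  if (nrow(sub) == 0L)
    stop_sigrev("no scoreable rows for this disease", "sigrev_input_error")
  agg <- stats::aggregate(score ~ compound, data = sub, FUN = mean)
  agg$percentile <- vapply(agg$score, percentile_rank,
                           numeric(1), library_scores = agg$score)
  agg[order(agg$score, agg$compound), , drop = FALSE]
}
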