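#' Expression matrix with group labels
#'
#' Thin validated container: a numeric genes x samples matrix with unique
#' dimnames and a treated/control label per sample. Values are raw counts
#' unless `counts = FALSE`, in which case they are taken as already on log
#' scale and used as-is by [differential_signature()].
#'
#' @param values numeric matrix, rows = genes, columns = samples, with
#'   dimnames set.
#' @param groups character vector, one of "treated"/"control" per sample.
#' @param counts logical; TRUE for non-negative count data.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups, counts = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_sigrev("values must be a numeric matrix", "sigrev_input_error")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop_sigrev("gene identifiers must be present and unique", "sigrev_input_error")
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop_sigrev("sample identifiers must be unique", "sigrev_input_error")
  if (length(groups) != ncol(values))
    stop_sigrev("one group label per sample is required", "sigrev_input_error")
  if (!all(groups %in% c("treated", "control")))
    stop_sigrev("group labels must be 'treated' or 'control'", "sigrev_input_error")
  if (counts && any(values < 0))
    stop_sigrev("count matrices must be non-negative", "sigrev_input_error")
  structure(list(values = values,
                 groups = stats::setNames(as.character(groups), colnames(values)),
                 counts = counts),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s; %d treated / %d control)\n",
              nrow(x$values), ncol(x$values),
              if (x$counts) "counts" else "log scale",
              sum(x$groups == "treated"), sum(x$groups == "control")))
  invisible(x)
}

log_cpm <- function(m, pseudocount) {
  libsize <- colSums(m)
  if (any(libsize == 0))
    stop_sigrev("sample with zero library size", "sigrev_input_error")
  log2(sweep(m, 2, libsize, "/") * 1e6 + pseudocount)
}

#' Moderated-t differential signature between two arms
#'
#' Counts are normalised to counts-per-million and log2-transformed with a
#' pseudocount; each gene's pooled two-sample variance is shrunk toward the
#' across-gene mean variance with prior weight `prior_df`, and a two-sided
#' p-value is taken from the t distribution on `prior_df + residual df`
#' degrees of freedom. q-values are Benjamini-Hochberg over all genes.
#'
#' With a single sample in either arm only the log2 fold-change is defined;
#' `stat`, `p` and `q` are returned as `NA` and the result is flagged.
#'
#' @param treated,control [expression_matrix()] objects over the identical
#'   gene universe (same identifiers; order may differ).
#' @param pseudocount added to CPM before log2 (default 0.5).
#' @param prior_df prior degrees of freedom of the variance shrinkage
#'   (default 10).
#' @return a `differential_signature`: data.frame with columns
#'   gene, log2fc, stat, p, q (one row per gene, gene order of `treated`).
#' @export
differential_signature <- function(treated, control,
                                   pseudocount = 0.5, prior_df = 10) {
  stopifnot(inherits(treated, "expression_matrix"),
            inherits(control, "expression_matrix"))
  g1 <- rownames(treated$values); g2 <- rownames(control$values)
  if (!setequal(g1, g2) || length(g1) != length(g2))
    stop_sigrev("treated and control gene universes differ", "sigrev_alignment_error")
  ctl_vals <- control$values[g1, , drop = FALSE]
  x <- if (treated$counts) log_cpm(treated$values, pseudocount) else treated$values
  y <- if (control$counts) log_cpm(ctl_vals, pseudocount) else ctl_vals
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  log2fc <- unname(m1 - m2)
  if (n1 < 2L || n2 < 2L) {
    out <- data.frame(gene = g1, log2fc = log2fc,
                      stat = NA_real_, p = NA_real_, q = NA_real_,
                      stringsAsFactors = FALSE)
    attr(out, "tests_available") <- FALSE
    class(out) <- c("differential_signature", "data.frame")
    return(out)
  }
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  df_res <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df_res
  s2_prior <- mean(s2)
  s2_mod <- (prior_df * s2_prior + df_res * s2) / (prior_df + df_res)
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  stat <- ifelse(se == 0, ifelse(log2fc == 0, 0, sign(log2fc) * Inf), log2fc / se)
  p <- 2 * stats::pt(-abs(stat), df = prior_df + df_res)
  out <- data.frame(gene = g1, log2fc = log2fc, stat = unname(stat),
                    p = unname(p), q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "tests_available") <- TRUE
  class(out) <- c("differential_signature", "data.frame")
  out
}

#' Up/down tag sets from a signature
#'
#' Size mode (`n_top`): the `n_top` genes with the largest statistic form
#' the up tags, the `n_top` smallest the down tags. Cutoff mode
#' (`q_cutoff`): genes with q below the cutoff, split by the sign of the
#' log2 fold-change. Exactly one mode must be given; the two sets are
#' disjoint by construction, and an empty side in cutoff mode is an error
#' so the caller can decide a fallback.
#'
#' @param sig a `differential_signature` with statistics available.
#' @param n_top tag-set size (size mode); at most half the universe.
#' @param q_cutoff FDR cutoff (cutoff mode).
#' @param origin optional identifier recorded on the pair.
#' @return a `gene_set_pair`: list with `up`, `down`, `origin`.
#' @export
signature_gene_sets <- function(sig, n_top = NULL, q_cutoff = NULL, origin = NULL) {
  stopifnot(inherits(sig, "differential_signature"))
  if (is.null(n_top) == is.null(q_cutoff))
    stop_sigrev("give exactly one of n_top or q_cutoff", "sigrev_config_error")
  if (!isTRUE(attr(sig, "tests_available")) || anyNA(sig$stat))
    stop_sigrev("signature lacks test statistics", "sigrev_input_error")
  ord <- order(-sig$stat, sig$gene)
  if (!is.null(n_top)) {
    n_top <- as.integer(n_top)
    if (n_top < 1L || n_top > floor(nrow(sig) / 2))
      stop_sigrev("n_top must be in [1, n_genes/2]", "sigrev_config_error")
    up <- sig$gene[ord[seq_len(n_top)]]
    down <- sig$gene[rev(ord)[seq_len(n_top)]]
  } else {
    hit <- !is.na(sig$q) & sig$q < q_cutoff
    up <- sig$gene[hit & sig$log2fc > 0]
    down <- sig$gene[hit & sig$log2fc < 0]
    if (length(up) == 0L || length(down) == 0L)
      stop_sigrev("q cutoff leaves an empty tag set", "sigrev_empty_tagset_error")
  }
  structure(list(up = up, down = down, origin = origin), class = "gene_set_pair")
}

#' Ranked gene list from a signature
#'
#' Genes sorted by the moderated statistic, most up-regulated first; ties
#' are broken by ascending gene identifier so the ordering is reproducible
#' across platforms.
#'
#' @param sig a `differential_signature`.
#' @return a `ranked_list`: data.frame with columns gene, stat in rank order.
#' @export
ranked_list <- function(sig) {
  stopifnot(inherits(sig, "differential_signature"))
  key <- if (isTRUE(attr(sig, "tests_available")) && !anyNA(sig$stat)) sig$stat else sig$log2fc
  ord <- order(-key, sig$gene)
  structure(data.frame(gene = sig$gene[ord], stat = key[ord],
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("ranked_list", "data.frame"))
}
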