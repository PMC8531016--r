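#' Gene-set library with a declared background universe
#'
#' @param sets named list of character vectors (term -> gene set), e.g.
#'   transcription factor -> targets or kinase -> substrates.
#' @param background character vector of the background gene universe.
#' @return an object of class `gene_set_library`.
#' @export
gene_set_library <- function(sets, background) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_sigrev("library terms must be uniquely named", "sigrev_input_error")
  background <- unique(as.character(background))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L))
    stop_sigrev("every term's gene set must be non-empty", "sigrev_input_error")
  outside <- !vapply(sets, function(s) all(s %in% background), logical(1))
  if (any(outside))
    stop_sigrev(sprintf("term(s) %s contain genes outside the background",
                        paste(names(sets)[outside], collapse = ", ")),
                "sigrev_input_error")
  structure(list(sets = sets, background = background), class = "gene_set_library")
}

#' Overrepresentation enrichment of a query gene set in a library
#'
#' One-sided hypergeometric (Fisher) test per term: the p-value is the
#' upper tail probability of drawing at least the observed overlap when
#' `query_size` genes are sampled from the background. Query genes outside
#' the background are dropped with a warning. Results are BH-adjusted
#' across terms and sorted by ascending p, ties by descending odds ratio
#' then term identifier.
#'
#' @param query character vector of gene identifiers (e.g. a DEG list).
#' @param library a [gene_set_library()].
#' @return data.frame with columns term, overlap, term_size, query_size,
#'   background_size, odds_ratio, p, q.
#' @export
fisher_enrichment <- function(query, library) {
  stopifnot(inherits(library, "gene_set_library"))
  query <- unique(as.character(query))
  inside <- query %in% library$background
  if (!all(inside)) {
    warning(sprintf("%d query gene(s) outside the background were dropped",
                    sum(!inside)))
    query <- query[inside]
  }
  if (length(query) == 0L)
    stop_sigrev("query is empty after background intersection", "sigrev_input_error")
  N <- length(library$background)
  nq <- length(query)
  rows <- lapply(names(library$sets), function(term) {
    set <- library$sets[[term]]
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, nq, lower.tail = FALSE)
    a <- k; b <- nq - k; cc <- K - k; d <- N - K - nq + k
    or <- if (b == 0L || cc == 0L) Inf else (a * d) / (b * cc)
    data.frame(term = term, overlap = k, term_size = K, query_size = nq,
               background_size = N, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, -out$odds_ratio, out$term), , drop = FALSE]
}

#' Undirected interaction network from an edge list
#'
#' Self-loops and duplicate edges are removed (with a warning when any are
#' dropped).
#'
#' @param edges two-column data.frame or matrix of gene identifiers.
#' @return an undirected simple `igraph` graph.
#' @export
interaction_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop_sigrev("edge list needs two columns", "sigrev_input_error")
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::ecount(gs) < igraph::ecount(g))
    warning("self-loops and/or duplicate edges were removed")
  gs
}

#' Expand seed regulators through an interaction network
#'
#' Returns the subnetwork induced by every node lying on a simple path of
#' length at most `max_path_length` between two distinct seed nodes, plus
#' the seeds themselves. Seeds absent from the network are reported via the
#' `missing_seeds` attribute (not fatal); seed pairs with no connecting
#' path within the bound simply contribute nothing, so the expansion may be
#' edgeless. The result is independent of edge-list and seed ordering.
#'
#' @param seed_terms character vector of seed node identifiers (e.g.
#'   enriched transcription factors).
#' @param network an [interaction_network()] (igraph) object.
#' @param max_path_length maximum path length in edges (default 2).
#' @return an igraph subnetwork with attributes `missing_seeds` and
#'   `seeds_used`; nodes sorted by identifier.
#' @export
expand_network <- function(seed_terms, network, max_path_length = 2L) {
  seed_terms <- unique(as.character(seed_terms))
  vnames <- igraph::V(network)$name
  missing <- setdiff(seed_terms, vnames)
  seeds <- sort(intersect(seed_terms, vnames))
  nodes <- character(0)
  if (length(seeds) >= 2L) {
    for (i in seq_len(length(seeds) - 1L)) {
      paths <- igraph::all_simple_paths(network, from = seeds[i],
                                        to = seeds[(i + 1L):length(seeds)],
                                        cutoff = max_path_length)
      nodes <- union(nodes, unlist(lapply(paths, function(p) igraph::V(network)$name[p])))
    }
  }
  nodes <- sort(union(nodes, seeds))
  sub <- igraph::induced_subgraph(network, vids = nodes)
  sub <- igraph::permute(sub, rank(igraph::V(sub)$name))
  attr(sub, "missing_seeds") <- missing
  attr(sub, "seeds_used") <- seeds
  sub
}

#' Kinase enrichment of an expanded subnetwork
#'
#' Identical contract to [fisher_enrichment()], with the subnetwork's node
#' set as the query against a kinase -> substrates library.
#'
#' @param subnetwork an igraph object (from [expand_network()]) or a
#'   character vector of node identifiers.
#' @param kinase_library a [gene_set_library()].
#' @return ranked enrichment data.frame as in [fisher_enrichment()].
#' @export
kinase_enrichment <- function(subnetwork, kinase_library) {
  nodes <- if (inherits(subnetwork, "igraph")) igraph::V(subnetwork)$name
           else as.character(subnetwork)
  if (length(nodes) == 0L)
    stop_sigrev("empty subnetwork", "sigrev_input_error")
  fisher_enrichment(nodes, kinase_library)
}
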