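# Independent brute-force oracles used across the suite. These deliberately
# re-derive each statistic with plain loops, separate from the package's
# vectorised implementations.

# Benjamini-Hochberg step-up, literal definition.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Signed KS tag statistic as a running walk over the whole list.
ks_walk_oracle <- function(hits) {
  n <- length(hits); t <- sum(hits)
  j <- 0; a <- -Inf; b <- -Inf
  for (i in seq_len(n)) {
    if (hits[i]) {
      b <- max(b, i / n - j / t)
      j <- j + 1
      a <- max(a, j / t - i / n)
    }
  }
  if (a >= b) a else -b
}

# Unweighted GSEA running sum, sequential accumulation.
gsea_walk_oracle <- function(hits) {
  n <- length(hits); t <- sum(hits)
  s <- 0; mx <- 0; mn <- 0
  path <- numeric(n)
  for (i in seq_len(n)) {
    s <- s + if (hits[i]) 1 / t else -1 / (n - t)
    path[i] <- s
  }
  mx <- max(path); mn <- min(path)
  if (mx >= -mn) mx else mn
}

# Upper-tail hypergeometric by explicit enumeration over overlap outcomes.
hyper_enum_oracle <- function(k, K, N, nq) {
  ks <- seq(k, min(K, nq))
  sum(choose(K, ks) * choose(N - K, nq - ks)) / choose(N, nq)
}

# All nodes on simple paths of length <= cutoff between two seeds, by DFS.
path_nodes_oracle <- function(adj, seeds, cutoff) {
  nodes <- character(0)
  dfs <- function(current, target, visited) {
    if (length(visited) - 1L > cutoff) return()
    if (current == target && length(visited) > 1L) {
      nodes <<- union(nodes, visited)
      return()
    }
    if (length(visited) - 1L == cutoff) return()
    for (nb in adj[[current]]) {
      if (!(nb %in% visited)) dfs(nb, target, c(visited, nb))
    }
  }
  if (length(seeds) >= 2L) {
    pairs <- utils::combn(seeds, 2)
    for (p in seq_len(ncol(pairs))) {
      if (pairs[1, p] %in% names(adj) && pairs[2, p] %in% names(adj))
        dfs(pairs[1, p], pairs[2, p], pairs[1, p])
    }
  }
  sort(union(nodes, intersect(seeds, names(adj))))
}

adjacency_from_edges <- function(edges) {
  nodes <- sort(unique(c(edges[[1]], edges[[2]])))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[[1]][i]; b <- edges[[2]][i]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# Build a ranked_list directly from an ordered stat vector (rank order as given).
make_ranked <- function(stats, genes = sprintf("g%03d", seq_along(stats))) {
  structure(data.frame(gene = genes, stat = stats, stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

make_pair <- function(up, down, origin = "toy") {
  structure(list(up = up, down = down, origin = origin), class = "gene_set_pair")
}

small_config <- function(seed = 11, ...) {
  synthetic_config(n_genes = 500, n_effect_genes = 60, n_compounds = 5,
                   n_diseases = 3, seed = seed, ...)
}
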