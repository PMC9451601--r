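# Independent oracles and small generators used across the suite.
# These deliberately share no code with the package implementations.

# Brute-force Benjamini-Hochberg step-up: sort ascending, q_i = p_i * m / i,
# cumulative minimum from the largest rank down, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in rev(seq_len(m - 1L))) q[i] <- min(q[i], q[i + 1L])
  pmin(q, 1)[order(ord)]
}

# Build an snp_graph from an explicit edge list through the public API:
# every requested edge gets a qualifying LD measurement.
graph_from_edges <- function(node_ids, edges, chrom = "1") {
  snps <- tibble::tibble(variant_id = node_ids, chrom = chrom)
  if (nrow(edges) == 0L) {
    ld <- tibble::tibble(snp_a = character(), snp_b = character(),
                         dprime = double(), pval = double())
  } else {
    ld <- tibble::tibble(snp_a = edges[[1]], snp_b = edges[[2]],
                         dprime = 0.95, pval = 1e-6)
  }
  build_snp_graph(snps, ld)
}

random_snp_graph <- function(n, p_edge) {
  ids <- sprintf("s%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p_edge
  graph_from_edges(ids, as.data.frame(pairs[keep, , drop = FALSE]))
}

adjacency_oracle <- function(graph, members) {
  adj <- matrix(FALSE, length(members), length(members),
                dimnames = list(members, members))
  e <- graph$edges
  e <- e[e$snp_a %in% members & e$snp_b %in% members, , drop = FALSE]
  adj[cbind(e$snp_a, e$snp_b)] <- TRUE
  adj[cbind(e$snp_b, e$snp_a)] <- TRUE
  adj
}

subset_density <- function(adj, members) {
  k <- length(members)
  sub <- adj[members, members, drop = FALSE]
  sum(sub) / (k * (k - 1))
}

# Exhaustive quasi-clique oracle: enumerate every vertex subset of size >=
# min_size with combn, keep those meeting the density threshold, then retain
# the inclusion-maximal sets.
dense_oracle <- function(graph, members, delta, min_size) {
  members <- sort(members)
  adj <- adjacency_oracle(graph, members)
  qualifying <- list()
  for (k in seq(min_size, length(members))) {
    sets <- combn(members, k, simplify = FALSE)
    ok <- vapply(sets, function(s) subset_density(adj, s) >= delta,
                 logical(1))
    qualifying <- c(qualifying, sets[ok])
  }
  if (length(qualifying) == 0L) return(list())
  # maximality: walk sets from largest to smallest; a set is maximal iff it
  # is not contained in an already-retained (necessarily larger) set
  qualifying <- qualifying[order(-lengths(qualifying))]
  res <- list()
  for (s in qualifying) {
    contained <- any(vapply(res, function(k) all(s %in% k), logical(1)))
    if (!contained) res[[length(res) + 1L]] <- s
  }
  ord <- order(-lengths(res), vapply(res, `[`, character(1), 1L))
  res[ord]
}

# Canonical form for comparing lists of vertex sets.
setlist_key <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = "|"),
              character(1)))
}

write_gwas_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}
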