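#' Build the SNP-SNP linkage-disequilibrium graph
#'
#' Nodes are the shared significant SNPs; an undirected edge joins two SNPs
#' when their measured LD satisfies `dprime > dprime_threshold` (strict) and
#' the chi-squared test `pval < p_threshold` (strict). LD is only defined
#' within a chromosome, so pairs whose endpoints sit on different
#' chromosomes, reference unknown SNPs, or are self-pairs are rejected with
#' a warning.
#'
#' @param snps Tibble with columns `variant_id` and `chrom`.
#' @param ld_pairs Tibble with columns `snp_a`, `snp_b`, `dprime`, `pval`
#'   (optionally `r2`, `chrom`).
#' @param dprime_threshold D' threshold, edge requires strictly greater
#'   (default 0.7).
#' @param p_threshold LD test p-value threshold, edge requires strictly
#'   smaller (default 1e-4).
#' @return An object of class `snp_graph`: list with tibbles `nodes`
#'   (`variant_id`, `chrom`) and `edges` (`snp_a`, `snp_b`, `dprime`, `r2`,
#'   `pval`; pairs normalized so `snp_a < snp_b`).
#' @export
build_snp_graph <- function(snps, ld_pairs, dprime_threshold = 0.7,
                            p_threshold = 1e-4) {
  assert_fraction(dprime_threshold, "dprime_threshold")
  assert_fraction(p_threshold, "p_threshold")
  assert_columns(snps, c("variant_id", "chrom"), "SNP table")
  assert_columns(ld_pairs, c("snp_a", "snp_b", "dprime", "pval"), "LD table")

  nodes <- snps |>
    distinct(.data$variant_id, .data$chrom) |>
    arrange(.data$variant_id)
  if (anyDuplicated(nodes$variant_id)) {
    stop_validation("SNP `%s` listed with more than one chromosome",
                    nodes$variant_id[anyDuplicated(nodes$variant_id)])
  }
  chrom_of <- setNames(nodes$chrom, nodes$variant_id)

  lp <- as_tibble(ld_pairs)
  if (!("r2" %in% names(lp))) lp$r2 <- NA_real_
  known <- lp$snp_a %in% nodes$variant_id & lp$snp_b %in% nodes$variant_id
  if (any(!known)) {
    warn(sprintf("build_snp_graph: rejected %d LD pair(s) referencing unknown SNP ids",
                 sum(!known)))
    lp <- lp[known, , drop = FALSE]
  }
  selfp <- lp$snp_a == lp$snp_b
  if (any(selfp)) {
    warn(sprintf("build_snp_graph: rejected %d self-pair(s)", sum(selfp)))
    lp <- lp[!selfp, , drop = FALSE]
  }
  cross <- chrom_of[lp$snp_a] != chrom_of[lp$snp_b]
  if (any(cross)) {
    warn(sprintf("build_snp_graph: rejected %d LD pair(s) spanning two chromosomes",
                 sum(cross)))
    lp <- lp[!cross, , drop = FALSE]
  }

  keep <- lp$dprime > dprime_threshold & lp$pval < p_threshold
  edges <- lp[keep, c("snp_a", "snp_b", "dprime", "r2", "pval"), drop = FALSE]
  # normalize unordered pairs and deduplicate
  flip <- edges$snp_a > edges$snp_b
  tmp <- edges$snp_a[flip]
  edges$snp_a[flip] <- edges$snp_b[flip]
  edges$snp_b[flip] <- tmp
  edges <- edges |>
    arrange(.data$snp_a, .data$snp_b) |>
    distinct(.data$snp_a, .data$snp_b, .keep_all = TRUE)

  structure(
    list(nodes = nodes, edges = as_tibble(edges),
         dprime_threshold = dprime_threshold, p_threshold = p_threshold),
    class = "snp_graph"
  )
}

#' @export
print.snp_graph <- function(x, ...) {
  cat(sprintf("<snp_graph> %d nodes, %d edges (D' > %g, p < %g)\n",
              nrow(x$nodes), nrow(x$edges), x$dprime_threshold,
              x$p_threshold))
  invisible(x)
}

as_igraph_snp <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("snp_a", "snp_b")],
    directed = FALSE,
    vertices = graph$nodes[, c("variant_id", "chrom")]
  )
}

#' Connected components of the SNP graph
#'
#' Includes isolated SNPs as singleton components. Components are ordered by
#' descending size, ties broken by the lexicographically smallest member.
#'
#' @param graph An `snp_graph`.
#' @return List of character vectors (sorted member ids).
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "snp_graph"))
  if (nrow(graph$nodes) == 0L) return(list())
  comp <- igraph::components(as_igraph_snp(graph))
  comps <- split(names(comp$membership), comp$membership)
  comps <- lapply(comps, sort_ids)
  ord <- order(-lengths(comps), map_chr(comps, 1L), method = "radix")
  unname(comps[ord])
}

# ---- dense (quasi-clique) subgraph enumeration ------------------------------

adjacency_of <- function(graph, members) {
  adj <- matrix(FALSE, length(members), length(members),
                dimnames = list(members, members))
  e <- graph$edges
  keep <- e$snp_a %in% members & e$snp_b %in% members
  e <- e[keep, , drop = FALSE]
  adj[cbind(e$snp_a, e$snp_b)] <- TRUE
  adj[cbind(e$snp_b, e$snp_a)] <- TRUE
  adj
}

popcount_vec <- function(x) {
  cnt <- integer(length(x))
  while (any(x > 0L)) {
    cnt <- cnt + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  cnt
}

# Exhaustive search over all vertex subsets via bitmasks (n <= 24 hard cap;
# intended for n <= 15). Returns qualifying inclusion-maximal masks.
dense_subsets_exhaustive <- function(adj, density_threshold, min_size) {
  n <- nrow(adj)
  members <- rownames(adj)
  masks <- 0:(2L^n - 1L)
  size <- popcount_vec(masks)
  adj_mask <- vapply(seq_len(n), function(v) {
    sum(bitwShiftL(1L, which(adj[v, ]) - 1L))
  }, integer(1))
  ecount <- integer(length(masks))
  for (v in seq_len(n)) {
    bit_v <- bitwShiftL(1L, v - 1L)
    inm <- bitwAnd(masks, bit_v) > 0L
    ecount[inm] <- ecount[inm] + popcount_vec(bitwAnd(masks[inm], adj_mask[v]))
  }
  ecount <- ecount %/% 2L
  dens <- ifelse(size >= 2L, 2 * ecount / (size * (size - 1)), 1)
  qual <- masks[size >= min_size & dens >= density_threshold]
  if (length(qual) == 0L) return(list())
  # keep inclusion-maximal qualifying masks, largest first
  qual <- qual[order(-size[match(qual, masks)])]
  kept <- integer(0)
  for (m in qual) {
    if (!any(bitwAnd(m, kept) == m)) kept <- c(kept, m)
  }
  lapply(kept, function(m) members[bitwAnd(bitwShiftR(m, seq_len(n) - 1L), 1L) == 1L])
}

# Greedy expansion for larger components. One seed per vertex (the vertex
# plus its highest-degree neighbor, ties broken lexicographically); each
# seed repeatedly absorbs the neighboring vertex that maximizes the
# resulting edge density while the density constraint holds. Deterministic
# and O(n^3) per component, and unlike maximal-clique seeding it cannot
# blow up combinatorially on near-complete blocks.
dense_subsets_greedy <- function(adj, density_threshold, min_size) {
  n <- nrow(adj)
  members <- rownames(adj)
  deg <- rowSums(adj)

  grow_from <- function(v) {
    nbrs <- which(adj[v, ])
    if (length(nbrs) == 0L) return(NULL)
    u <- nbrs[order(-deg[nbrs], members[nbrs], method = "radix")][1L]
    current <- rep(FALSE, n)
    current[c(v, u)] <- TRUE
    e <- 1L
    repeat {
      k <- sum(current)
      links <- colSums(adj[current, , drop = FALSE])
      cand <- which(!current & links > 0L)
      if (length(cand) == 0L) break
      new_dens <- (e + links[cand]) / (k * (k + 1) / 2)
      ok <- new_dens >= density_threshold
      if (!any(ok)) break
      pick <- cand[ok][order(-new_dens[ok], members[cand[ok]],
                             method = "radix")][1L]
      e <- e + as.integer(links[pick])
      current[pick] <- TRUE
    }
    sort_ids(members[current])
  }

  grown <- lapply(seq_len(n), grow_from)
  grown <- unique(grown[!vapply(grown, is.null, logical(1))])
  grown <- grown[lengths(grown) >= min_size]
  if (length(grown) == 0L) return(list())
  # drop non-maximal results
  ord <- order(-lengths(grown), map_chr(grown, 1L), method = "radix")
  grown <- grown[ord]
  kept <- list()
  for (s in grown) {
    if (!any(vapply(kept, function(k) all(s %in% k), logical(1)))) {
      kept <- c(kept, list(s))
    }
  }
  kept
}

#' Enumerate dense subgraphs (quasi-cliques) of one component
#'
#' A vertex set S qualifies when its induced edge density
#' `2|E(S)| / (|S| (|S|-1))` is at least `density_threshold` and
#' `|S| >= min_size`. Returned sets are inclusion-maximal among qualifying
#' sets and may overlap. For components of at most `exhaustive_limit`
#' vertices the search is exhaustive over all subsets; above that, each
#' vertex (paired with its highest-degree neighbor) seeds a greedy
#' expansion that repeatedly adds the neighbor maximizing the resulting
#' density while the density constraint holds (deterministic tie-break:
#' lexicographically smallest id), followed by de-duplication to maximal
#' sets.
#'
#' @param graph An `snp_graph`.
#' @param members Character vector: the component's vertex ids.
#' @param density_threshold Minimum induced edge density in (0, 1].
#' @param min_size Minimum vertex count (>= 2).
#' @param method `"auto"` (default: exhaustive up to `exhaustive_limit`),
#'   `"exhaustive"`, or `"greedy"`.
#' @param exhaustive_limit Largest component size searched exhaustively
#'   (default 15).
#' @return List of sorted character vectors, ordered by descending size then
#'   lexicographic smallest member.
#' @export
enumerate_dense_subgraphs <- function(graph, members, density_threshold,
                                      min_size,
                                      method = c("auto", "exhaustive", "greedy"),
                                      exhaustive_limit = 15L) {
  method <- match.arg(method)
  if (density_threshold <= 0 || density_threshold > 1) {
    stop_config("`density_threshold` must be in (0, 1]")
  }
  min_size <- assert_count(min_size, "min_size", min = 2L)
  members <- sort_ids(members)
  if (length(members) < min_size) return(list())
  adj <- adjacency_of(graph, members)
  use_exhaustive <- switch(method,
    exhaustive = TRUE,
    greedy = FALSE,
    auto = length(members) <= exhaustive_limit
  )
  res <- if (use_exhaustive) {
    if (length(members) > 24L) {
      stop_config("exhaustive search capped at 24 vertices; use method = \"greedy\"")
    }
    dense_subsets_exhaustive(adj, density_threshold, min_size)
  } else {
    dense_subsets_greedy(adj, density_threshold, min_size)
  }
  res <- lapply(res, sort_ids)
  ord <- order(-lengths(res), map_chr(res, function(s) s[1L]), method = "radix")
  res[ord]
}

signature_labels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(n)]
}

min_size_for <- function(comp_size, min_fraction, rounding) {
  raw <- min_fraction * comp_size
  k <- switch(rounding,
    ceil = ceiling(raw),
    floor = floor(raw),
    round = round(raw)
  )
  max(2L, as.integer(k))
}

#' Extract dense-subgraph signatures from the SNP graph
#'
#' For each connected component, qualifying dense subgraphs containing at
#' least `min_fraction` of the component's nodes are enumerated; each
#' becomes a labelled signature (A, B, C, ... across components in
#' deterministic order). A SNP may belong to several signatures. Singleton
#' components can never form signatures.
#'
#' @param graph An `snp_graph`.
#' @param min_fraction Minimum fraction of the component a signature must
#'   contain (default 0.2).
#' @param density_threshold Quasi-clique density threshold (default 0.8).
#' @param rounding How `min_fraction * |component|` is converted to a
#'   minimum size: `"ceil"` (default), `"floor"`, or `"round"`.
#' @param ... Passed to [enumerate_dense_subgraphs()] (e.g. `method`,
#'   `exhaustive_limit`).
#' @return Tibble with columns `signature_id`, `component_id`, `size`,
#'   `density`, and list-column `members`.
#' @export
extract_signatures <- function(graph, min_fraction = 0.2,
                               density_threshold = 0.8,
                               rounding = c("ceil", "floor", "round"), ...) {
  assert_fraction(min_fraction, "min_fraction")
  rounding <- match.arg(rounding)
  comps <- connected_components(graph)
  rows <- list()
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    if (length(comp) < 2L) next
    min_size <- min_size_for(length(comp), min_fraction, rounding)
    subs <- enumerate_dense_subgraphs(graph, comp, density_threshold,
                                      min_size, ...)
    adj <- if (length(subs) > 0L) adjacency_of(graph, comp) else NULL
    for (s in subs) {
      rows[[length(rows) + 1L]] <- tibble(
        component_id = ci,
        size = length(s),
        density = edge_density_of(adj, s),
        members = list(s)
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble(signature_id = character(), component_id = integer(),
                  size = integer(), density = double(), members = list()))
  }
  out <- bind_rows(rows)
  out <- out[order(out$component_id, -out$size,
                   map_chr(out$members, 1L), method = "radix"), ]
  out <- mutate(out, signature_id = signature_labels(n()), .before = 1L)
  out
}

#' SNPs of a component participating in no signature
#'
#' @param component Character vector of a component's member ids.
#' @param signatures Signature tibble from [extract_signatures()] (or a
#'   list of member vectors).
#' @return Sorted character vector of unassigned ids.
#' @export
unassigned_snps <- function(component, signatures) {
  member_sets <- if (is.data.frame(signatures)) signatures$members else signatures
  covered <- unique(unlist(member_sets))
  sort_ids(setdiff(component, covered))
}

#' Export the SNP graph as GraphML and edge-list TSV
#'
#' Node attributes carry the chromosome and the semicolon-joined signature
#' labels. Output is byte-stable for identical inputs (nodes and edges are
#' written in sorted order).
#'
#' @param graph An `snp_graph`.
#' @param signatures Signature tibble from [extract_signatures()].
#' @param path Output path prefix; writes `<path>.graphml` and
#'   `<path>_edges.tsv`.
#' @return Invisibly, the two file paths.
#' @export
export_snp_graph <- function(graph, signatures, path) {
  stopifnot(inherits(graph, "snp_graph"))
  labels <- rep("", nrow(graph$nodes))
  names(labels) <- graph$nodes$variant_id
  if (nrow(signatures) > 0L) {
    for (i in seq_len(nrow(signatures))) {
      m <- signatures$members[[i]]
      labels[m] <- ifelse(labels[m] == "", signatures$signature_id[i],
                          paste(labels[m], signatures$signature_id[i],
                                sep = ";"))
    }
  }
  g <- as_igraph_snp(graph)
  igraph::V(g)$signatures <- unname(labels[igraph::V(g)$name])
  graphml_path <- paste0(path, ".graphml")
  edges_path <- paste0(path, "_edges.tsv")
  igraph::write_graph(g, graphml_path, format = "graphml")
  readr::write_tsv(graph$edges, edges_path)
  invisible(c(graphml = graphml_path, edges = edges_path))
}

#' @rdname tripnet-methods
#' @exportS3Method ggplot2::autoplot
autoplot.snp_graph <- function(object, signatures = NULL, seed = 1L, ...) {
  g <- as_igraph_snp(object)
  set.seed(seed)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(
    variant_id = igraph::V(g)$name,
    chrom = igraph::V(g)$chrom,
    x = lay[, 1], y = lay[, 2]
  )
  idx <- setNames(seq_len(nrow(nodes)), nodes$variant_id)
  e <- object$edges
  seg <- tibble(
    x = nodes$x[idx[e$snp_a]], y = nodes$y[idx[e$snp_a]],
    xend = nodes$x[idx[e$snp_b]], yend = nodes$y[idx[e$snp_b]]
  )
  if (!is.null(signatures) && nrow(signatures) > 0L) {
    first_sig <- rep(NA_character_, nrow(nodes))
    names(first_sig) <- nodes$variant_id
    for (i in rev(seq_len(nrow(signatures)))) {
      first_sig[signatures$members[[i]]] <- signatures$signature_id[i]
    }
    nodes$signature <- unname(first_sig[nodes$variant_id])
  } else {
    nodes$signature <- nodes$chrom
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$signature), size = 2) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = if (is.null(signatures)) "chrom" else "signature")
}
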