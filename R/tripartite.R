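#' Assemble the protein-miRNA-lncRNA tripartite network
#'
#' The first layer is the protein set from gene mapping, the second the
#' tie-extended top-degree miRNAs, the third the tie-extended top-degree
#' lncRNAs. Edges must have passed [validate_edges()]. All selected nodes
#' are retained even when one of their layers contributes no validated
#' edge (a miRNA keeps its protein partners, and hence its score, even if
#' every lncRNA edge was removed). Edges referencing unselected nodes are
#' dropped with a warning; edge sets are deduplicated.
#'
#' @param pm_edges Tibble with columns `protein`, `mirna` (validated
#'   protein-miRNA edges).
#' @param ml_edges Tibble with columns `mirna`, `lncrna` (validated
#'   miRNA-lncRNA edges).
#' @param proteins,mirnas,lncrnas Character vectors of the selected nodes.
#' @return Object of class `tripartite_network`.
#' @export
assemble_tripartite <- function(pm_edges, ml_edges, proteins, mirnas,
                                lncrnas) {
  assert_columns(pm_edges, c("protein", "mirna"), "protein-miRNA edges")
  assert_columns(ml_edges, c("mirna", "lncrna"), "miRNA-lncRNA edges")
  proteins <- sort_ids(proteins)
  mirnas <- sort_ids(mirnas)
  lncrnas <- sort_ids(lncrnas)
  if (length(proteins) == 0L) stop_validation("protein layer is empty")

  pm <- distinct(pm_edges, .data$protein, .data$mirna)
  bad_pm <- !(pm$protein %in% proteins & pm$mirna %in% mirnas)
  if (any(bad_pm)) {
    warn(sprintf("assemble_tripartite: dropped %d protein-miRNA edge(s) referencing unselected nodes",
                 sum(bad_pm)))
    pm <- pm[!bad_pm, , drop = FALSE]
  }
  ml <- distinct(ml_edges, .data$mirna, .data$lncrna)
  bad_ml <- !(ml$mirna %in% mirnas & ml$lncrna %in% lncrnas)
  if (any(bad_ml)) {
    warn(sprintf("assemble_tripartite: dropped %d miRNA-lncRNA edge(s) referencing unselected nodes",
                 sum(bad_ml)))
    ml <- ml[!bad_ml, , drop = FALSE]
  }
  structure(
    list(proteins = proteins, mirnas = mirnas, lncrnas = lncrnas,
         pm_edges = arrange(pm, .data$protein, .data$mirna),
         ml_edges = arrange(ml, .data$mirna, .data$lncrna)),
    class = "tripartite_network"
  )
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat(sprintf("<tripartite_network> %d proteins | %d miRNAs (%d edges) | %d lncRNAs (%d edges)\n",
              length(x$proteins), length(x$mirnas), nrow(x$pm_edges),
              length(x$lncrnas), nrow(x$ml_edges)))
  invisible(x)
}

# Exact rational miRNA score numerators: every score is k / N_P with
# integer k, so the common denominator N_P keeps all arithmetic exact.
mirna_numerators <- function(network) {
  deg <- table(factor(network$pm_edges$mirna, levels = network$mirnas))
  setNames(as.integer(deg), network$mirnas)
}

#' Degree-normalized miRNA score
#'
#' The score of a miRNA is the number of proteins it regulates in the final
#' tripartite network divided by the total number of proteins N_P, so it
#' lies in \[0, 1\]. Computed exactly as an integer numerator over N_P.
#'
#' @param network A `tripartite_network`.
#' @param m miRNA id (must belong to the network's miRNA layer).
#' @return Numeric score; attributes `numerator` and `denominator` carry
#'   the exact fraction.
#' @export
score_mirna <- function(network, m) {
  if (!(m %in% network$mirnas)) {
    stop_validation("miRNA `%s` is not in the tripartite network", m)
  }
  num <- mirna_numerators(network)[[m]]
  den <- length(network$proteins)
  structure(num / den, numerator = num, denominator = den)
}

#' Additive lncRNA score
#'
#' The score of a lncRNA is the sum of the scores of the miRNAs it
#' regulates in the final network; with miRNA scores k_i / N_P this is
#' (sum k_i) / N_P, kept exact.
#'
#' @param network A `tripartite_network`.
#' @param l lncRNA id (must belong to the network's lncRNA layer).
#' @return Numeric score with `numerator`/`denominator` attributes.
#' @export
score_lncrna <- function(network, l) {
  if (!(l %in% network$lncrnas)) {
    stop_validation("lncRNA `%s` is not in the tripartite network", l)
  }
  nums <- mirna_numerators(network)
  partners <- network$ml_edges$mirna[network$ml_edges$lncrna == l]
  num <- sum(nums[partners])
  den <- length(network$proteins)
  structure(num / den, numerator = num, denominator = den)
}

#' Score, rank and flag every ncRNA in the tripartite network
#'
#' Computes the degree-normalized score for every miRNA and the additive
#' score for every lncRNA, sorts each kind by descending score (ties by
#' id), and flags entities whose score is strictly greater than the
#' arithmetic mean of their kind (`above_average`) and, for miRNAs,
#' strictly greater than 1/2 (`above_half`). All comparisons are made on
#' the exact integer numerators (common denominator N_P), so flags are
#' tolerance-free.
#'
#' @param network A `tripartite_network`.
#' @return Tibble of class `tripnet_scores` with columns `entity`, `kind`,
#'   `neighbor_count`, `score_num`, `score_den`, `score`, `above_average`,
#'   `above_half`.
#' @export
rank_and_flag <- function(network) {
  den <- length(network$proteins)
  nums <- mirna_numerators(network)
  m_tbl <- tibble(
    entity = network$mirnas,
    kind = "miRNA",
    neighbor_count = unname(nums),
    score_num = unname(nums)
  )
  ml_deg <- table(factor(network$ml_edges$lncrna, levels = network$lncrnas))
  l_num <- vapply(network$lncrnas, function(l) {
    sum(nums[network$ml_edges$mirna[network$ml_edges$lncrna == l]])
  }, integer(1))
  l_tbl <- tibble(
    entity = network$lncrnas,
    kind = "lncRNA",
    neighbor_count = as.integer(ml_deg),
    score_num = as.integer(l_num)
  )
  out <- bind_rows(m_tbl, l_tbl) |>
    mutate(score_den = den, score = .data$score_num / den)
  # strict above-mean on exact numerators: num_i * n_kind > sum(num)
  out <- out |>
    group_by(.data$kind) |>
    mutate(above_average = .data$score_num * n() > sum(.data$score_num)) |>
    ungroup() |>
    mutate(above_half = dplyr::if_else(.data$kind == "miRNA",
                                       2L * .data$score_num > den, NA))
  out <- out[order(match(out$kind, c("miRNA", "lncRNA")), -out$score_num,
                   out$entity, method = "radix"), ]
  class(out) <- c("tripnet_scores", class(out))
  out
}

#' @rdname tripnet-methods
#' @exportS3Method generics::tidy
tidy.tripartite_network <- function(x, ...) {
  out <- rank_and_flag(x)
  class(out) <- setdiff(class(out), "tripnet_scores")
  out
}

#' Broom-style accessors and plots for tripnet objects
#'
#' `tidy()` on a `tripartite_network` returns the ranked score table;
#' `glance()` returns a one-row summary of layer and edge counts.
#' `autoplot()` draws the score distribution (scores object), the SNP
#' graph coloured by signature (`snp_graph`), or a layered layout of the
#' tripartite network.
#'
#' @param x,object A tripnet object.
#' @param signatures Optional signature tibble (snp_graph plot).
#' @param seed Layout seed (snp_graph plot).
#' @param ... Unused.
#' @name tripnet-methods
#' @aliases autoplot-tripnet
#' @return A tibble (`tidy`, `glance`) or a ggplot object (`autoplot`).
NULL

#' @rdname tripnet-methods
#' @exportS3Method generics::glance
glance.tripartite_network <- function(x, ...) {
  tibble(
    n_proteins = length(x$proteins),
    n_mirnas = length(x$mirnas),
    n_lncrnas = length(x$lncrnas),
    pm_edge_count = nrow(x$pm_edges),
    ml_edge_count = nrow(x$ml_edges)
  )
}

#' @rdname tripnet-methods
#' @exportS3Method ggplot2::autoplot
autoplot.tripnet_scores <- function(object, ...) {
  df <- as_tibble(object)
  df$entity <- factor(df$entity, levels = rev(df$entity))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$entity,
                                   fill = .data$above_average)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::labs(x = "score", y = NULL, fill = "above mean") +
    ggplot2::theme_minimal()
}

#' @rdname tripnet-methods
#' @exportS3Method ggplot2::autoplot
autoplot.tripartite_network <- function(object, ...) {
  layer_df <- function(ids, layer, xpos) {
    tibble(id = ids, layer = layer, x = xpos,
           y = seq(0, 1, length.out = max(length(ids), 2L))[seq_along(ids)])
  }
  nodes <- bind_rows(
    layer_df(object$proteins, "protein", 0),
    layer_df(object$mirnas, "miRNA", 1),
    layer_df(object$lncrnas, "lncRNA", 2)
  )
  pos <- function(ids) match(ids, nodes$id)
  seg <- bind_rows(
    tibble(x = nodes$x[pos(object$pm_edges$protein)],
           y = nodes$y[pos(object$pm_edges$protein)],
           xend = nodes$x[pos(object$pm_edges$mirna)],
           yend = nodes$y[pos(object$pm_edges$mirna)]),
    tibble(x = nodes$x[pos(object$ml_edges$mirna)],
           y = nodes$y[pos(object$ml_edges$mirna)],
           xend = nodes$x[pos(object$ml_edges$lncrna)],
           yend = nodes$y[pos(object$ml_edges$lncrna)])
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "grey75", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$layer), size = 2.5) +
    ggplot2::scale_x_continuous(breaks = 0:2,
                                labels = c("proteins", "miRNAs",
                                           "lncRNAs")) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, colour = "layer") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Export scoring results
#'
#' Writes the score table as TSV (with the exact fraction and a 4-decimal
#' rendering), the tripartite network as GraphML with a `layer` node
#' attribute, and a JSON run summary with per-layer node and edge counts.
#'
#' @param table Score tibble from [rank_and_flag()].
#' @param network The scored `tripartite_network`.
#' @param path Output path prefix; writes `<path>_scores.tsv`,
#'   `<path>.graphml`, `<path>_summary.json`.
#' @return Invisibly, the written paths.
#' @export
export_results <- function(table, network, path) {
  scores_path <- paste0(path, "_scores.tsv")
  graphml_path <- paste0(path, ".graphml")
  json_path <- paste0(path, "_summary.json")

  out <- as_tibble(table) |>
    mutate(score_fraction = paste0(.data$score_num, "/", .data$score_den),
           score_decimal = sprintf("%.4f", .data$score)) |>
    select("entity", "kind", "neighbor_count", "score_fraction",
           "score_decimal", "above_average", "above_half")
  readr::write_tsv(out, scores_path)

  nodes <- tibble(
    id = c(network$proteins, network$mirnas, network$lncrnas),
    layer = rep(c("protein", "miRNA", "lncRNA"),
                c(length(network$proteins), length(network$mirnas),
                  length(network$lncrnas)))
  )
  edges <- bind_rows(
    tibble(from = network$pm_edges$protein, to = network$pm_edges$mirna),
    tibble(from = network$ml_edges$mirna, to = network$ml_edges$lncrna)
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, graphml_path, format = "graphml")

  summary <- c(as.list(glance(network)),
               list(n_mirnas_above_half =
                      sum(table$above_half %in% TRUE),
                    n_above_average = sum(table$above_average)))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(scores = scores_path, graphml = graphml_path,
              summary = json_path))
}
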