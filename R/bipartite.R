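#' Canonicalize miRNA names
#'
#' Interaction tables mix `miR-199a-5p` and `hsa-miR-199a-5p` spellings;
#' names are matched case-insensitively with the `hsa-` prefix optional on
#' input and canonicalized with the prefix on output.
#'
#' @param x Character vector of miRNA names.
#' @return Canonical names (`hsa-` prefixed, `miR` capitalization).
#' @export
#' @examples
#' canonical_mirna(c("miR-199a-5p", "HSA-MIR-423-5p"))
canonical_mirna <- function(x) {
  x <- as.character(x)
  bare <- sub("^hsa-", "", x, ignore.case = TRUE)
  bare <- sub("^mir", "miR", bare, ignore.case = TRUE)
  bare <- sub("^miR-?", "miR-", bare)
  paste0("hsa-", bare)
}

#' Read an interaction table
#'
#' TSV with columns `regulator`, `target`, `layer`, `evidence` (database
#' codes, comma-joined). For the `protein_mirna` layer the regulator is a
#' miRNA and the target a protein; for `mirna_lncrna` the regulator is a
#' lncRNA and the target a miRNA.
#'
#' @param path TSV path.
#' @return Tibble of interaction records with `evidence` as a list-column
#'   of character code sets.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop_config("interaction file not found: %s", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  assert_columns(raw, c("regulator", "target", "layer", "evidence"),
                 "interaction table")
  raw |>
    mutate(evidence = map(strsplit(.data$evidence, ","), trimws)) |>
    as_tibble()
}

#' Build a bipartite regulatory network
#'
#' Left nodes are fixed by `left_ids` (proteins, or the selected miRNAs);
#' right nodes are the regulators appearing against at least one left node
#' (miRNAs, or lncRNAs). Records of other layers, or targeting unknown left
#' nodes, are skipped with a warning. Duplicate (regulator, target) pairs
#' collapse to a single edge.
#'
#' @param records Interaction tibble (columns `regulator`, `target`,
#'   `layer`).
#' @param left_ids Character vector fixing the left node set.
#' @param layer `"protein_mirna"` or `"mirna_lncrna"`.
#' @return Object of class `bipartite_network`: list with `left_nodes`,
#'   `right_nodes` (sorted character vectors) and `edges` tibble
#'   (`left`, `right`).
#' @export
build_bipartite <- function(records, left_ids,
                            layer = c("protein_mirna", "mirna_lncrna")) {
  layer <- match.arg(layer)
  assert_columns(records, c("regulator", "target", "layer"),
                 "interaction table")
  rec <- records[records$layer == layer, , drop = FALSE]
  left_ids <- sort_ids(left_ids)
  unknown <- !(rec$target %in% left_ids)
  if (any(unknown)) {
    warn(sprintf("build_bipartite: skipped %d record(s) targeting unknown left node(s)",
                 sum(unknown)))
    rec <- rec[!unknown, , drop = FALSE]
  }
  edges <- rec |>
    mutate(left = .data$target, right = .data$regulator) |>
    distinct(.data$left, .data$right) |>
    arrange(.data$left, .data$right)
  structure(
    list(left_nodes = left_ids, right_nodes = sort_ids(edges$right),
         edges = edges, layer = layer),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network:%s> %d left x %d right nodes, %d edges\n",
              x$layer, length(x$left_nodes), length(x$right_nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Node degrees on one side of a bipartite network
#'
#' @param network A `bipartite_network`.
#' @param side `"left"` or `"right"`.
#' @return Tibble with columns `node` and `degree` (zero-degree nodes
#'   included), ordered by descending degree then node id.
#' @export
degree_table <- function(network, side = c("left", "right")) {
  side <- match.arg(side)
  nodes <- if (side == "left") network$left_nodes else network$right_nodes
  col <- if (side == "left") network$edges$left else network$edges$right
  deg <- table(factor(col, levels = nodes))
  out <- tibble(node = nodes, degree = as.integer(deg))
  out[order(-out$degree, out$node, method = "radix"), ]
}

#' Top-degree nodes with tie extension
#'
#' Selects every node whose degree is at least the k-th largest degree
#' value, so ties at the cutoff are all included and more than `k` nodes
#' may be returned (the rule that turns a top-10 request into 15 miRNAs or
#' 11 lncRNAs when degrees tie).
#'
#' @param degrees Tibble from [degree_table()] (`node`, `degree`).
#' @param k Number of top nodes requested (default 10).
#' @return Tibble of the selected rows, ordered by descending degree then
#'   node id.
#' @export
top_degree_with_ties <- function(degrees, k = 10L) {
  k <- assert_count(k, "k", min = 1L)
  assert_columns(degrees, c("node", "degree"), "degree table")
  if (nrow(degrees) == 0L) return(degrees)
  if (nrow(degrees) < k) {
    warn(sprintf("top_degree_with_ties: only %d node(s) available for k = %d",
                 nrow(degrees), k))
    k <- nrow(degrees)
  }
  cutoff <- sort(degrees$degree, decreasing = TRUE)[k]
  out <- degrees[degrees$degree >= cutoff, , drop = FALSE]
  out[order(-out$degree, out$node, method = "radix"), ]
}

#' Default evidence-code vocabulary per layer
#'
#' Protein-miRNA records originate from starBase (`a`) and are corroborated
#' by miRWalk (`b`), TargetScan (`c`), miRanda-via-starBase (`d`), miRmap
#' (`e`) or microT (`f`); miRNA-lncRNA records originate from starBase
#' (`S`) and are corroborated by LncBase (`L`).
#'
#' @return Named list with `primary` code and `validation` code set per
#'   layer.
#' @export
evidence_codes <- function() {
  list(
    protein_mirna = list(primary = "a",
                         validation = c("b", "c", "d", "e", "f")),
    mirna_lncrna = list(primary = "S", validation = "L")
  )
}

#' Validate interaction edges by multi-database consensus
#'
#' Keeps a record only when its evidence set contains at least `min_extra`
#' of the validation codes, i.e. the interaction is corroborated by at
#' least one database beyond its originating (primary) source. Every input
#' record must carry the primary code; a record lacking it indicates an
#' inconsistent source table and raises a validation error.
#'
#' @param records Interaction tibble with an `evidence` list-column.
#' @param primary_code Originating database code (all records must carry
#'   it).
#' @param validation_codes Character vector of corroborating codes.
#' @param min_extra Minimum number of corroborating codes required
#'   (default 1).
#' @return The kept records (subset of the input, order preserved).
#' @export
validate_edges <- function(records, primary_code, validation_codes,
                           min_extra = 1L) {
  min_extra <- assert_count(min_extra, "min_extra", min = 1L)
  assert_columns(records, "evidence", "interaction table")
  has_primary <- vapply(records$evidence,
                        function(ev) primary_code %in% ev, logical(1))
  if (!all(has_primary)) {
    stop_validation("record %d lacks the primary evidence code `%s`",
                    which(!has_primary)[1L], primary_code)
  }
  n_extra <- map_int(records$evidence,
                     function(ev) length(intersect(ev, validation_codes)))
  records[n_extra >= min_extra, , drop = FALSE]
}

#' Restrict a bipartite network to selected right-side nodes
#'
#' @param network A `bipartite_network`.
#' @param keep_right Character vector, subset of `right_nodes`.
#' @return The restricted `bipartite_network` (left side unchanged).
#' @export
induced_subnetwork <- function(network, keep_right) {
  keep_right <- sort_ids(keep_right)
  extra <- setdiff(keep_right, network$right_nodes)
  if (length(extra) > 0L) {
    stop_validation("keep_right contains unknown node(s): %s",
                    paste(head(extra, 3L), collapse = ", "))
  }
  network$right_nodes <- keep_right
  network$edges <- network$edges[network$edges$right %in% keep_right, ,
                                 drop = FALSE]
  network
}
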