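#' Pipeline configuration
#'
#' Collects every input path and tunable threshold of the pipeline. The
#' defaults are the analysis' stated thresholds: MAF 0.001, adjusted-p
#' 0.05, D' 0.7 with LD p 1e-4, signatures covering at least 20% of their
#' component at density 0.8, genes with at least 3 SNPs, top-10 hub
#' selection with tie extension.
#'
#' @param gwas_a,gwas_b Character vectors of per-trait GWAS TSV paths.
#' @param ld_pairs LD pair TSV path.
#' @param annotation SNP-to-gene annotation TSV path.
#' @param interactions_pm,interactions_ml Interaction TSV paths.
#' @param gene_disease Optional gene-disease TSV path.
#' @param output_dir Directory for stage artifacts.
#' @param maf_threshold,alpha,combine_policy,pooled_fdr GWAS-stage
#'   parameters.
#' @param dprime_threshold,ld_p_threshold LD edge rule.
#' @param min_fraction,density_threshold,min_size_rounding Signature
#'   extraction parameters.
#' @param min_snps_per_gene Gene filter.
#' @param top_k Hub selection size before tie extension.
#' @param column_map GWAS column mapping ([gwas_column_map()]).
#' @param evidence Evidence-code vocabulary ([evidence_codes()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(gwas_a, gwas_b, ld_pairs, annotation,
                            interactions_pm, interactions_ml,
                            gene_disease = NULL,
                            output_dir = tempfile("tripnet_run_"),
                            maf_threshold = 0.001, alpha = 0.05,
                            combine_policy = "union", pooled_fdr = FALSE,
                            dprime_threshold = 0.7, ld_p_threshold = 1e-4,
                            min_fraction = 0.2, density_threshold = 0.8,
                            min_size_rounding = "ceil",
                            min_snps_per_gene = 3L, top_k = 10L,
                            column_map = gwas_column_map(),
                            evidence = evidence_codes()) {
  assert_fraction(alpha, "alpha")
  assert_fraction(dprime_threshold, "dprime_threshold")
  assert_fraction(ld_p_threshold, "ld_p_threshold")
  assert_fraction(min_fraction, "min_fraction")
  assert_fraction(density_threshold, "density_threshold")
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_stages <- c("gwas_select", "ld_graph", "signatures", "map_genes",
                     "networks", "validate", "score")

stage_dir <- function(config, stage) {
  d <- file.path(config$output_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

artifact_path <- function(config, stage, file, producer = stage) {
  path <- file.path(config$output_dir, stage, file)
  if (!file.exists(path)) {
    stop_dependency("missing artifact `%s`: run stage \"%s\" first",
                    path, producer)
  }
  path
}

write_manifest <- function(config, stage, inputs, outputs, params, counts) {
  hash_by_name <- function(paths) {
    paths <- paths[file.exists(paths)]
    h <- tools::md5sum(paths)
    as.list(setNames(unname(h), basename(paths)))
  }
  manifest <- list(
    stage = stage,
    parameters = params,
    inputs = hash_by_name(inputs),
    outputs = hash_by_name(outputs),
    counts = counts
  )
  jsonlite::write_json(manifest,
                       file.path(stage_dir(config, stage), "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Each stage reads its inputs (raw input tables or upstream artifacts),
#' writes its outputs plus a `manifest.json` (parameters, MD5 hashes of
#' inputs and outputs, record counts) under
#' `<output_dir>/<stage>/`, and returns its main artifact invisibly.
#' Reruns on identical inputs are byte-identical. Stages:
#' `gwas_select`, `ld_graph`, `signatures`, `map_genes`, `networks`,
#' `validate`, `score`.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @return The stage's main result, invisibly.
#' @export
run_stage <- function(stage = pipeline_stages, config) {
  stage <- match.arg(stage)
  switch(stage,
    gwas_select = stage_gwas_select(config),
    ld_graph = stage_ld_graph(config),
    signatures = stage_signatures(config),
    map_genes = stage_map_genes(config),
    networks = stage_networks(config),
    validate = stage_validate(config),
    score = stage_score(config)
  )
}

stage_gwas_select <- function(config) {
  read_many <- function(paths) lapply(paths, read_gwas_table,
                                      column_map = config$column_map)
  tabs_a <- read_many(config$gwas_a)
  tabs_b <- read_many(config$gwas_b)
  if (all(vapply(tabs_a, nrow, integer(1)) == 0L)) {
    stop_validation("trait A GWAS input is empty")
  }
  ids_a <- combine_trait_files(tabs_a, alpha = config$alpha,
                               maf_threshold = config$maf_threshold,
                               policy = config$combine_policy,
                               pooled_fdr = config$pooled_fdr)
  ids_b <- combine_trait_files(tabs_b, alpha = config$alpha,
                               maf_threshold = config$maf_threshold,
                               policy = config$combine_policy,
                               pooled_fdr = config$pooled_fdr)
  shared <- intersect_traits(ids_a, ids_b)
  all_a <- bind_rows(tabs_a)
  shared_tbl <- tibble(variant_id = shared) |>
    left_join(distinct(all_a, .data$variant_id, .data$chrom),
              by = "variant_id")
  d <- stage_dir(config, "gwas_select")
  out_shared <- file.path(d, "shared_snps.tsv")
  readr::write_tsv(shared_tbl, out_shared)
  readr::write_tsv(tibble(variant_id = ids_a), file.path(d, "sig_a.tsv"))
  readr::write_tsv(tibble(variant_id = ids_b), file.path(d, "sig_b.tsv"))
  write_manifest(config, "gwas_select",
                 inputs = c(config$gwas_a, config$gwas_b),
                 outputs = c(out_shared, file.path(d, c("sig_a.tsv", "sig_b.tsv"))),
                 params = list(maf_threshold = config$maf_threshold,
                               alpha = config$alpha,
                               combine_policy = config$combine_policy,
                               pooled_fdr = config$pooled_fdr),
                 counts = list(n_sig_a = length(ids_a),
                               n_sig_b = length(ids_b),
                               n_shared = length(shared)))
  invisible(shared_tbl)
}

read_ld_pairs <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    snp_a = "c", snp_b = "c", chrom = "c", dprime = "d", r2 = "d",
    pval = "d"
  ), progress = FALSE)
}

stage_ld_graph <- function(config) {
  shared <- readr::read_tsv(
    artifact_path(config, "gwas_select", "shared_snps.tsv"),
    col_types = "cc", progress = FALSE)
  ld <- read_ld_pairs(config$ld_pairs)
  graph <- build_snp_graph(shared, ld,
                           dprime_threshold = config$dprime_threshold,
                           p_threshold = config$ld_p_threshold)
  d <- stage_dir(config, "ld_graph")
  out_edges <- file.path(d, "graph_edges.tsv")
  out_nodes <- file.path(d, "graph_nodes.tsv")
  readr::write_tsv(graph$edges, out_edges)
  readr::write_tsv(graph$nodes, out_nodes)
  write_manifest(config, "ld_graph",
                 inputs = config$ld_pairs,
                 outputs = c(out_edges, out_nodes),
                 params = list(dprime_threshold = config$dprime_threshold,
                               ld_p_threshold = config$ld_p_threshold),
                 counts = list(n_nodes = nrow(graph$nodes),
                               n_edges = nrow(graph$edges)))
  invisible(graph)
}

load_graph <- function(config) {
  nodes <- readr::read_tsv(
    artifact_path(config, "ld_graph", "graph_nodes.tsv"),
    col_types = "cc", progress = FALSE)
  edges <- readr::read_tsv(
    artifact_path(config, "ld_graph", "graph_edges.tsv"),
    col_types = "ccddd", progress = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 dprime_threshold = config$dprime_threshold,
                 p_threshold = config$ld_p_threshold),
            class = "snp_graph")
}

stage_signatures <- function(config) {
  graph <- load_graph(config)
  sigs <- extract_signatures(graph, min_fraction = config$min_fraction,
                             density_threshold = config$density_threshold,
                             rounding = config$min_size_rounding)
  d <- stage_dir(config, "signatures")
  out <- file.path(d, "signatures.tsv")
  flat <- sigs |>
    mutate(members = map_chr(.data$members, paste, collapse = ";"))
  readr::write_tsv(flat, out)
  export_snp_graph(graph, sigs, file.path(d, "snp_graph"))
  write_manifest(config, "signatures",
                 inputs = file.path(config$output_dir, "ld_graph",
                                    c("graph_nodes.tsv", "graph_edges.tsv")),
                 outputs = out,
                 params = list(min_fraction = config$min_fraction,
                               density_threshold = config$density_threshold,
                               rounding = config$min_size_rounding),
                 counts = list(n_signatures = nrow(sigs)))
  invisible(sigs)
}

load_signatures <- function(config) {
  flat <- readr::read_tsv(
    artifact_path(config, "signatures", "signatures.tsv"),
    col_types = "ciidc", progress = FALSE)
  flat$members <- strsplit(flat$members, ";", fixed = TRUE)
  flat
}

stage_map_genes <- function(config) {
  sigs <- load_signatures(config)
  ann <- readr::read_tsv(config$annotation,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  gene_map <- map_signatures_to_genes(sigs, ann) |>
    filter_genes_min_snps(min_snps = config$min_snps_per_gene)
  summaries <- summarize_genes(gene_map, ann)
  proteins <- select_protein_set(summaries)
  d <- stage_dir(config, "map_genes")
  out_sum <- file.path(d, "gene_summary.tsv")
  out_prot <- file.path(d, "proteins.tsv")
  readr::write_tsv(summaries, out_sum)
  readr::write_tsv(tibble(gene_symbol = proteins), out_prot)
  if (!is.null(config$gene_disease)) {
    report <- disease_association_report(proteins,
      readr::read_tsv(config$gene_disease, col_types = "cci",
                      progress = FALSE))
    readr::write_tsv(report, file.path(d, "gene_disease_report.tsv"))
  }
  write_manifest(config, "map_genes",
                 inputs = c(config$annotation,
                            file.path(config$output_dir, "signatures",
                                      "signatures.tsv")),
                 outputs = c(out_sum, out_prot),
                 params = list(min_snps_per_gene = config$min_snps_per_gene),
                 counts = list(n_genes = nrow(summaries),
                               n_proteins = length(proteins)))
  invisible(summaries)
}

stage_networks <- function(config) {
  proteins <- readr::read_tsv(
    artifact_path(config, "map_genes", "proteins.tsv"),
    col_types = "c", progress = FALSE)$gene_symbol
  pm <- read_interactions(config$interactions_pm)
  pm$regulator <- canonical_mirna(pm$regulator)
  ml <- read_interactions(config$interactions_ml)
  ml$target <- canonical_mirna(ml$target)

  pm_net <- build_bipartite(pm, proteins, layer = "protein_mirna")
  top_m <- top_degree_with_ties(degree_table(pm_net, "right"),
                                k = config$top_k)
  ml_net <- build_bipartite(ml, top_m$node, layer = "mirna_lncrna")
  top_l <- top_degree_with_ties(degree_table(ml_net, "right"),
                                k = config$top_k)
  d <- stage_dir(config, "networks")
  readr::write_tsv(pm_net$edges, file.path(d, "pm_edges.tsv"))
  readr::write_tsv(ml_net$edges, file.path(d, "ml_edges.tsv"))
  readr::write_tsv(top_m, file.path(d, "selected_mirnas.tsv"))
  readr::write_tsv(top_l, file.path(d, "selected_lncrnas.tsv"))
  write_manifest(config, "networks",
                 inputs = c(config$interactions_pm, config$interactions_ml),
                 outputs = file.path(d, c("pm_edges.tsv", "ml_edges.tsv",
                                          "selected_mirnas.tsv",
                                          "selected_lncrnas.tsv")),
                 params = list(top_k = config$top_k,
                               tie_rule = "degree >= k-th largest degree"),
                 counts = list(n_mirnas_selected = nrow(top_m),
                               n_lncrnas_selected = nrow(top_l)))
  invisible(list(pm_net = pm_net, ml_net = ml_net,
                 selected_mirnas = top_m$node,
                 selected_lncrnas = top_l$node))
}

stage_validate <- function(config) {
  sel_m <- readr::read_tsv(
    artifact_path(config, "networks", "selected_mirnas.tsv"),
    col_types = "ci", progress = FALSE)$node
  sel_l <- readr::read_tsv(
    artifact_path(config, "networks", "selected_lncrnas.tsv"),
    col_types = "ci", progress = FALSE)$node
  proteins <- readr::read_tsv(
    artifact_path(config, "map_genes", "proteins.tsv"),
    col_types = "c", progress = FALSE)$gene_symbol

  pm <- read_interactions(config$interactions_pm)
  pm$regulator <- canonical_mirna(pm$regulator)
  pm <- pm[pm$regulator %in% sel_m & pm$target %in% proteins, ]
  ml <- read_interactions(config$interactions_ml)
  ml$target <- canonical_mirna(ml$target)
  ml <- ml[ml$target %in% sel_m & ml$regulator %in% sel_l, ]

  ev <- config$evidence
  pm_kept <- validate_edges(pm, ev$protein_mirna$primary,
                            ev$protein_mirna$validation)
  ml_kept <- validate_edges(ml, ev$mirna_lncrna$primary,
                            ev$mirna_lncrna$validation)
  d <- stage_dir(config, "validate")
  flat <- function(x) mutate(x, evidence = map_chr(.data$evidence, paste,
                                                   collapse = ","))
  readr::write_tsv(flat(pm_kept), file.path(d, "pm_validated.tsv"))
  readr::write_tsv(flat(ml_kept), file.path(d, "ml_validated.tsv"))
  write_manifest(config, "validate",
                 inputs = c(config$interactions_pm, config$interactions_ml),
                 outputs = file.path(d, c("pm_validated.tsv",
                                          "ml_validated.tsv")),
                 params = list(rule = "evidence beyond primary source >= 1"),
                 counts = list(pm_in = nrow(pm), pm_kept = nrow(pm_kept),
                               ml_in = nrow(ml), ml_kept = nrow(ml_kept)))
  invisible(list(pm_kept = pm_kept, ml_kept = ml_kept))
}

stage_score <- function(config) {
  pm <- readr::read_tsv(
    artifact_path(config, "validate", "pm_validated.tsv"),
    col_types = readr::cols(.default = "c"), progress = FALSE)
  ml <- readr::read_tsv(
    artifact_path(config, "validate", "ml_validated.tsv"),
    col_types = readr::cols(.default = "c"), progress = FALSE)
  proteins <- readr::read_tsv(
    artifact_path(config, "map_genes", "proteins.tsv"),
    col_types = "c", progress = FALSE)$gene_symbol
  sel_m <- readr::read_tsv(
    artifact_path(config, "networks", "selected_mirnas.tsv"),
    col_types = "ci", progress = FALSE)$node
  sel_l <- readr::read_tsv(
    artifact_path(config, "networks", "selected_lncrnas.tsv"),
    col_types = "ci", progress = FALSE)$node

  network <- assemble_tripartite(
    pm_edges = tibble(protein = pm$target, mirna = pm$regulator),
    ml_edges = tibble(mirna = ml$target, lncrna = ml$regulator),
    proteins = proteins, mirnas = sel_m, lncrnas = sel_l
  )
  scores <- rank_and_flag(network)
  d <- stage_dir(config, "score")
  paths <- export_results(scores, network, file.path(d, "tripartite"))
  write_manifest(config, "score",
                 inputs = file.path(config$output_dir, "validate",
                                    c("pm_validated.tsv", "ml_validated.tsv")),
                 outputs = unname(paths),
                 params = list(),
                 counts = as.list(glance(network)))
  invisible(list(network = network, scores = scores))
}

#' Run the whole pipeline
#'
#' Executes every stage in order (GWAS selection and trait intersection,
#' LD graph, signatures, gene mapping, bipartite networks and hub
#' selection, consensus validation, tripartite scoring) and writes a
#' consolidated `run_summary.json` under the output directory. Equivalent
#' to calling [run_stage()] for each stage in sequence.
#'
#' @param config A [pipeline_config()].
#' @return List with the final `network`, `scores`, and the `summary`
#'   list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (stage in head(pipeline_stages, -1L)) run_stage(stage, config)
  final <- run_stage("score", config)
  manifests <- map(pipeline_stages, function(s) {
    jsonlite::read_json(file.path(config$output_dir, s, "manifest.json"))
  })
  summary <- list(
    stages = setNames(map(manifests, "counts"), pipeline_stages),
    network = as.list(glance(final$network))
  )
  jsonlite::write_json(summary,
                       file.path(config$output_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  c(final, list(summary = summary))
}
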