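gene_classes <- c("protein_coding", "lncRNA", "pseudogene", "other")

normalize_gene_class <- function(x) {
  x <- as.character(x)
  norm <- dplyr::case_when(
    tolower(x) %in% c("protein_coding", "protein coding") ~ "protein_coding",
    tolower(x) %in% c("lncrna", "lnc_rna") ~ "lncRNA",
    grepl("pseudogene", x, ignore.case = TRUE) ~ "pseudogene",
    tolower(x) == "other" ~ "other",
    TRUE ~ NA_character_
  )
  if (anyNA(norm)) {
    warn(sprintf("unknown gene class(es) mapped to \"other\": %s",
                 paste(unique(x[is.na(norm)]), collapse = ", ")))
    norm[is.na(norm)] <- "other"
  }
  norm
}

#' Map signature SNPs to genes
#'
#' Aggregates, per gene, every signature SNP carrying an annotation row for
#' that gene, together with the set of signatures contributing at least one
#' such SNP. A SNP annotating several genes contributes to each of them.
#' Signature SNPs with no annotation are counted and reported.
#'
#' @param signatures Signature tibble from [extract_signatures()].
#' @param annotation Tibble with columns `variant_id`, `gene_symbol`,
#'   `gene_class`, `chrom` (one row per SNP-gene assignment).
#' @return Tibble with columns `gene_symbol`, `snp_count`, and list-columns
#'   `snps` and `signature_ids`.
#' @export
map_signatures_to_genes <- function(signatures, annotation) {
  assert_columns(annotation, c("variant_id", "gene_symbol"),
                 "annotation table")
  if (nrow(signatures) == 0L || nrow(annotation) == 0L) {
    if (nrow(annotation) == 0L) warn("annotation table is empty")
    return(tibble(gene_symbol = character(), snps = list(),
                  signature_ids = list(), snp_count = integer()))
  }
  ann <- distinct(annotation, .data$variant_id, .data$gene_symbol)
  long <- signatures |>
    select("signature_id", "members") |>
    tidyr::unnest_longer(col = "members", values_to = "variant_id") |>
    dplyr::inner_join(ann, by = "variant_id",
                      relationship = "many-to-many")
  sig_snps <- unique(unlist(signatures$members))
  n_unannotated <- length(setdiff(sig_snps, ann$variant_id))
  if (n_unannotated > 0L) {
    inform(sprintf("map_signatures_to_genes: %d signature SNP(s) carry no annotation",
                   n_unannotated))
  }
  long |>
    group_by(.data$gene_symbol) |>
    summarise(
      snps = list(sort_ids(.data$variant_id)),
      signature_ids = list(sort_ids(.data$signature_id)),
      .groups = "drop"
    ) |>
    mutate(snp_count = lengths(.data$snps)) |>
    arrange(.data$gene_symbol)
}

#' Keep genes supported by a minimum number of SNPs
#'
#' @param gene_map Tibble from [map_signatures_to_genes()].
#' @param min_snps Minimum SNP count, inclusive (default 3).
#' @return The filtered tibble.
#' @export
filter_genes_min_snps <- function(gene_map, min_snps = 3L) {
  min_snps <- assert_count(min_snps, "min_snps", min = 1L)
  gene_map[gene_map$snp_count >= min_snps, , drop = FALSE]
}

#' Summarize mapped genes
#'
#' One row per gene with its class, chromosome, contributing signatures and
#' SNP count, ordered by chromosome then symbol.
#'
#' @param gene_map Filtered tibble from [filter_genes_min_snps()].
#' @param annotation Annotation tibble with `gene_symbol`, `gene_class`,
#'   `chrom`.
#' @return Tibble with columns `gene_symbol`, `gene_class`, `chrom`,
#'   `signature_ids` (semicolon-joined), `snp_count`.
#' @export
summarize_genes <- function(gene_map, annotation) {
  assert_columns(annotation, c("gene_symbol", "gene_class", "chrom"),
                 "annotation table")
  if (nrow(gene_map) == 0L) {
    return(tibble(gene_symbol = character(), gene_class = character(),
                  chrom = character(), signature_ids = character(),
                  snp_count = integer()))
  }
  meta <- annotation |>
    distinct(.data$gene_symbol, .data$gene_class, .data$chrom)
  conflicted <- meta |>
    dplyr::count(.data$gene_symbol) |>
    filter(.data$n > 1L)
  if (nrow(conflicted) > 0L) {
    stop_validation("gene `%s` has conflicting class/chromosome annotations",
                    conflicted$gene_symbol[1L])
  }
  meta$gene_class <- normalize_gene_class(meta$gene_class)
  gene_map |>
    left_join(meta, by = "gene_symbol") |>
    mutate(signature_ids = map_chr(.data$signature_ids, paste,
                                   collapse = ";")) |>
    select("gene_symbol", "gene_class", "chrom", "signature_ids",
           "snp_count") |>
    arrange(.data$chrom, .data$gene_symbol)
}

#' Protein-coding genes defining the tripartite network's first layer
#'
#' @param summaries Tibble from [summarize_genes()].
#' @return Sorted character vector of protein-coding gene symbols.
#' @export
select_protein_set <- function(summaries) {
  proteins <- sort_ids(
    summaries$gene_symbol[summaries$gene_class == "protein_coding"]
  )
  if (length(proteins) == 0L) {
    stop_state("no protein-coding genes survive mapping; downstream network stages are undefined")
  }
  proteins
}

#' Gene-disease association report
#'
#' Joins the mapped genes against an ingested gene-disease association
#' table (gene symbol, disease label, supporting PubMed count). Genes with
#' no association rows appear once with `disease = "no evidence"` and
#' `n_pmids = NA`.
#'
#' @param genes Character vector of gene symbols.
#' @param records Tibble with columns `gene_symbol`, `disease`, `n_pmids`.
#' @return Tibble with one row per gene-disease pair.
#' @export
disease_association_report <- function(genes, records) {
  assert_columns(records, c("gene_symbol", "disease", "n_pmids"),
                 "gene-disease table")
  hits <- records |>
    filter(.data$gene_symbol %in% genes) |>
    mutate(n_pmids = as.integer(.data$n_pmids)) |>
    arrange(.data$gene_symbol, desc(.data$n_pmids), .data$disease)
  missing <- setdiff(genes, hits$gene_symbol)
  if (length(missing) > 0L) {
    hits <- bind_rows(hits, tibble(gene_symbol = sort_ids(missing),
                                   disease = "no evidence",
                                   n_pmids = NA_integer_))
  }
  hits
}
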