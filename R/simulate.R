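#' Configuration for the synthetic two-trait study
#'
#' Defaults emulate the study conditions of the analysed data: 127 shared
#' true signals between the two traits embedded in per-trait summary
#' statistics, four LD blocks (two per chromosome, sized like the observed
#' components, with 10 chromosome-6 satellite SNPs outside every block),
#' near-clique LD within blocks and rare qualifying LD across blocks,
#' three genes per block of which two (the protein-coding ones) carry at
#' least three SNPs, and hub-structured interaction tables whose degree
#' ties extend a top-10 request to 15 miRNAs and 11 lncRNAs.
#'
#' @param seed Integer seed; identical seed and config give identical
#'   output.
#' @param n_snps_per_trait Variants per trait file.
#' @param n_shared_true Planted shared true signals (must not exceed
#'   `n_snps_per_trait`).
#' @param signal_p_scale Upper bound for planted raw p-values; the default
#'   keeps them below `alpha / n_snps_per_trait` so Benjamini-Hochberg
#'   selection is guaranteed.
#' @param maf_low_fraction Fraction of null variants given MAF < 0.001
#'   (removed by the confidence filter).
#' @param block_sizes Integer vector of LD block sizes; the sum must not
#'   exceed `n_shared_true`, and leftover shared SNPs become satellites in
#'   no block.
#' @param block_chroms Chromosome label per block.
#' @param intra_block_edge_prob Probability an intra-block SNP pair gets a
#'   threshold-passing LD measurement.
#' @param inter_block_edge_prob Same for same-chromosome across-block
#'   pairs.
#' @param dprime_in_block,dprime_out_block Ranges (length-2) for D' of
#'   qualifying and non-qualifying pairs.
#' @param genes_per_block Genes hosted by each block.
#' @param n_mirnas,n_lncrnas Sizes of the interaction-table universes.
#' @param hub_degrees_mirna,hub_degrees_lncrna Planted hub degree
#'   multisets (defaults tie at rank 10 so tie-extended top-10 selection
#'   returns all hubs).
#' @param evidence_corroboration_prob Probability each validation-database
#'   code corroborates an edge, independently per code.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_snps_per_trait = 5000L,
                              n_shared_true = 127L,
                              signal_p_scale = 1e-8,
                              maf_low_fraction = 0.1,
                              block_sizes = c(5L, 38L, 14L, 60L),
                              block_chroms = c("19", "19", "6", "6"),
                              intra_block_edge_prob = 0.95,
                              inter_block_edge_prob = 0.02,
                              dprime_in_block = c(0.8, 1.0),
                              dprime_out_block = c(0.0, 0.6),
                              genes_per_block = 3L,
                              n_mirnas = 40L,
                              n_lncrnas = 30L,
                              hub_degrees_mirna = c(rep(6L, 4L), rep(4L, 11L)),
                              hub_degrees_lncrna = c(rep(8L, 3L), rep(5L, 8L)),
                              evidence_corroboration_prob = 0.9) {
  seed <- assert_count(seed, "seed", min = 0L)
  n_snps_per_trait <- assert_count(n_snps_per_trait, "n_snps_per_trait")
  n_shared_true <- assert_count(n_shared_true, "n_shared_true", min = 0L)
  if (n_shared_true > n_snps_per_trait) {
    stop_config("n_shared_true (%d) exceeds n_snps_per_trait (%d)",
                n_shared_true, n_snps_per_trait)
  }
  assert_fraction(maf_low_fraction, "maf_low_fraction")
  assert_fraction(intra_block_edge_prob, "intra_block_edge_prob")
  assert_fraction(inter_block_edge_prob, "inter_block_edge_prob")
  assert_fraction(evidence_corroboration_prob, "evidence_corroboration_prob")
  if (sum(block_sizes) > n_shared_true && n_shared_true > 0L) {
    stop_config("block sizes sum (%d) exceeds n_shared_true (%d)",
                sum(block_sizes), n_shared_true)
  }
  if (length(block_chroms) != length(block_sizes)) {
    stop_config("block_chroms must match block_sizes in length")
  }
  structure(as.list(environment()), class = "simulation_config")
}

# Deterministic sub-stream seeding: every generator draws from its own
# offset of the config seed so stages can be rerun independently.
with_stream <- function(config, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((config$seed * 131L + offset) %% .Machine$integer.max)
  force(code)
}

#' Generate a synthetic two-trait GWAS pair with planted shared signals
#'
#' Both traits share one variant universe. The planted shared signals get
#' raw p-values at most `signal_p_scale` in both traits; all other
#' variants draw p ~ Uniform(0, 1) independently per trait.
#' `maf_low_fraction` of the null variants receive MAF < 0.001 and are
#' removed by the confidence filter; planted signals always pass it.
#'
#' @param config A [simulation_config()].
#' @return List with tibbles `trait_a`, `trait_b`, the `planted_shared` id
#'   vector, and `block_map` (tibble `variant_id`, `chrom`, `block`;
#'   block `NA` marks satellites).
#' @export
generate_gwas_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_snps_per_trait
  k <- config$n_shared_true
  ids <- sprintf("snp%06d", seq_len(n))
  planted <- ids[seq_len(k)]

  blocks <- rep(NA_integer_, k)
  if (k > 0L && length(config$block_sizes) > 0L) {
    blocks[seq_len(sum(config$block_sizes))] <-
      rep(seq_along(config$block_sizes), config$block_sizes)
  }
  chrom_planted <- ifelse(is.na(blocks), "6", config$block_chroms[blocks])

  with_stream(config, 1L, {
    chrom_null <- sample(c("19", "6", "2", "11"), n - k, replace = TRUE)
    chrom <- c(chrom_planted, chrom_null)
    pos <- sample.int(5e7, n)
    low_maf <- c(rep(FALSE, k),
                 runif(n - k) < config$maf_low_fraction)
    maf <- ifelse(low_maf, runif(n, 0, 0.00099), runif(n, 0.01, 0.5))
    make_trait <- function() {
      p <- runif(n)
      p[seq_len(k)] <- runif(k, .Machine$double.xmin, config$signal_p_scale)
      beta <- stats::rnorm(n, 0, 0.05)
      beta[seq_len(k)] <- stats::rnorm(k, 0.4, 0.05)
      se <- runif(n, 0.01, 0.05)
      tibble(variant_id = ids, rsid = ids, chrom = chrom, pos = pos,
             maf = maf, beta = beta, se = se, pval = p)
    }
    trait_a <- make_trait()
    trait_b <- make_trait()
    list(
      trait_a = trait_a, trait_b = trait_b, planted_shared = planted,
      block_map = tibble(variant_id = planted, chrom = chrom_planted,
                         block = blocks)
    )
  })
}

#' Generate a block-structured LD pair table
#'
#' Intra-block pairs receive a qualifying measurement (D' drawn from
#' `dprime_in_block`, p < 1e-6) with probability `intra_block_edge_prob`.
#' Same-chromosome across-block pairs always fail the joint edge rule, as
#' LD blocks are by construction separated by recombination: a fraction
#' `inter_block_edge_prob` of them are decoys with inflated D' (drawn from
#' the in-block range, as happens for noisy small-sample LD estimates) but
#' a non-significant chi-squared p-value, and the rest are plain
#' low-D' pairs. Satellite SNPs only appear in non-qualifying pairs.
#'
#' @param config A [simulation_config()].
#' @param block_map Tibble from [generate_gwas_pair()] (`variant_id`,
#'   `chrom`, `block`).
#' @return List with `ld_pairs` tibble (`snp_a`, `snp_b`, `chrom`,
#'   `dprime`, `r2`, `pval`), the `block_map`, and `satellites`.
#' @export
generate_ld_blocks <- function(config, block_map) {
  stopifnot(inherits(config, "simulation_config"))
  assert_columns(block_map, c("variant_id", "chrom", "block"), "block map")
  with_stream(config, 2L, {
    qualify_pair <- function(a, b, chrom,
                             mode = c("edge", "background", "decoy")) {
      mode <- match.arg(mode)
      dr <- if (mode == "background") config$dprime_out_block else
        config$dprime_in_block
      tibble(
        snp_a = a, snp_b = b, chrom = chrom,
        dprime = runif(length(a), dr[1], dr[2]),
        r2 = runif(length(a), 0.1, 1),
        pval = if (mode == "edge") 10^-runif(length(a), 6, 12)
               else runif(length(a), 0.001, 1)
      )
    }
    out <- list()
    for (b in unique(stats::na.omit(block_map$block))) {
      mem <- block_map$variant_id[!is.na(block_map$block) &
                                    block_map$block == b]
      chrom <- block_map$chrom[match(mem[1], block_map$variant_id)]
      if (length(mem) < 2L) next
      pr <- t(combn(mem, 2L))
      q <- runif(nrow(pr)) < config$intra_block_edge_prob
      out[[length(out) + 1L]] <- qualify_pair(pr[q, 1], pr[q, 2], chrom,
                                              "edge")
      out[[length(out) + 1L]] <- qualify_pair(pr[!q, 1], pr[!q, 2], chrom,
                                              "background")
    }
    # same-chromosome across-block / satellite pairs, sparse sample
    for (ch in unique(block_map$chrom)) {
      mem <- block_map$variant_id[block_map$chrom == ch]
      blk <- block_map$block[block_map$chrom == ch]
      if (length(mem) < 2L) next
      n_cross <- min(4L * length(mem), 400L)
      ia <- sample.int(length(mem), n_cross, replace = TRUE)
      ib <- sample.int(length(mem), n_cross, replace = TRUE)
      keep <- ia != ib &
        (is.na(blk[ia]) | is.na(blk[ib]) | blk[ia] != blk[ib])
      ia <- ia[keep]; ib <- ib[keep]
      if (length(ia) == 0L) next
      q <- runif(length(ia)) < config$inter_block_edge_prob
      if (any(q)) {
        out[[length(out) + 1L]] <- qualify_pair(mem[ia[q]], mem[ib[q]],
                                                ch, "decoy")
      }
      if (any(!q)) {
        out[[length(out) + 1L]] <- qualify_pair(mem[ia[!q]], mem[ib[!q]],
                                                ch, "background")
      }
    }
    ld <- bind_rows(out)
    # normalize and deduplicate unordered pairs
    flip <- ld$snp_a > ld$snp_b
    tmp <- ld$snp_a[flip]; ld$snp_a[flip] <- ld$snp_b[flip]
    ld$snp_b[flip] <- tmp
    ld <- distinct(ld, .data$snp_a, .data$snp_b, .keep_all = TRUE) |>
      arrange(.data$snp_a, .data$snp_b)
    list(ld_pairs = ld, block_map = block_map,
         satellites = sort_ids(block_map$variant_id[is.na(block_map$block)]))
  })
}

#' Generate a SNP-to-gene annotation table over the LD blocks
#'
#' Each block hosts `genes_per_block` genes: two protein-coding genes with
#' at least three SNPs each and one lncRNA with two SNPs (removed by the
#' minimum-SNP filter). Ground truth records which genes must survive.
#'
#' @param config A [simulation_config()].
#' @param block_map Tibble (`variant_id`, `chrom`, `block`).
#' @return List with `annotation` tibble and truth vectors
#'   `genes_min3` (symbols that must survive the >= 3 SNP filter) and
#'   `protein_genes` (the protein-coding subset of those).
#' @export
generate_annotation <- function(config, block_map) {
  stopifnot(inherits(config, "simulation_config"))
  rows <- list()
  genes_min3 <- character()
  protein_genes <- character()
  for (b in unique(stats::na.omit(block_map$block))) {
    mem <- sort_ids(block_map$variant_id[!is.na(block_map$block) &
                                           block_map$block == b])
    chrom <- block_map$chrom[match(mem[1], block_map$variant_id)]
    n_genes <- min(config$genes_per_block, 3L)
    # chunk sizes: >=3, >=3, 2 (as available)
    sizes <- c(max(3L, length(mem) %/% 3L), 3L, 2L)[seq_len(n_genes)]
    start <- 1L
    for (gi in seq_len(n_genes)) {
      size <- min(sizes[gi], length(mem) - start + 1L)
      if (size <= 0L) break
      gene <- sprintf("GENE_B%d_%d", b, gi)
      class <- if (gi <= 2L) "protein_coding" else "lncRNA"
      rows[[length(rows) + 1L]] <- tibble(
        variant_id = mem[start:(start + size - 1L)],
        gene_symbol = gene, gene_class = class, chrom = chrom
      )
      if (size >= 3L) {
        genes_min3 <- c(genes_min3, gene)
        if (class == "protein_coding") {
          protein_genes <- c(protein_genes, gene)
        }
      }
      start <- start + size
    }
  }
  list(annotation = bind_rows(rows), genes_min3 = sort_ids(genes_min3),
       protein_genes = sort_ids(protein_genes))
}

random_evidence <- function(n, primary, validation, prob) {
  extra <- lapply(seq_len(n), function(i) {
    validation[runif(length(validation)) < prob]
  })
  map(extra, function(e) c(primary, e))
}

#' Generate hub-structured interaction tables with evidence codes
#'
#' Hub miRNAs receive their planted degrees against the protein set and
#' non-hub miRNAs low degrees; hub lncRNAs likewise against the hub
#' miRNAs. Each edge's evidence contains the layer's primary code plus
#' each validation code independently with probability
#' `evidence_corroboration_prob`. Ground truth includes the hub lists, the
#' planted degree multisets and the exact kept-edge row indices under the
#' consensus-validation rule.
#'
#' @param config A [simulation_config()].
#' @param proteins Character vector of protein symbols (the left layer).
#' @return List with interaction tibbles `pm_records`, `ml_records` and a
#'   `truth` list (`hub_mirnas`, `hub_lncrnas`, `pm_kept`, `ml_kept`
#'   logical vectors, degree tables).
#' @export
generate_interaction_tables <- function(config, proteins) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(proteins) == 0L) stop_config("protein list must be non-empty")
  codes <- evidence_codes()
  with_stream(config, 3L, {
    mirnas <- sprintf("hsa-miR-sim-%03d", seq_len(config$n_mirnas))
    hub_deg <- pmin(config$hub_degrees_mirna, length(proteins))
    hubs_m <- mirnas[seq_along(hub_deg)]
    deg_m <- c(hub_deg,
               sample(1:2, config$n_mirnas - length(hub_deg),
                      replace = TRUE))
    pm <- bind_rows(map(seq_along(mirnas), function(i) {
      tibble(regulator = mirnas[i],
             target = sample(proteins, deg_m[i]),
             layer = "protein_mirna")
    }))
    pm$evidence <- random_evidence(nrow(pm), codes$protein_mirna$primary,
                                   codes$protein_mirna$validation,
                                   config$evidence_corroboration_prob)

    lncrnas <- sprintf("LNC-SIM-%03d", seq_len(config$n_lncrnas))
    hub_deg_l <- pmin(config$hub_degrees_lncrna, length(hubs_m))
    hubs_l <- lncrnas[seq_along(hub_deg_l)]
    deg_l <- c(hub_deg_l,
               sample(1:2, config$n_lncrnas - length(hub_deg_l),
                      replace = TRUE))
    ml <- bind_rows(map(seq_along(lncrnas), function(i) {
      tibble(regulator = lncrnas[i],
             target = sample(hubs_m, min(deg_l[i], length(hubs_m))),
             layer = "mirna_lncrna")
    }))
    ml$evidence <- random_evidence(nrow(ml), codes$mirna_lncrna$primary,
                                   codes$mirna_lncrna$validation,
                                   config$evidence_corroboration_prob)

    truth <- list(
      hub_mirnas = sort_ids(hubs_m),
      hub_lncrnas = sort_ids(hubs_l),
      mirna_degrees = setNames(deg_m, mirnas),
      lncrna_degrees = setNames(deg_l, lncrnas),
      pm_kept = map_int(pm$evidence, function(e) {
        length(intersect(e, codes$protein_mirna$validation))
      }) >= 1L,
      ml_kept = map_int(ml$evidence, function(e) {
        length(intersect(e, codes$mirna_lncrna$validation))
      }) >= 1L
    )
    list(pm_records = pm, ml_records = ml, truth = truth)
  })
}

#' Generate and optionally write the full synthetic input bundle
#'
#' Runs every generator in sequence (GWAS pair, LD blocks, annotation,
#' interaction tables) and, when `dir` is given, writes `gwas_a.tsv`,
#' `gwas_b.tsv`, `ld_pairs.tsv`, `annotation.tsv`, `interactions_pm.tsv`,
#' `interactions_ml.tsv` and `truth.json`. Identical seed and config give
#' byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory (created if needed).
#' @return The bundle as a list (`gwas`, `ld`, `annotation`,
#'   `interactions`, and `paths` when written), invisibly when writing.
#' @export
simulate_crosstalk_inputs <- function(config = simulation_config(),
                                      dir = NULL) {
  gwas <- generate_gwas_pair(config)
  ld <- generate_ld_blocks(config, gwas$block_map)
  ann <- generate_annotation(config, gwas$block_map)
  inter <- generate_interaction_tables(config, ann$protein_genes)
  bundle <- list(gwas = gwas, ld = ld, annotation = ann,
                 interactions = inter, config = config)
  if (is.null(dir)) return(bundle)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat_evidence <- function(rec) {
    rec$evidence <- map_chr(rec$evidence, paste, collapse = ",")
    rec
  }
  paths <- c(
    gwas_a = file.path(dir, "gwas_a.tsv"),
    gwas_b = file.path(dir, "gwas_b.tsv"),
    ld_pairs = file.path(dir, "ld_pairs.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    interactions_pm = file.path(dir, "interactions_pm.tsv"),
    interactions_ml = file.path(dir, "interactions_ml.tsv"),
    truth = file.path(dir, "truth.json")
  )
  # GWAS files use the UK-Biobank-style column names the default
  # column map expects
  as_neale <- function(tbl) {
    rename(tbl, variant = "variant_id", chr = "chrom",
           minor_AF = "maf")
  }
  readr::write_tsv(as_neale(gwas$trait_a), paths[["gwas_a"]])
  readr::write_tsv(as_neale(gwas$trait_b), paths[["gwas_b"]])
  readr::write_tsv(ld$ld_pairs, paths[["ld_pairs"]])
  readr::write_tsv(ann$annotation, paths[["annotation"]])
  readr::write_tsv(flat_evidence(inter$pm_records),
                   paths[["interactions_pm"]])
  readr::write_tsv(flat_evidence(inter$ml_records),
                   paths[["interactions_ml"]])
  truth <- list(
    planted_shared = gwas$planted_shared,
    satellites = ld$satellites,
    genes_min3 = ann$genes_min3,
    protein_genes = ann$protein_genes,
    hub_mirnas = inter$truth$hub_mirnas,
    hub_lncrnas = inter$truth$hub_lncrnas,
    n_pm_kept = sum(inter$truth$pm_kept),
    n_ml_kept = sum(inter$truth$ml_kept)
  )
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE)
  bundle$paths <- paths
  invisible(bundle)
}
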