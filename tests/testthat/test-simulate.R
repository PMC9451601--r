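test_that("identical seed and config give identical bundles", {
  cfg <- simulation_config(seed = 42L, n_snps_per_trait = 500L)
  b1 <- simulate_crosstalk_inputs(cfg)
  b2 <- simulate_crosstalk_inputs(cfg)
  expect_identical(b1$gwas$trait_a, b2$gwas$trait_a)
  expect_identical(b1$ld$ld_pairs, b2$ld$ld_pairs)
  expect_identical(b1$interactions$pm_records, b2$interactions$pm_records)

  d1 <- file.path(tempdir(), "sim1")
  d2 <- file.path(tempdir(), "sim2")
  simulate_crosstalk_inputs(cfg, d1)
  simulate_crosstalk_inputs(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(n_shared_true = 10L,
                                 n_snps_per_trait = 5L),
               class = "tripnet_config_error")
  expect_error(simulation_config(block_sizes = c(100L, 100L),
                                 n_shared_true = 127L),
               class = "tripnet_config_error")
  expect_error(simulation_config(maf_low_fraction = 2),
               class = "tripnet_config_error")
})

test_that("the GWAS stage recovers exactly the planted shared signals", {
  cfg <- simulation_config(seed = 7L)
  gwas <- generate_gwas_pair(cfg)
  sig <- function(tbl) {
    select_significant(add_adjusted_pvalues(filter_low_confidence(tbl)))
  }
  shared <- intersect_traits(sig(gwas$trait_a), sig(gwas$trait_b))
  expect_identical(shared, sort(gwas$planted_shared))
})

test_that("a null simulation yields no shared discoveries", {
  cfg <- simulation_config(seed = 5L, n_snps_per_trait = 2000L,
                           n_shared_true = 0L, block_sizes = integer(0),
                           block_chroms = character(0))
  gwas <- generate_gwas_pair(cfg)
  expect_length(gwas$planted_shared, 0L)
  sig <- function(tbl) {
    select_significant(add_adjusted_pvalues(filter_low_confidence(tbl)))
  }
  expect_length(intersect_traits(sig(gwas$trait_a), sig(gwas$trait_b)), 0L)
})

test_that("BH selection on uniform nulls is calibrated on average", {
  set.seed(2024)
  n <- 200L
  counts <- vapply(1:200, function(i) {
    p <- runif(n)
    sum(adjust_pvalues_bh(p) < 0.05)
  }, numeric(1))
  expect_lte(mean(counts), 0.05 * n)
})

test_that("LD blocks become components; satellites stay unassigned", {
  cfg <- simulation_config(seed = 3L, inter_block_edge_prob = 0)
  gwas <- generate_gwas_pair(cfg)
  ld <- generate_ld_blocks(cfg, gwas$block_map)
  graph <- build_snp_graph(
    tibble::tibble(variant_id = gwas$block_map$variant_id,
                   chrom = gwas$block_map$chrom),
    ld$ld_pairs)
  comps <- connected_components(graph)
  big <- comps[lengths(comps) > 1L]
  expect_length(big, length(cfg$block_sizes))
  blocks <- split(gwas$block_map$variant_id, gwas$block_map$block)
  for (b in blocks) {
    match_one <- vapply(big, function(cmp) setequal(cmp, b), logical(1))
    expect_equal(sum(match_one), 1L)
  }
  expect_identical(ld$satellites,
                   sort(gwas$block_map$variant_id[is.na(gwas$block_map$block)]))
  # satellites participate in no signature
  sigs <- extract_signatures(graph, exhaustive_limit = 5L)
  comp4 <- comps[[1]]
  expect_true(all(!(ld$satellites %in% unlist(sigs$members))))
})

test_that("saturated blocks are cliques with density one", {
  cfg <- simulation_config(seed = 9L, n_snps_per_trait = 200L,
                           n_shared_true = 20L,
                           block_sizes = c(6L, 6L),
                           block_chroms = c("19", "6"),
                           intra_block_edge_prob = 1,
                           dprime_in_block = c(0.9, 1.0),
                           inter_block_edge_prob = 0)
  gwas <- generate_gwas_pair(cfg)
  ld <- generate_ld_blocks(cfg, gwas$block_map)
  graph <- build_snp_graph(
    tibble::tibble(variant_id = gwas$block_map$variant_id,
                   chrom = gwas$block_map$chrom),
    ld$ld_pairs)
  sigs <- extract_signatures(graph)
  blocks <- split(gwas$block_map$variant_id, gwas$block_map$block)
  expect_equal(nrow(sigs), 2L)
  expect_true(all(sigs$density == 1))
  for (b in blocks) {
    expect_true(any(vapply(sigs$members, setequal, logical(1), sort(b))))
  }
})

test_that("evidence corroboration probability drives validation extremes", {
  codes <- evidence_codes()
  cfg1 <- simulation_config(seed = 2L, n_snps_per_trait = 200L,
                            evidence_corroboration_prob = 1)
  i1 <- generate_interaction_tables(cfg1, sprintf("P%d", 1:8))
  expect_equal(nrow(validate_edges(i1$pm_records,
                                   codes$protein_mirna$primary,
                                   codes$protein_mirna$validation)),
               nrow(i1$pm_records))

  cfg0 <- simulation_config(seed = 2L, n_snps_per_trait = 200L,
                            evidence_corroboration_prob = 0)
  i0 <- generate_interaction_tables(cfg0, sprintf("P%d", 1:8))
  expect_equal(nrow(validate_edges(i0$pm_records,
                                   codes$protein_mirna$primary,
                                   codes$protein_mirna$validation)), 0L)
  expect_equal(nrow(validate_edges(i0$ml_records,
                                   codes$mirna_lncrna$primary,
                                   codes$mirna_lncrna$validation)), 0L)
})

test_that("planted hub degree ties extend top-10 selection to all hubs", {
  cfg <- simulation_config(seed = 6L, n_snps_per_trait = 200L)
  inter <- generate_interaction_tables(cfg, sprintf("P%d", 1:8))
  net <- build_bipartite(inter$pm_records, sprintf("P%d", 1:8),
                         "protein_mirna")
  sel <- top_degree_with_ties(degree_table(net, "right"), 10L)
  expect_equal(nrow(sel), 15L)
  expect_setequal(sel$node, inter$truth$hub_mirnas)

  mnet <- build_bipartite(inter$ml_records, inter$truth$hub_mirnas,
                          "mirna_lncrna")
  sel_l <- top_degree_with_ties(degree_table(mnet, "right"), 10L)
  expect_equal(nrow(sel_l), 11L)
  expect_setequal(sel_l$node, inter$truth$hub_lncrnas)
})

test_that("interaction generation demands a non-empty protein list", {
  cfg <- simulation_config(seed = 1L, n_snps_per_trait = 200L)
  expect_error(generate_interaction_tables(cfg, character(0)),
               class = "tripnet_config_error")
})
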