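chain_network <- function() {
  assemble_tripartite(
    pm_edges = tibble::tibble(protein = "P1", mirna = "m1"),
    ml_edges = tibble::tibble(mirna = "m1", lncrna = "l1"),
    proteins = "P1", mirnas = "m1", lncrnas = "l1"
  )
}

test_that("tripartite assembly keeps all selected nodes and drops strays", {
  net <- chain_network()
  expect_equal(nrow(net$pm_edges), 1L)
  expect_equal(nrow(net$ml_edges), 1L)

  iso <- assemble_tripartite(
    pm_edges = tibble::tibble(protein = "P1", mirna = "m1"),
    ml_edges = tibble::tibble(mirna = character(), lncrna = character()),
    proteins = "P1", mirnas = c("m1", "m2"), lncrnas = c("l1", "l2")
  )
  expect_equal(iso$lncrnas, c("l1", "l2"))   # isolated lncRNAs retained
  expect_equal(nrow(iso$ml_edges), 0L)

  expect_warning(
    assemble_tripartite(
      pm_edges = tibble::tibble(protein = c("P1", "P9"),
                                mirna = c("m1", "m1")),
      ml_edges = tibble::tibble(mirna = character(),
                                lncrna = character()),
      proteins = "P1", mirnas = "m1", lncrnas = "l1"),
    "unselected")
})

test_that("the published fixture reproduces every network count", {
  ft <- fixture_tripartite()
  g <- glance(ft$network)
  expect_equal(g$n_proteins, 7L)
  expect_equal(g$n_mirnas, 15L)
  expect_equal(g$n_lncrnas, 11L)
  expect_equal(g$pm_edge_count, 49L)
  expect_equal(g$ml_edge_count, 45L)
})

test_that("miRNA scores are protein counts over N_P, exactly", {
  ft <- fixture_tripartite()
  s <- score_mirna(ft$network, "hsa-miR-199a-5p")
  expect_equal(attr(s, "numerator"), 4L)
  expect_equal(attr(s, "denominator"), 7L)
  expect_equal(as.numeric(s), 4 / 7)

  net <- assemble_tripartite(
    pm_edges = tibble::tibble(protein = c("P1", "P2"),
                              mirna = c("m1", "m1")),
    ml_edges = tibble::tibble(mirna = character(), lncrna = character()),
    proteins = c("P1", "P2"), mirnas = c("m1", "m2"), lncrnas = "l1"
  )
  expect_equal(as.numeric(score_mirna(net, "m2")), 0)   # no partners
  expect_equal(as.numeric(score_mirna(net, "m1")), 1)   # all proteins
  expect_error(score_mirna(net, "m9"),
               class = "tripnet_validation_error")
})

test_that("lncRNA scores add their miRNA partners' scores", {
  ft <- fixture_tripartite()
  s <- score_lncrna(ft$network, "KCNQ1OT1")
  expect_equal(attr(s, "numerator"), 34L)
  expect_equal(as.numeric(s), 34 / 7)
  partners <- ft$network$ml_edges$mirna[
    ft$network$ml_edges$lncrna == "KCNQ1OT1"]
  expect_length(partners, 10L)
  expect_equal(as.numeric(s),
               sum(vapply(partners,
                          function(m) as.numeric(score_mirna(ft$network, m)),
                          numeric(1))))

  net <- chain_network()
  lonely <- assemble_tripartite(
    pm_edges = tibble::tibble(protein = "P1", mirna = "m1"),
    ml_edges = tibble::tibble(mirna = character(), lncrna = character()),
    proteins = "P1", mirnas = "m1", lncrnas = "l1"
  )
  expect_equal(as.numeric(score_lncrna(lonely, "l1")), 0)
})

test_that("ranking flags the published hubs and handles degenerate ties", {
  ft <- fixture_tripartite()
  s <- ft$scores
  above_half <- s$entity[s$kind == "miRNA" & s$above_half]
  expect_setequal(above_half,
                  c("hsa-miR-199a-5p", "hsa-miR-199b-5p",
                    "hsa-miR-423-5p", "hsa-miR-3184-5p"))
  lnc <- s[s$kind == "lncRNA", ]
  expect_equal(lnc$entity[1:3], c("KCNQ1OT1", "NEAT1", "XIST"))
  expect_true(all(lnc$above_average[1:3]))
  expect_false(any(lnc$above_average[-(1:3)]))

  flat <- assemble_tripartite(
    pm_edges = tibble::tibble(protein = c("P1", "P1"),
                              mirna = c("m1", "m2")),
    ml_edges = tibble::tibble(mirna = character(), lncrna = character()),
    proteins = "P1", mirnas = c("m1", "m2"), lncrnas = "l1"
  )
  fs <- rank_and_flag(flat)
  expect_false(any(fs$above_average[fs$kind == "miRNA"]))
})

test_that("score identities hold exactly in rational arithmetic", {
  check_identities <- function(net) {
    s <- rank_and_flag(net)
    m <- s[s$kind == "miRNA", ]
    # sum of miRNA numerators equals the pm edge count
    expect_identical(sum(m$score_num), nrow(net$pm_edges))
    # lncRNA total equals miRNA scores weighted by kept partners
    l <- s[s$kind == "lncRNA", ]
    partners <- table(factor(net$ml_edges$mirna, levels = net$mirnas))
    expect_identical(sum(l$score_num),
                     as.integer(sum(m$score_num[match(net$mirnas,
                                                      m$entity)] *
                                      as.integer(partners))))
  }
  check_identities(fixture_tripartite()$network)
  set.seed(77)
  for (i in 1:5) {
    cfg <- simulation_config(seed = i, n_snps_per_trait = 300L)
    inter <- generate_interaction_tables(cfg, sprintf("P%d", 1:7))
    codes <- evidence_codes()
    pmk <- validate_edges(inter$pm_records, codes$protein_mirna$primary,
                          codes$protein_mirna$validation)
    mlk <- validate_edges(inter$ml_records, codes$mirna_lncrna$primary,
                          codes$mirna_lncrna$validation)
    net <- assemble_tripartite(
      pm_edges = tibble::tibble(protein = pmk$target,
                                mirna = pmk$regulator),
      ml_edges = tibble::tibble(mirna = mlk$target,
                                lncrna = mlk$regulator),
      proteins = sprintf("P%d", 1:7),
      mirnas = unique(inter$pm_records$regulator),
      lncrnas = unique(inter$ml_records$regulator)
    )
    check_identities(net)
  }
})

test_that("removing a protein-miRNA edge never increases any score", {
  ft <- fixture_tripartite()
  net <- ft$network
  base <- rank_and_flag(net)
  set.seed(13)
  for (i in sample(nrow(net$pm_edges), 5)) {
    pruned <- net
    pruned$pm_edges <- net$pm_edges[-i, ]
    after <- rank_and_flag(pruned)
    merged <- merge(as.data.frame(base)[, c("entity", "score_num")],
                    as.data.frame(after)[, c("entity", "score_num")],
                    by = "entity")
    expect_true(all(merged$score_num.y <= merged$score_num.x))
  }
})

test_that("tidy and glance expose the fitted network broom-style", {
  ft <- fixture_tripartite()
  td <- generics::tidy(ft$network)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 26L)             # 15 miRNAs + 11 lncRNAs
  expect_named(glance(ft$network),
               c("n_proteins", "n_mirnas", "n_lncrnas", "pm_edge_count",
                 "ml_edge_count"))
  p1 <- ggplot2::autoplot(ft$scores)
  p2 <- ggplot2::autoplot(ft$network)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})

test_that("result export writes scores, GraphML and a faithful summary", {
  ft <- fixture_tripartite()
  prefix <- file.path(tempdir(), "tri_export")
  paths <- export_results(ft$scores, ft$network, prefix)
  summary <- jsonlite::read_json(paths[["summary"]])
  expect_equal(summary$pm_edge_count, 49L)
  expect_equal(summary$ml_edge_count, 45L)
  back <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(back), 7 + 15 + 11)
  expect_equal(igraph::ecount(back), 49 + 45)
  scores <- readr::read_tsv(paths[["scores"]], show_col_types = FALSE)
  expect_equal(scores$score_fraction[scores$entity == "KCNQ1OT1"],
               "34/7")
})
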