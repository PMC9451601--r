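test_that("LD edge rule is strict on both thresholds", {
  snps <- tibble::tibble(variant_id = c("s1", "s2", "s3"), chrom = "19")
  ld <- tibble::tibble(
    snp_a = c("s1", "s1"), snp_b = c("s2", "s3"),
    dprime = c(0.9, 0.7), pval = c(1e-6, 1e-6)
  )
  g <- build_snp_graph(snps, ld)
  expect_equal(nrow(g$edges), 1L)           # D' = 0.7 exactly fails (> is strict)
  expect_equal(g$edges$snp_a, "s1")
  expect_equal(g$edges$snp_b, "s2")

  g2 <- build_snp_graph(snps, dplyr::mutate(ld, pval = c(1e-4, 1e-5)))
  expect_equal(nrow(g2$edges), 0L)          # p = 1e-4 exactly fails for s1-s2
})

test_that("edge count matches a direct scan of the pair table", {
  set.seed(21)
  snps <- tibble::tibble(variant_id = sprintf("s%02d", 1:20), chrom = "6")
  pairs <- t(combn(snps$variant_id, 2))
  idx <- sample(nrow(pairs), 50)
  ld <- tibble::tibble(
    snp_a = pairs[idx, 1], snp_b = pairs[idx, 2],
    dprime = runif(50), pval = 10^-runif(50, 0, 8)
  )
  expected <- sum(ld$dprime > 0.7 & ld$pval < 1e-4)
  g <- build_snp_graph(snps, ld)
  expect_equal(nrow(g$edges), expected)
  # soundness: every retained edge satisfies the rule in the source table
  key <- paste(pmin(ld$snp_a, ld$snp_b), pmax(ld$snp_a, ld$snp_b))
  ok <- ld$dprime > 0.7 & ld$pval < 1e-4
  expect_true(all(paste(g$edges$snp_a, g$edges$snp_b) %in% key[ok]))
})

test_that("cross-chromosome, self, and unknown-id pairs are rejected", {
  snps <- tibble::tibble(variant_id = c("a", "b", "c"),
                         chrom = c("19", "19", "6"))
  ld <- tibble::tibble(snp_a = c("a", "a", "a", "zz"),
                       snp_b = c("c", "a", "b", "b"),
                       dprime = 0.9, pval = 1e-6)
  expect_warning(expect_warning(expect_warning(
    g <- build_snp_graph(snps, ld),
    "unknown"), "self-pair"), "two chromosomes")
  expect_equal(nrow(g$edges), 1L)
})

test_that("connected components partition the graph deterministically", {
  g <- graph_from_edges(
    c("a", "b", "c", "x", "y", "z"),
    data.frame(from = c("a", "b", "c", "x", "y", "z"),
               to   = c("b", "c", "a", "y", "z", "x"))
  )
  comps <- connected_components(g)
  expect_length(comps, 2L)
  expect_equal(comps[[1]], c("a", "b", "c"))  # size tie -> lexicographic
  expect_equal(comps[[2]], c("x", "y", "z"))

  iso <- graph_from_edges(letters[1:5],
                          data.frame(from = character(), to = character()))
  expect_length(connected_components(iso), 5L)
})

test_that("dense subgraphs: clique and path base cases", {
  k5 <- graph_from_edges(letters[1:5],
                         as.data.frame(t(combn(letters[1:5], 2))))
  res <- enumerate_dense_subgraphs(k5, letters[1:5], 0.9, 2L)
  expect_equal(res, list(letters[1:5]))

  path6 <- graph_from_edges(letters[1:6],
                            data.frame(from = letters[1:5],
                                       to = letters[2:6]))
  expect_equal(
    enumerate_dense_subgraphs(path6, letters[1:6], 0.9, 3L), list())
  # too-small component
  expect_equal(enumerate_dense_subgraphs(k5, c("a", "b"), 0.8, 3L), list())
})

test_that("exhaustive enumeration equals the combn oracle on random graphs", {
  set.seed(99)
  for (i in 1:12) {
    n <- sample(6:11, 1)
    g <- random_snp_graph(n, runif(1, 0.3, 0.8))
    members <- g$nodes$variant_id
    delta <- sample(c(0.6, 0.8), 1)
    got <- enumerate_dense_subgraphs(g, members, delta, 3L,
                                     method = "exhaustive")
    want <- dense_oracle(g, members, delta, 3L)
    expect_equal(setlist_key(got), setlist_key(want))
  }
})

test_that("greedy search recovers planted near-clique blocks", {
  set.seed(5)
  blocks <- list(sprintf("a%02d", 1:8), sprintf("b%02d", 1:7),
                 sprintf("c%02d", 1:6))
  nodes <- unlist(blocks)
  edges <- do.call(rbind, lapply(blocks, function(b) {
    pr <- t(combn(b, 2))
    pr[runif(nrow(pr)) < 0.95, , drop = FALSE]
  }))
  # sparse inter-block noise
  cross <- cbind(sample(blocks[[1]], 3), sample(blocks[[2]], 3))
  g <- graph_from_edges(nodes, as.data.frame(rbind(edges, cross)))
  res <- enumerate_dense_subgraphs(g, nodes, 0.8, 4L, method = "greedy")
  for (b in blocks) {
    jac <- vapply(res, function(s) {
      length(intersect(s, b)) / length(union(s, b))
    }, numeric(1))
    expect_gte(max(jac), 0.9)
  }
})

test_that("raising the density threshold only shrinks dense sets", {
  set.seed(123)
  for (i in 1:6) {
    g <- random_snp_graph(10, 0.5)
    members <- g$nodes$variant_id
    lo <- enumerate_dense_subgraphs(g, members, 0.6, 3L)
    hi <- enumerate_dense_subgraphs(g, members, 0.85, 3L)
    # every set found at the stricter threshold qualifies at the looser
    # one too, so it must sit inside one of the looser maximal sets
    for (s in hi) {
      expect_true(any(vapply(lo, function(k) all(s %in% k), logical(1))))
    }
    if (length(hi) > 0L && length(lo) > 0L) {
      expect_lte(max(lengths(hi)), max(lengths(lo)))
    }
  }
})

test_that("signatures respect per-component minimum size and density", {
  k10 <- graph_from_edges(sprintf("n%02d", 1:10),
                          as.data.frame(t(combn(sprintf("n%02d", 1:10), 2))))
  sigs <- extract_signatures(k10, min_fraction = 0.2,
                             density_threshold = 0.8)
  expect_equal(nrow(sigs), 1L)
  expect_equal(sigs$signature_id, "A")
  expect_equal(sigs$members[[1]], sprintf("n%02d", 1:10))
  expect_equal(sigs$density, 1)

  set.seed(8)
  g <- random_snp_graph(14, 0.55)
  sigs <- extract_signatures(g, min_fraction = 0.2,
                             density_threshold = 0.7)
  comps <- connected_components(g)
  for (i in seq_len(nrow(sigs))) {
    comp <- comps[[sigs$component_id[i]]]
    expect_gte(sigs$size[i], max(2L, ceiling(0.2 * length(comp))))
    expect_gte(sigs$density[i], 0.7)
    expect_true(all(sigs$members[[i]] %in% comp))
  }
})

test_that("minimum-size rounding convention is configurable", {
  # an 84-node component: ceil(0.2 * 84) = 17 but floor gives 16
  ids <- sprintf("m%03d", 1:84)
  # a 16-clique with the remaining nodes attached as a chain
  chain <- data.frame(V1 = ids[16:83], V2 = ids[17:84])
  g <- graph_from_edges(ids, rbind(as.data.frame(t(combn(ids[1:16], 2))),
                                   chain))
  ceil_sigs <- extract_signatures(g, density_threshold = 0.95,
                                  rounding = "ceil",
                                  exhaustive_limit = 0L)
  floor_sigs <- extract_signatures(g, density_threshold = 0.95,
                                   rounding = "floor",
                                   exhaustive_limit = 0L)
  # the 16-clique qualifies only under floor rounding (16 >= 16 but < 17)
  expect_equal(nrow(ceil_sigs), 0L)
  expect_equal(nrow(floor_sigs), 1L)
  expect_equal(floor_sigs$size, 16L)
})

test_that("unassigned SNPs are the complement of signature coverage", {
  expect_equal(unassigned_snps(c("a", "b"), list(c("a", "b"))),
               character(0))
  expect_equal(unassigned_snps(letters[1:5], list(c("a", "b", "c"))),
               c("d", "e"))
})

test_that("graph export round-trips and is byte-stable", {
  g <- graph_from_edges(c("a", "b", "c"),
                        data.frame(from = c("a", "b", "c"),
                                   to = c("b", "c", "a")))
  sigs <- extract_signatures(g, min_fraction = 0.2)
  p1 <- file.path(tempdir(), "g1")
  p2 <- file.path(tempdir(), "g2")
  export_snp_graph(g, sigs, p1)
  export_snp_graph(g, sigs, p2)
  expect_identical(readLines(paste0(p1, ".graphml")),
                   readLines(paste0(p2, ".graphml")))
  back <- igraph::read_graph(paste0(p1, ".graphml"), format = "graphml")
  expect_setequal(igraph::V(back)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(back), 3)
  expect_setequal(igraph::V(back)$signatures, rep("A", 3))

  empty <- graph_from_edges(character(0),
                            data.frame(from = character(),
                                       to = character()))
  p3 <- file.path(tempdir(), "g3")
  export_snp_graph(empty, extract_signatures(empty), p3)
  back0 <- igraph::read_graph(paste0(p3, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(back0), 0)
})
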