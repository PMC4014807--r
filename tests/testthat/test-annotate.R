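test_that("GO annotation loading dedups and maps categories", {
  path <- withr::local_tempfile(fileext = ".tsv")
  go_fixture(path)
  store <- load_go(path)
  expect_equal(nrow(store$go), 6L)
  # hand tally of the namespace mapping
  expect_equal(sum(store$go$namespace == "CC"), 4L)
  expect_equal(sum(store$go$namespace == "BP"), 1L)
  expect_equal(sum(store$go$namespace == "MF"), 1L)

  # duplicated rows collapse; unmappable categories are skipped + counted
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GeneID\tGO_ID\tGO_term\tCategory",
               "1\tGO:1\tsome term\tProcess",
               "1\tGO:1\tsome term\tProcess",
               "2\tGO:2\tother term\tNotAnOntology"), dup)
  store2 <- load_go(dup)
  expect_equal(nrow(store2$go), 1L)
  expect_equal(attr(store2, "load_report")$n_skipped, 1L)
})

test_that("PPI loading canonicalizes the undirected edge set", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tinteractant_id",
               "10\t20", "20\t10",   # symmetric duplicate
               "30\t30",             # self-loop
               "40\t50", "40\t50",   # duplicate
               "60\tNA"),            # incomplete
             path)
  store <- load_ppi(path)
  expect_equal(store$ppi, data.frame(a = c(10L, 40L), b = c(20L, 50L)))
  expect_equal(attr(store, "load_report")$n_skipped, 1L)
})

test_that("enrichment p-values match an explicit hypergeometric-sum oracle", {
  # the printed selection-vs-genome table, hand-sized fixture
  out <- enrichment_test(g_c = 5, x = 10, G_c = 100, N = 22000)
  expect_equal(out$p_value, hyper_tail_p(5, 10, 100, 22000),
               tolerance = 1e-10)
  expect_equal(out$odds_ratio, 5 * (22000 - 100) / (5 * 100))

  # spot grid across sizes
  for (x in c(1, 7, 15)) {
    for (G_c in c(3, 40, 180)) {
      for (g_c in unique(c(1, min(x, G_c)))) {
        expect_equal(enrichment_test(g_c, x, G_c, 22000)$p_value,
                     hyper_tail_p(g_c, x, G_c, 22000), tolerance = 1e-10)
      }
    }
  }

  # enrichment p is monotone in the overlap
  p_seq <- vapply(1:8, function(g) enrichment_test(g, 10, 100, 22000)$p_value,
                  numeric(1))
  expect_true(all(diff(p_seq) < 0))
})

test_that("go_enrichment ranks planted categories and filters on p", {
  genes <- 1:200
  store <- annotation_store(go = data.frame(
    gene_id = c(1:10, 5:8, 100:190),
    go_id = c(rep("GO:A", 10), rep("GO:B", 4), rep("GO:C", 91)),
    term = c(rep("all selected", 10), rep("partial", 4), rep("background", 91)),
    namespace = "BP", stringsAsFactors = FALSE
  ))
  res <- go_enrichment(1:10, store, p_threshold = 1)
  # the category containing every selected gene has the smallest p
  expect_equal(res$go_id[1], "GO:A")
  expect_equal(res$g_c[res$go_id == "GO:A"], 10L)
  expect_equal(res$N[1], 22000L)
  for (k in seq_len(nrow(res))) {
    expect_equal(res$p_value[k],
                 hyper_tail_p(res$g_c[k], res$x[k], res$G_c[k], res$N[k]),
                 tolerance = 1e-10)
  }
  # p-threshold filtering
  strict <- go_enrichment(1:10, store, p_threshold = 0.01)
  expect_true(all(strict$p_value <= 0.01))
  expect_true(all(res$p_value[!res$go_id %in% strict$go_id] > 0.01))
  # namespace filter and empty-selection error
  expect_equal(nrow(go_enrichment(1:10, store, namespace = "CC",
                                  p_threshold = 1)), 0L)
  expect_error(go_enrichment(integer(), store), "empty")
})

test_that("the standard-background table gives the conventional test", {
  out <- enrichment_test(5, 10, 100, 22000, background = "standard")
  # conventional hypergeometric enrichment: draw x from N with G_c marked
  oracle <- sum(stats::dhyper(5:10, 100, 22000 - 100, 10))
  expect_equal(out$p_value, oracle, tolerance = 1e-10)
})

test_that("GO text search is a case-insensitive substring scan", {
  path <- withr::local_tempfile(fileext = ".tsv")
  go_fixture(path)
  store <- load_go(path)
  expect_equal(search_go(NULL, "golgi", store, namespace = "CC"),
               c(1003L, 1004L))
  expect_equal(search_go(NULL, "Golgi membrane", store), 1003L)
  expect_equal(search_go(NULL, "mitochondrion", store), integer(0))
  # restricted to a gene subset
  expect_equal(search_go(c(1004L, 1005L), "Golgi", store), 1004L)
  expect_error(search_go(NULL, "", store), "non-empty")
  # equals a brute-force scan over all annotations
  brute <- sort(unique(store$go$gene_id[
    grepl("golgi", tolower(store$go$term), fixed = TRUE)]))
  expect_equal(search_go(NULL, "GOLGI", store), brute)
})

test_that("GO-based exclusion partitions the table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  go_fixture(path)
  store <- load_go(path)
  tab <- tiny_table(c(1, 2, 3, 4, 5), well_type = rep("sample", 5L))
  tab$records$entrez_id <- 1001:1005
  # 2 of 5 genes carry a proteasome term -> 3 rows remain
  out <- exclude_by_go(tab, "proteasome", store)
  expect_equal(nrow(out$records), 3L)
  expect_equal(out$records$entrez_id, 1003:1005)
  expect_match(out$derivation_log, "proteasome")
  # non-matching term leaves the table unchanged
  same <- exclude_by_go(tab, "spliceosome", store)
  expect_equal(same$records, tab$records)
  # excluded and retained rows partition the original
  excluded <- setdiff(tab$records$entrez_id, out$records$entrez_id)
  expect_equal(sort(c(excluded, out$records$entrez_id)),
               tab$records$entrez_id)
})

test_that("subnetwork extraction equals exhaustive pairwise lookup", {
  store <- annotation_store(ppi = data.frame(a = c(1, 2), b = c(2, 3)))
  expect_equal(ppi_subnetwork(c(1, 2, 3), store)$a, c(1L, 2L))
  expect_equal(nrow(ppi_subnetwork(5, store)), 0L)
  expect_equal(nrow(ppi_subnetwork(integer(), store)), 0L)

  set.seed(60)
  universe <- sample(1:5000, 300)
  pairs <- t(utils::combn(universe[1:60], 2))
  keep <- stats::runif(nrow(pairs)) < 0.05
  store2 <- annotation_store(ppi = data.frame(a = pairs[keep, 1],
                                              b = pairs[keep, 2]))
  genes <- sample(universe, 120)
  net <- ppi_subnetwork(genes, store2)
  # brute force: test every pair of the gene list against the store
  edge_key <- paste(store2$ppi$a, store2$ppi$b)
  gp <- t(utils::combn(sort(genes), 2))
  brute <- gp[paste(pmin(gp[, 1], gp[, 2]), pmax(gp[, 1], gp[, 2])) %in%
                edge_key, , drop = FALSE]
  expect_equal(nrow(net), nrow(brute))
  expect_setequal(paste(net$a, net$b), paste(brute[, 1], brute[, 2]))
  # connected nodes flagged
  expect_setequal(attr(net, "connected"), unique(c(net$a, net$b)))

  # monotonicity: a union of gene sets keeps every edge of the parts
  s1 <- genes[1:60]; s2 <- genes[61:120]
  e_union <- paste(ppi_subnetwork(c(s1, s2), store2)$a,
                   ppi_subnetwork(c(s1, s2), store2)$b)
  e_parts <- c(paste(ppi_subnetwork(s1, store2)$a, ppi_subnetwork(s1, store2)$b),
               paste(ppi_subnetwork(s2, store2)$a, ppi_subnetwork(s2, store2)$b))
  expect_true(all(e_parts %in% e_union))
})

test_that("network export round-trips and writes SIF", {
  edges <- data.frame(a = c(10L, 30L), b = c(20L, 40L))
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(edges, sif, format = "sif")
  expect_equal(readLines(sif), c("10 pp 20", "30 pp 40"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(edges, tsv, format = "tsv")
  back <- utils::read.delim(tsv)
  expect_equal(back$a, edges$a)
  expect_equal(back$b, edges$b)

  empty <- withr::local_tempfile(fileext = ".sif")
  export_network(edges[0, ], empty, format = "sif")
  expect_length(readLines(empty), 0L)
})
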