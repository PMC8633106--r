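comp2 <- function() passing_components(c("c1", "c2"))

test_that("C-T layer is bipartite with correct degrees and nc", {
  edges <- data.frame(from = rep(c("c1", "c2"), each = 3),
                      to = c("t1", "t2", "t3", "t4", "t5", "t6"))
  net <- build_ct_network(comp2(), edges)
  g <- net$graph
  expect_equal(igraph::ecount(g), 6L)
  expect_equal(mean(igraph::degree(g, c("c1", "c2"))), 3)
  expect_equal(unname(igraph::V(g)$nc[match("t1", igraph::V(g)$name)]), 1L)

  lonely <- build_ct_network(passing_components("c1"),
                             data.frame(from = character(0), to = character(0)))
  expect_equal(igraph::vcount(lonely$graph), 1L)
  expect_equal(igraph::ecount(lonely$graph), 0L)

  expect_error(build_ct_network(comp2(), data.frame(from = "ghost", to = "t1")),
               "ghost")
})

test_that("CTPD assembly unions roles and wires the disease star", {
  net <- build_ct_network(comp2(), data.frame(from = c("c1", "c2"),
                                              to = c("A", "B")))
  ctpd <- assemble_ctpd(net,
                        ppi_edges = data.frame(from = c("A", "B"),
                                               to = c("B", "C")),
                        pathogenic_genes = data.frame(symbol = c("B", "C"),
                                                      nv = c(3, 1)),
                        disease_label = "depression")
  g <- ctpd$graph
  b <- match("B", igraph::V(g)$name)
  expect_true(igraph::V(g)$is_target[b] && igraph::V(g)$is_pathogenic[b])
  expect_equal(sum(igraph::E(g)$type == "PPI"), 2L)
  expect_equal(sum(igraph::E(g)$type == "GD"), 2L)
  expect_equal(igraph::V(g)$nv[b], 3)

  # no PPI: CT layer + gene-disease star only
  bare <- assemble_ctpd(net, ppi_edges = NULL,
                        pathogenic_genes = data.frame(symbol = "B", nv = 1))
  expect_equal(sort(unique(igraph::E(bare$graph)$type)), c("CT", "GD"))
})

test_that("T-P extraction keeps the gene layer and only PPI edges", {
  net <- build_ct_network(comp2(), data.frame(from = c("c1", "c2"),
                                              to = c("A", "B")))
  ctpd <- assemble_ctpd(net,
                        ppi_edges = data.frame(from = c("A", "B"),
                                               to = c("B", "C")),
                        pathogenic_genes = data.frame(symbol = c("B", "C"),
                                                      nv = c(3, 1)))
  tp <- extract_tp(ctpd)
  expect_setequal(igraph::V(tp)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(tp), 2L)
  expect_true(all(igraph::E(tp)$type == "PPI"))

  noppi <- assemble_ctpd(net, NULL, data.frame(symbol = "C", nv = 2))
  tp2 <- extract_tp(noppi)
  expect_equal(igraph::ecount(tp2), 0L)
  expect_setequal(igraph::V(tp2)$name, c("A", "B", "C"))
})

test_that("bookkeeping invariants hold on a random bundle", {
  b <- generate_bundle(bundle_params(n_components = 40, n_hubs = 6,
                                     leaves_per_hub = 8, cover_size = 4),
                       seed = 11)
  scr <- screen_components(b$components)
  ct <- b$ct_edges[b$ct_edges$from %in% scr$kept$id, ]
  net <- build_ct_network(scr$kept, ct)
  g0 <- net$graph
  # conservation: sum of nc over targets equals the number of CT edges
  expect_equal(sum(igraph::V(g0)$nc, na.rm = TRUE), nrow(unique(ct)))
  ctpd <- assemble_ctpd(net, b$ppi_edges, b$pathogenic)
  g <- ctpd$graph
  # roles are monotone under layer addition
  expect_true(all(igraph::V(g)$is_target[match(unique(ct$to),
                                               igraph::V(g)$name)]))
  tp <- extract_tp(ctpd)
  expect_setequal(igraph::V(tp)$name,
                  union(unique(ct$to), b$pathogenic$symbol))
  # second extraction is a no-op
  tp_nodes <- igraph::V(tp)$name
  expect_setequal(tp_nodes[igraph::V(tp)$is_target |
                             igraph::V(tp)$is_pathogenic], tp_nodes)
})

test_that("evidence binning counts each gene once and averages term hits", {
  genes <- data.frame(symbol = c("a", "b", "c"), nv = c(1, 1, 3))
  prof <- bin_evidence_profile(genes, NULL, breaks = c(1, 2, Inf))
  expect_equal(prof$n_genes, c(2L, 1L))
  expect_equal(sum(prof$n_genes), nrow(genes))
  expect_equal(prof$mean_terms, c(0, 0))  # empty collection

  col <- structure(list(t1 = c("a", "b"), t2 = c("a", "c"), t3 = c("c")),
                   class = "gene_set_collection")
  prof2 <- bin_evidence_profile(genes, col, breaks = c(1, 2, Inf))
  # bin [1,2): a in 2 terms, b in 1 -> mean 1.5 ; bin [2,Inf): c in 2 terms
  expect_equal(prof2$mean_terms, c(1.5, 2))
  expect_error(bin_evidence_profile(genes, NULL, breaks = c(1, 1, 3)),
               "increasing")
})
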