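test_that("effective diameter is the max over components", {
  p3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(effective_diameter(p3), 2)
  two <- igraph::make_graph(~ a - b, c - d)
  expect_equal(effective_diameter(two), 1)
  one <- igraph::make_empty_graph(1, directed = FALSE)
  expect_error(effective_diameter(one), "diameter")
  set.seed(5)
  g <- random_connected_graph(30, 0.12)
  d <- igraph::distances(g, weights = NA)   # all-pairs BFS reference
  expect_equal(effective_diameter(g), max(d[is.finite(d)]))
})

test_that("importance matches hand-derived values on canonical graphs", {
  p3 <- igraph::make_graph(~ a - b, b - c)
  im <- node_importance(p3)
  expect_equal(im$im[match(c("a", "b", "c"), im$node)], c(0, 1 / 6, 0))

  star <- igraph::make_star(4, "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
  ims <- node_importance(star)
  expect_equal(ims$im[ims$node == "hub"], 0.25)
  expect_equal(ims$im[ims$node != "hub"], rep(0, 3))

  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("x", "y", "z")
  expect_equal(node_importance(k3)$im, rep(0, 3))  # no transit paths
})

test_that("importance equals exhaustive path enumeration on random graphs", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    g <- random_connected_graph(n, runif(1, 0.25, 0.6))
    got <- node_importance(g)
    oracle <- im_oracle(g)
    expect_equal(got$im[match(igraph::V(g)$name, got$node)], oracle$im,
                 tolerance = 1e-12)
    # im is zero exactly when no shortest path transits the node
    expect_equal(got$im == 0, oracle$m == 0)
    # transit paths are 2..diameter hops, bounding the first factor
    lens <- oracle$mean_len[!is.na(oracle$mean_len)]
    expect_true(all(lens >= 2 & lens <= oracle$diameter))
  }
})

test_that("adding an isolated node rescales im only through the pair count", {
  set.seed(7)
  g <- random_connected_graph(12, 0.3)
  im1 <- node_importance(g)
  g2 <- igraph::add_vertices(g, 1, attr = list(name = "island"))
  im2 <- node_importance(g2)
  n1 <- 12; n2 <- 13
  ratio <- (n1 * (n1 - 1) / 2) / (n2 * (n2 - 1) / 2)
  expect_equal(im2$im[match(im1$node, im2$node)], im1$im * ratio,
               tolerance = 1e-12)
  expect_equal(im2$im[im2$node == "island"], 0)
})

test_that("baseline centralities follow the stated conventions", {
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("x", "y", "z")
  b <- baseline_centralities(k3)
  expect_equal(b$degree, rep(2, 3))
  expect_equal(b$clustering, rep(1, 3))

  star <- igraph::make_star(5, "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("l", 1:4))
  bs <- baseline_centralities(star)
  expect_equal(bs$betweenness[bs$node == "hub"], 1)  # all transit pairs

  set.seed(19)
  g <- random_connected_graph(25, 0.15)
  bg <- baseline_centralities(g)
  oracle <- im_oracle(g)
  n <- 25
  # normalised betweenness must equal the enumerated transit fractions
  expect_equal(bg$betweenness, oracle$frac / ((n - 1) * (n - 2) / 2),
               tolerance = 1e-12)
  # neighbourhood connectivity is the mean degree of neighbours
  deg <- igraph::degree(g)
  nc_ref <- vapply(seq_len(n), function(i) {
    mean(deg[as.integer(igraph::neighbors(g, i))])
  }, numeric(1))
  expect_equal(bg$neighborhood_connectivity, nc_ref)
})

test_that("EIS keeps strictly-above-median nodes and errors on flat scores", {
  star <- igraph::make_star(4, "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
  eis <- extract_eis(star)
  expect_equal(eis$nodes, "hub")
  expect_equal(igraph::ecount(eis$graph), 0L)

  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("x", "y", "z")
  expect_error(extract_eis(k3), "median")          # all scores equal (0)
  eis_ge <- extract_eis(k3, mode = ">=")
  expect_setequal(eis_ge$nodes, c("x", "y", "z"))

  # strict mode selects a subset of the inclusive mode
  set.seed(3)
  g <- random_connected_graph(15, 0.25)
  imp <- node_importance(g)
  strict <- extract_eis(g, imp)
  expect_true(all(strict$nodes %in% extract_eis(g, imp, mode = ">=")$nodes))
})

test_that("node categories partition the EIS", {
  cats <- categorize_nodes(c("A", "B", "C"), target_set = c("A", "B"),
                           pathogenic_set = c("B", "C"))
  expect_equal(unname(cats), c("component_specific", "essential_common",
                               "disease_specific"))
  expect_error(categorize_nodes(c("A", "Z"), "A", "B"), "Z")
  set.seed(9)
  g <- random_connected_graph(20, 0.25)
  nodes <- igraph::V(g)$name
  tg <- sample(nodes, 12)
  pg <- sample(nodes, 12)
  pg <- union(pg, setdiff(nodes, tg))  # ensure full coverage
  cats2 <- categorize_nodes(nodes, tg, pg)
  expect_equal(length(cats2), length(nodes))
  expect_equal(sum(table(cats2)), length(nodes))
})
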