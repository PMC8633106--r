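make_eis <- function(graph) {
  structure(list(graph = graph, nodes = sort(igraph::V(graph)$name),
                 threshold = 0, mode = ">", importance = NULL),
            class = "eis")
}

test_that("knapsack items encode coverage and pathogenic reach", {
  # EIS: target T wired to pathogenic P1..P3; P4, P5 pathogenic but remote;
  # four extra neutral nodes bring the space to 10 nodes
  g <- igraph::make_graph(~ T - P1, T - P2, T - P3, P4 - P5,
                          N1 - N2, N3 - N4)
  eis <- make_eis(g)
  pg <- c("P1", "P2", "P3", "P4", "P5")
  ct <- data.frame(from = c("cA", "cA", "cB", "cC"),
                   to = c("N1", "N2", "T", "outside"))
  expect_message(items <- compute_items(eis, ct, pg), "dropped")
  expect_equal(nrow(items), 2L)                 # cC has no EIS target
  expect_equal(items$w[items$component_id == "cA"], 2 / 10)
  expect_equal(items$v[items$component_id == "cB"], 3 / 5)
  expect_error(compute_items(eis, ct, "nowhere"), "no pathogenic")
})

test_that("knapsack DP matches subset enumeration and honours the budget", {
  items <- data.frame(component_id = c("a", "b", "c", "d"),
                      w = c(2, 3, 4, 5), v = c(3, 4, 5, 6))
  res <- knapsack_select(items, R = 5, resolution = 1)
  expect_equal(res$objective, 7)
  expect_setequal(res$selected, c("a", "b"))
  expect_equal(knapsack_select(items, R = 0.5, resolution = 1)$objective, 0)
  expect_equal(knapsack_select(items, R = 0, resolution = 1)$objective, 0)
  all_in <- knapsack_select(items, R = sum(items$w), resolution = 1)
  expect_equal(all_in$objective, sum(items$v))
  expect_setequal(all_in$selected, items$component_id)

  set.seed(23)
  for (rep in 1:60) {
    n <- sample(4:16, 1)
    w <- sample(1:30, n, replace = TRUE)
    v <- round(runif(n, 0.1, 10), 3)
    R <- sample(5:60, 1)
    it <- data.frame(component_id = sprintf("i%02d", 1:n), w = w, v = v)
    got <- knapsack_select(it, R, resolution = 1)
    expect_equal(got$objective, knapsack_oracle(w, v, R), tolerance = 1e-9)
    expect_lte(got$weight, R + 1e-9)
  }
})

test_that("greedy curve accumulates disjoint covers and handles nesting", {
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, 10, attr = list(name = sprintf("e%02d", 1:10)))
  eis <- make_eis(g)
  nodes <- sort(igraph::V(g)$name)
  ct <- rbind(data.frame(from = "big", to = nodes[1:5]),
              data.frame(from = "mid", to = nodes[6:8]),
              data.frame(from = "sml", to = nodes[9:10]))
  items <- compute_items(eis, ct, pathogenic_set = nodes)
  curve <- greedy_coverage_curve(items, eis)
  expect_equal(curve$component_id, c("big", "mid", "sml"))
  expect_equal(curve$cumulative_coverage, c(0.5, 0.8, 1.0))
  # marginal gains are non-increasing by construction
  expect_true(all(diff(curve$marginal_gain) <= 1e-12))

  nested <- rbind(data.frame(from = "superset", to = nodes[1:6]),
                  data.frame(from = "subset", to = nodes[1:3]))
  c2 <- greedy_coverage_curve(compute_items(eis, nested, nodes), eis)
  expect_equal(c2$component_id[1], "superset")
  expect_equal(c2$marginal_gain[2], 0)
  expect_equal(max(c2$cumulative_coverage), 0.6)
})

test_that("final coverage is order-free and ties break lexicographically", {
  set.seed(31)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, 20, attr = list(name = sprintf("e%02d", 1:20)))
  eis <- make_eis(g)
  nodes <- igraph::V(g)$name
  ct <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(from = sprintf("c%02d", i),
               to = sample(nodes, sample(2:6, 1)))
  }))
  items <- compute_items(eis, ct, nodes)
  curve <- greedy_coverage_curve(items, eis)
  expect_equal(max(curve$cumulative_coverage),
               length(unique(intersect(ct$to, eis$nodes))) / 20)
  shuffled <- items[sample(nrow(items)), ]
  curve2 <- greedy_coverage_curve(shuffled, eis)
  expect_equal(curve2$component_id, curve$component_id)  # deterministic

  # explicit tie: two identical target sets -> alphabetical first
  tie <- rbind(data.frame(from = "zeta", to = nodes[1:3]),
               data.frame(from = "alpha", to = nodes[1:3]))
  ctie <- greedy_coverage_curve(compute_items(eis, tie, nodes), eis)
  expect_equal(ctie$component_id, c("alpha", "zeta"))
})

test_that("CGFC selection reads the shortest sufficient prefix", {
  curve <- structure(data.frame(step = 1:3,
                                component_id = c("a", "b", "c"),
                                marginal_gain = c(0.5, 0.3, 0.2),
                                cumulative_coverage = c(0.5, 0.8, 1.0)),
                     class = c("cgfc_curve", "data.frame"))
  expect_equal(select_cgfc(curve, 0.95)$selected, c("a", "b", "c"))
  expect_equal(select_cgfc(curve, 0.5)$selected, "a")
  short <- curve[1:2, ]
  class(short) <- class(curve)
  expect_warning(sel <- select_cgfc(short, 0.99), "unreachable")
  expect_equal(sel$selected, c("a", "b"))
})
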