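ctx0 <- function(r_avg = 0.5, d_avg = 0.5,
                 pg_bounds = c(0, 10), tg_bounds = c(0, 10)) {
  structure(list(pg_bounds = pg_bounds, tg_bounds = tg_bounds,
                 r_avg = r_avg, d_avg = d_avg), class = "score_context")
}

test_that("min-max normalisation maps bounds to 0/1 and degenerates to 0", {
  expect_equal(normalize_evidence(11, c(1, 11)), 1)
  expect_equal(normalize_evidence(1, c(1, 11)), 0)
  expect_equal(normalize_evidence(6, c(1, 11)), 0.5)
  expect_equal(normalize_evidence(5, c(4, 4)), 0)     # no spread
  expect_error(normalize_evidence(-1, c(0, 5)), ">= 0")
  expect_equal(normalize_regulation(2, c(0, 8)), 0.25)
  expect_equal(normalize_regulation(8, c(0, 8)), 1)
})

test_that("cascade scores follow the per-node membership corrections", {
  edges <- data.frame(from = c("A", "B"), to = c("B", "C"))
  g_all <- signaling_graph(edges, tg = c("A", "B", "C"),
                           pg = data.frame(symbol = c("A", "B", "C"), nv = 10),
                           nc = data.frame(node = c("A", "B", "C"), nc = 10),
                           im = data.frame(node = c("A", "B", "C"), im = 0.1))
  sc <- score_cascade(c("A", "B", "C"), g_all, ctx0())
  expect_equal(sc$raw, 9.3)        # 3 x (0.1 + 1 + 1 + 0.5 + 0.5)
  expect_equal(sc$score, 3.1)

  g_none <- signaling_graph(edges, tg = character(0),
                            pg = data.frame(symbol = character(0),
                                            nv = numeric(0)),
                            im = data.frame(node = c("A", "B", "C"), im = 0))
  sc0 <- score_cascade(c("A", "B", "C"), g_none, ctx0(pg_bounds = c(0, 1),
                                                      tg_bounds = c(0, 1)))
  expect_equal(sc0$raw, -3)        # 3 x (0 + 0 + 0 - 0.5 - 0.5)

  # concatenation: shared endpoint counted once
  long <- data.frame(from = c("A", "B", "C", "D"), to = c("B", "C", "D", "E"))
  nodes5 <- c("A", "B", "C", "D", "E")
  g5 <- signaling_graph(long, tg = nodes5,
                        pg = data.frame(symbol = nodes5, nv = 10),
                        nc = data.frame(node = nodes5, nc = 10),
                        im = data.frame(node = nodes5, im = 0.1))
  full <- score_cascade(nodes5, g5, ctx0())
  head3 <- score_cascade(c("A", "B", "C"), g5, ctx0())
  tail3 <- score_cascade(c("C", "D", "E"), g5, ctx0())
  expect_equal(full$raw, head3$raw + tail3$raw - 3.1)

  expect_error(score_cascade(c("A", "Z"), g_all, ctx0()), "Z")
  expect_error(score_cascade(c("C", "A"), g_all, ctx0()), "no directed edge")
})

test_that("score context averages normalised attributes over TG/PG", {
  edges <- data.frame(from = c("r", "m"), to = c("m", "t"))
  g <- signaling_graph(edges, tg = c("r", "m"),
                       pg = data.frame(symbol = c("m", "t"), nv = c(2, 6)),
                       nc = data.frame(node = c("r", "m"), nc = c(1, 3)))
  ctx <- score_context(g)
  expect_equal(ctx$pg_bounds, c(2, 6))
  expect_equal(ctx$r_avg, 0.5)     # normalised nv over PG: (0 + 1)/2
  expect_equal(ctx$d_avg, 0.5)
})

test_that("shortest cascades are deterministic minimum-weight paths", {
  chain <- signaling_graph(data.frame(from = c("r", "a", "b"),
                                      to = c("a", "b", "t")))
  expect_equal(shortest_cascades(chain), list(c("r", "a", "b", "t")))

  diamond <- signaling_graph(data.frame(from = c("r", "r", "a", "b"),
                                        to = c("a", "b", "t", "t")))
  expect_equal(shortest_cascades(diamond), list(c("r", "a", "t")))

  set.seed(41)
  for (rep in 1:15) {
    g <- random_dag(12, 0.3)
    paths <- shortest_cascades(g)
    nm <- igraph::V(g)$name
    src <- nm[igraph::degree(g, mode = "in") == 0]
    snk <- nm[igraph::degree(g, mode = "out") == 0]
    d <- igraph::distances(g, mode = "out", weights = igraph::E(g)$weight)
    reachable <- sum(vapply(src, function(s)
      sum(is.finite(d[s, snk]) & snk != s), numeric(1)))
    expect_equal(length(paths), reachable)   # unreachable pairs omitted
    for (p in paths) {
      wgt <- sum(vapply(seq_len(length(p) - 1), function(i) {
        eid <- igraph::get_edge_ids(g, c(p[i], p[i + 1]))
        igraph::E(g)$weight[eid]
      }, numeric(1)))
      expect_equal(wgt, min_path_weight_oracle(g, p[1], p[length(p)]))
    }
  }
})

test_that("retention filters strictly and orders by score", {
  ca <- chsgs_cascades()
  expect_equal(nrow(retain_cascades(ca, 0.7)), 13L)
  expect_equal(nrow(retain_cascades(ca, 0.95)), 1L)
  expect_equal(retain_cascades(ca, 0.95)$cascade[1],
               "ADCY1--cAMP--PRKACA--RHOA")
  expect_equal(nrow(retain_cascades(ca, 0.962)), 0L)  # strictly greater
  expect_equal(nrow(retain_cascades(ca[0, ], 0.7)), 0L)
  expect_false(is.unsorted(rev(retain_cascades(ca, 0.7)$score)))
})

test_that("module merging separates routes that only share an effector", {
  two <- list(c("a", "b", "c"), c("x", "y", "z"))
  m2 <- merge_modules(two)
  expect_equal(m2$n_modules, 2L)
  one <- list(c("a", "b", "c"), c("x", "b", "z"))
  expect_equal(merge_modules(one)$n_modules, 1L)

  ca <- chsgs_cascades()
  mm <- merge_modules(ca)
  expect_equal(mm$n_modules, 2L)
  sizes <- vapply(mm$modules, length, integer(1))
  # ADCY1/PRKACA branch vs DRD1/DRD5 branch; FOS attached to both
  expect_true(any(vapply(mm$modules, function(m) "ADCY1" %in% m, logical(1))))
  expect_true(any(vapply(mm$modules, function(m) "DRD1" %in% m, logical(1))))
  shared <- intersect(mm$modules[[1]], mm$modules[[2]])
  expect_true("FOS" %in% shared)
  # letting shared sinks bridge collapses the printed chains to one block
  expect_equal(merge_modules(ca, bridge_sinks = TRUE)$n_modules, 1L)
})

test_that("normalised attributes and scores stay within their bounds", {
  for (seed in 1:5) {
    sig <- generate_signaling(bundle_params(), seed = seed)
    g <- signaling_graph(sig$edges, tg = sig$tg, pg = sig$pg, nc = sig$nc)
    ctx <- score_context(g)
    r <- normalize_evidence(igraph::V(g)$nv, ctx$pg_bounds)
    d <- normalize_regulation(igraph::V(g)$nc, ctx$tg_bounds)
    expect_true(all(r >= 0 & r <= 1))
    expect_true(all(d >= 0 & d <= 1))
    casc <- mtw_cascades(g)
    cap <- max(igraph::V(g)$im) + 2 + ctx$r_avg + ctx$d_avg
    expect_true(all(casc$raw <= casc$n_nodes * cap + 1e-9))
  }
})
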