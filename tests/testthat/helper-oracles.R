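# Independent oracles used across the suite. They deliberately take the
# slow, literal route (explicit path enumeration, explicit subset search,
# explicit tail summation) so they share no code path with the package.

# Transit-path importance by exhaustive shortest-path enumeration.
# Returns per-node im plus the raw ingredients (m, mean transit length,
# fractional betweenness numerator).
im_oracle <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g, weights = NA)
  diam <- max(d[is.finite(d)])
  m <- numeric(n)
  lensum <- numeric(n)
  frac <- numeric(n)
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      if (!is.finite(d[j, k]) || d[j, k] == 0) next
      paths <- igraph::all_shortest_paths(g, from = j, to = k,
                                          weights = NA)$res
      g_jk <- length(paths)
      for (p in paths) {
        interior <- setdiff(as.integer(p), c(j, k))
        if (length(interior) == 0L) next
        m[interior] <- m[interior] + 1
        lensum[interior] <- lensum[interior] + (length(p) - 1)
        frac[interior] <- frac[interior] + 1 / g_jk
      }
    }
  }
  im <- ifelse(m == 0, 0,
               ((diam + 1) - lensum / pmax(m, 1)) / diam *
                 (frac / (n * (n - 1) / 2)))
  list(im = im, m = m,
       mean_len = ifelse(m == 0, NA_real_, lensum / pmax(m, 1)),
       frac = frac, diameter = diam)
}

# Seeded G(n, p) graph, resampled until connected.
random_connected_graph <- function(n, p) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
      return(g)
    }
  }
}

# All labeled connected graphs on n nodes (edge-subset enumeration).
all_connected_graphs <- function(n) {
  pairs <- utils::combn(n, 2)
  ne <- ncol(pairs)
  out <- list()
  for (mask in seq_len(2^ne - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(ne) - 1)) > 0)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, as.vector(pairs[, sel, drop = FALSE]))
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- letters[seq_len(n)]
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

# 0/1 knapsack optimum by meet-in-the-middle subset enumeration.
knapsack_oracle <- function(w, v, R) {
  enum <- function(wi, vi) {
    k <- length(wi)
    if (k == 0L) return(data.frame(w = 0, v = 0))
    m <- as.matrix(expand.grid(rep(list(0:1), k)))
    data.frame(w = as.numeric(m %*% wi), v = as.numeric(m %*% vi))
  }
  h <- length(w) %/% 2
  a <- enum(w[seq_len(h)], v[seq_len(h)])
  b <- enum(w[-seq_len(h)], v[-seq_len(h)])
  b <- b[order(b$w), , drop = FALSE]
  b$vmax <- cummax(b$v)
  best <- 0
  for (i in seq_len(nrow(a))) {
    if (a$w[i] > R) next
    j <- findInterval(R - a$w[i] + 1e-9, b$w)
    if (j >= 1L) best <- max(best, a$v[i] + b$vmax[j])
  }
  best
}

# Upper-tail hypergeometric probability by direct summation.
hyper_tail_oracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (length(js) == 0L) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Minimum source->sink path weight by exhaustive simple-path enumeration.
min_path_weight_oracle <- function(g, s, t) {
  paths <- igraph::all_simple_paths(g, from = s, to = t, mode = "out")
  if (length(paths) == 0L) return(Inf)
  min(vapply(paths, function(p) {
    idx <- as.integer(p)
    sum(vapply(seq_len(length(idx) - 1L), function(i) {
      eid <- igraph::get_edge_ids(g, c(idx[i], idx[i + 1L]))
      igraph::E(g)$weight[eid]
    }, numeric(1)))
  }, numeric(1)))
}

# Random DAG over a fixed topological order with unit-ish random weights.
random_dag <- function(n, p_edge, weights = TRUE) {
  el <- NULL
  for (i in seq_len(n - 1)) {
    kids <- which(stats::runif(n - i) < p_edge) + i
    if (length(kids) > 0L) el <- rbind(el, cbind(i, kids))
  }
  if (is.null(el)) el <- cbind(1, 2)
  g <- igraph::graph_from_edgelist(apply(el, 2, function(x) sprintf("v%02d", x)),
                                   directed = TRUE)
  igraph::E(g)$weight <- if (weights)
    sample(1:5, igraph::ecount(g), replace = TRUE) else 1
  g
}

# A tiny component-property table where every row passes the default rules.
passing_components <- function(ids) {
  n <- length(ids)
  structure(data.frame(
    id = ids, name = ids, herbs = "HB1",
    mw = rep(300, n), hdon = rep(2, n), hacc = rep(4, n), rbn = rep(3, n),
    logp = rep(1.5, n), ob = rep(50, n),
    gi_class = "high", herg_class = "low", carcinogenicity = "negative",
    stringsAsFactors = FALSE), class = c("component_table", "data.frame"))
}
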