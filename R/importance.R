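#' Effective diameter of a (possibly disconnected) graph
#'
#' The effective diameter is the largest finite shortest-path distance (hop
#' count) between any two nodes; for a disconnected graph it is the maximum
#' over connected components of the component diameter. Isolated nodes
#' contribute 0.
#'
#' @param graph An undirected `igraph`.
#' @return Integer hop count.
#' @export
effective_diameter <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2L) stop("diameter undefined for a graph with < 2 nodes",
                   call. = FALSE)
  d <- igraph::distances(graph, weights = NA)
  d <- d[is.finite(d)]
  max(d)
}

# All-pairs hop distances and shortest-path counts.
# Returns list(d = distance matrix, sigma = path-count matrix); sigma[j, k]
# is the number of distinct shortest paths between j and k (1 on the
# diagonal, 0 for disconnected pairs). Level-by-level BFS accumulation per
# source; dense matrices (the graphs this package targets are small).
shortest_path_counts <- function(graph) {
  n <- igraph::vcount(graph)
  d <- igraph::distances(graph, weights = NA)
  a <- matrix(0, n, n)
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el) > 0L) {
    a[el] <- 1
    a[el[, c(2, 1), drop = FALSE]] <- 1
  }
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ds <- d[s, ]
    sig <- numeric(n)
    sig[s] <- 1
    maxlev <- max(ds[is.finite(ds)])
    lev <- 1
    while (lev <= maxlev) {
      prev <- which(ds == lev - 1)
      cur <- which(ds == lev)
      sig[cur] <- a[cur, prev, drop = FALSE] %*% sig[prev]
      lev <- lev + 1
    }
    sigma[s, ] <- sig
  }
  list(d = d, sigma = sigma)
}

#' Transit-path node importance (IM)
#'
#' Scores every node of a simple undirected graph by the product of two
#' factors built from the shortest paths that *transit* the node (paths
#' between two other nodes j, k passing through i):
#' \deqn{IM_i = \frac{(\emptyset + 1) - \bar{\ell}_i}{\emptyset} \times
#'       \frac{\sum_{j<k} g_{jk}(i)/g_{jk}}{n(n-1)/2}}
#' where \eqn{\emptyset} is the effective diameter, \eqn{\bar{\ell}_i} the
#' mean length of all shortest paths through i (each path counted once, so a
#' pair with several shortest routes through i contributes each route),
#' \eqn{g_{jk}} the number of shortest paths between j and k and
#' \eqn{g_{jk}(i)} how many of them pass through i. Pairs in different
#' components are skipped. A node no shortest path transits gets
#' \eqn{IM_i = 0}. The pair sums run over unordered pairs with
#' \eqn{j \neq i \neq k}, the usual betweenness convention; the
#' \eqn{n(n-1)/2} normalisation keeps the second factor below 1 by design.
#'
#' The first factor rewards nodes that mediate *short* relays (mean transit
#' length close to 2 hops), the second rewards nodes mediating *many* pairs;
#' hubs score high on both.
#'
#' @param graph A simple undirected `igraph` with at least 3 nodes.
#' @return A data frame of class `importance_table` with columns `node` and
#'   `im` plus the baseline centralities of [baseline_centralities()];
#'   attributes `diameter` (effective diameter) and `im_median`.
#' @export
node_importance <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 3L) stop("node importance needs at least 3 nodes", call. = FALSE)
  if (igraph::any_multiple(graph) || any(igraph::which_loop(graph))) {
    stop("graph must be simple (no loops or parallel edges)", call. = FALSE)
  }
  diam <- effective_diameter(graph)
  if (diam == 0) stop("all nodes isolated: importance undefined",
                      call. = FALSE)
  sp <- shortest_path_counts(graph)
  d <- sp$d
  sigma <- sp$sigma
  im <- numeric(n)
  npairs <- n * (n - 1) / 2
  for (i in seq_len(n)) {
    di <- d[, i]
    reach <- which(is.finite(di) & seq_len(n) != i)
    if (length(reach) < 2L) next
    dmat <- outer(di[reach], di[reach], "+")
    dd <- d[reach, reach, drop = FALSE]
    on_path <- dmat == dd & is.finite(dd)
    if (!any(on_path)) next
    cnt <- outer(sigma[reach, i], sigma[i, reach]) * on_path
    m <- sum(cnt) / 2
    if (m == 0) next
    lensum <- sum(cnt * dd) / 2
    frac <- sum((cnt / ifelse(sigma[reach, reach] == 0, 1,
                              sigma[reach, reach]))) / 2
    first <- ((diam + 1) - lensum / m) / diam
    second <- frac / npairs
    im[i] <- first * second
  }
  base <- baseline_centralities(graph)
  out <- cbind(data.frame(node = igraph::V(graph)$name %||%
                            as.character(seq_len(n)),
                          im = im, stringsAsFactors = FALSE),
               base[, setdiff(names(base), "node"), drop = FALSE])
  attr(out, "diameter") <- diam
  attr(out, "im_median") <- stats::median(im)
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Baseline node centralities
#'
#' The standard centralities the importance score is compared against:
#' degree, betweenness (transit convention, normalised by the number of
#' ordered transit pairs), closeness (within the reachable set), local
#' clustering coefficient (isolates scored 0), and neighbourhood
#' connectivity (mean degree of a node's neighbours; 0 for isolates).
#'
#' @param graph An undirected `igraph`.
#' @return Data frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`, `clustering`, `neighborhood_connectivity`.
#' @export
baseline_centralities <- function(graph) {
  n <- igraph::vcount(graph)
  deg <- igraph::degree(graph)
  btw <- igraph::betweenness(graph, directed = FALSE, weights = NA,
                             normalized = n > 2)
  cls <- suppressWarnings(igraph::closeness(graph, weights = NA,
                                            normalized = TRUE))
  cls[!is.finite(cls)] <- 0
  clu <- igraph::transitivity(graph, type = "local", isolates = "zero")
  nc <- igraph::knn(graph, weights = NA)$knn
  nc[!is.finite(nc)] <- 0
  data.frame(node = igraph::V(graph)$name %||% as.character(seq_len(n)),
             degree = as.numeric(deg), betweenness = as.numeric(btw),
             closeness = as.numeric(cls), clustering = as.numeric(clu),
             neighborhood_connectivity = as.numeric(nc),
             stringsAsFactors = FALSE)
}

#' Extract the effective intervention space
#'
#' Keeps the nodes of the target-pathogenic-gene graph whose importance
#' score exceeds the median score of all nodes (strictly, by default) and
#' returns the induced subgraph — the effective intervention space (EIS).
#' Every retained node is an intervention-response protein.
#'
#' @param tp_graph The T-P `igraph` (see [extract_tp()]).
#' @param importance An `importance_table` computed on `tp_graph` (computed
#'   here when `NULL`).
#' @param mode `">"` (strict, default) or `">="` for the threshold.
#' @return A list of class `eis`: `graph` (induced subgraph), `nodes`,
#'   `threshold` (the parent-graph median), `mode`, `importance`.
#' @export
extract_eis <- function(tp_graph, importance = NULL, mode = c(">", ">=")) {
  mode <- match.arg(mode)
  if (is.null(importance)) importance <- node_importance(tp_graph)
  if (!setequal(importance$node, igraph::V(tp_graph)$name)) {
    stop("importance table does not match the graph's node set",
         call. = FALSE)
  }
  med <- attr(importance, "im_median")
  if (is.null(med)) med <- stats::median(importance$im)
  keep <- if (mode == ">") importance$node[importance$im > med]
          else importance$node[importance$im >= med]
  if (length(keep) == 0L) {
    stop("no node exceeds the median importance (all scores equal?); ",
         "consider mode = \">=\"", call. = FALSE)
  }
  sub <- igraph::induced_subgraph(tp_graph, keep)
  structure(list(graph = sub, nodes = sort(keep), threshold = med,
                 mode = mode, importance = importance),
            class = "eis")
}

#' Categorise intervention-response proteins
#'
#' Splits EIS nodes into the three reported categories: genes that are both
#' component targets and pathogenic genes (`essential_common`), pathogenic
#' genes only (`disease_specific`), and component targets only
#' (`component_specific`).
#'
#' @param eis An `eis` object or a character vector of node names.
#' @param target_set Character vector of component-target genes.
#' @param pathogenic_set Character vector of pathogenic genes.
#' @return Named character vector of categories, one per node.
#' @export
categorize_nodes <- function(eis, target_set, pathogenic_set) {
  nodes <- if (inherits(eis, "eis")) eis$nodes else as.character(eis)
  in_t <- nodes %in% target_set
  in_p <- nodes %in% pathogenic_set
  if (any(!in_t & !in_p)) {
    stop("node(s) in neither the target nor the pathogenic set: ",
         paste(nodes[!in_t & !in_p], collapse = ", "), call. = FALSE)
  }
  out <- ifelse(in_t & in_p, "essential_common",
                ifelse(in_p, "disease_specific", "component_specific"))
  stats::setNames(out, nodes)
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("importance_table: %d nodes, effective diameter %g, median IM %.6g\n",
              nrow(x), attr(x, "diameter"), attr(x, "im_median")))
  cols <- intersect(c("node", "im", "degree", "betweenness"), names(x))
  top <- utils::head(as.data.frame(x)[order(-x$im), cols, drop = FALSE], 5)
  print.data.frame(top, row.names = FALSE)
  invisible(x)
}

#' @export
print.eis <- function(x, ...) {
  cat(sprintf("effective intervention space: %d nodes, %d edges (IM %s %.6g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$mode, x$threshold))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
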