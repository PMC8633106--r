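#' Build a signalling graph for cascade scoring
#'
#' Wraps a directed edge list into an `igraph` carrying the node attributes
#' the maximum-targeting-weight (MTW) model needs: membership in the
#' component-target set (`in_tg`) and the pathogenic-gene set (`in_pg`),
#' literature-evidence counts (`nv`, 0 when unknown), regulating-component
#' counts (`nc`, 0 when unknown), and an importance score `im`. Unless
#' supplied, `im` is computed with [node_importance()] on the undirected
#' view of the graph.
#'
#' @param edges Data frame with `from`, `to` and optional `weight`
#'   (default 1, must be >= 0).
#' @param tg Character vector: target genes of the selected components.
#' @param pg Data frame with `symbol`, `nv` — pathogenic genes with
#'   evidence counts (see [read_pathogenic_table()]).
#' @param nc Optional data frame with `node`, `nc` — per-gene counts of
#'   regulating components.
#' @param im Optional data frame with `node`, `im`; computed when `NULL`.
#' @return A directed `igraph` with the attributes above.
#' @export
signaling_graph <- function(edges, tg = character(0),
                            pg = data.frame(symbol = character(0),
                                            nv = numeric(0)),
                            nc = NULL, im = NULL) {
  w <- if (is.null(edges$weight)) rep(1, nrow(edges)) else edges$weight
  if (any(w < 0)) stop("edge weights must be >= 0", call. = FALSE)
  el <- data.frame(from = as.character(edges$from),
                   to = as.character(edges$to), weight = w,
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = TRUE)
  nm <- igraph::V(g)$name
  igraph::V(g)$in_tg <- nm %in% tg
  igraph::V(g)$in_pg <- nm %in% pg$symbol
  nv <- rep(0, length(nm))
  nv[match(pg$symbol, nm)[!is.na(match(pg$symbol, nm))]] <-
    pg$nv[!is.na(match(pg$symbol, nm))]
  if (any(nv < 0)) stop("nv must be >= 0", call. = FALSE)
  igraph::V(g)$nv <- nv
  ncv <- rep(0, length(nm))
  if (!is.null(nc)) {
    hit <- match(nc$node, nm)
    ncv[hit[!is.na(hit)]] <- nc$nc[!is.na(hit)]
  }
  igraph::V(g)$nc <- ncv
  if (is.null(im)) {
    und <- igraph::as_undirected(igraph::delete_edge_attr(g, "weight"),
                                 mode = "collapse")
    imv <- if (igraph::vcount(und) >= 3 &&
               any(igraph::degree(und) > 0)) {
      tab <- node_importance(und)
      tab$im[match(nm, tab$node)]
    } else {
      rep(0, length(nm))
    }
    igraph::V(g)$im <- imv
  } else {
    hit <- match(nm, im$node)
    if (anyNA(hit)) {
      stop("im table missing node(s): ", paste(nm[is.na(hit)], collapse = ", "),
           call. = FALSE)
    }
    igraph::V(g)$im <- im$im[hit]
  }
  g
}

#' Min-max normalised literature evidence
#'
#' \eqn{R_i = (NV_i - \min_{PG} NV) / (\max_{PG} NV - \min_{PG} NV)},
#' clamped to `[0, 1]`; 0 when the pathogenic genes show no spread.
#'
#' @param nv Evidence count(s), >= 0.
#' @param pg_bounds Numeric `c(min, max)` of `nv` over pathogenic genes.
#' @return Value(s) in `[0, 1]`.
#' @export
normalize_evidence <- function(nv, pg_bounds) {
  if (any(nv < 0)) stop("nv must be >= 0", call. = FALSE)
  lo <- pg_bounds[[1]]; hi <- pg_bounds[[2]]
  if (hi <= lo) return(rep(0, length(nv)))
  pmin(1, pmax(0, (nv - lo) / (hi - lo)))
}

#' Min-max normalised multi-component regulation
#'
#' \eqn{D_i = (NC_i - \min_{TG} NC) / (\max_{TG} NC - \min_{TG} NC)} with
#' the same conventions as [normalize_evidence()], bounds taken over the
#' target-gene set.
#'
#' @param nc Regulating-component count(s), >= 0.
#' @param tg_bounds Numeric `c(min, max)` of `nc` over target genes.
#' @return Value(s) in `[0, 1]`.
#' @export
normalize_regulation <- function(nc, tg_bounds) {
  normalize_evidence(nc, tg_bounds)
}

#' Scoring context for the MTW model
#'
#' Computes the normalisation bounds (min/max `nv` over pathogenic-gene
#' nodes, min/max `nc` over target-gene nodes) and the network averages
#' `r_avg` (mean normalised evidence over PG nodes) and `d_avg` (mean
#' normalised regulation over TG nodes) used as membership corrections.
#'
#' @param graph A [signaling_graph()].
#' @return List of class `score_context` with `pg_bounds`, `tg_bounds`,
#'   `r_avg`, `d_avg`.
#' @export
score_context <- function(graph) {
  nv <- igraph::V(graph)$nv
  nc <- igraph::V(graph)$nc
  pg <- igraph::V(graph)$in_pg
  tg <- igraph::V(graph)$in_tg
  pg_bounds <- if (any(pg)) range(nv[pg]) else c(0, 0)
  tg_bounds <- if (any(tg)) range(nc[tg]) else c(0, 0)
  r_avg <- if (any(pg)) mean(normalize_evidence(nv[pg], pg_bounds)) else 0
  d_avg <- if (any(tg)) mean(normalize_regulation(nc[tg], tg_bounds)) else 0
  structure(list(pg_bounds = pg_bounds, tg_bounds = tg_bounds,
                 r_avg = r_avg, d_avg = d_avg),
            class = "score_context")
}

#' Shortest receptor-to-effector cascades
#'
#' For every (source, sink) pair with a directed route, returns one
#' minimum-weight path (Dijkstra distances; among equal-weight paths the
#' lexicographically smallest node sequence, so results are deterministic).
#' Sources default to in-degree-0 nodes (extracellular receptors — the
#' entry points of drug action), sinks to out-degree-0 nodes (terminal
#' effectors). Unreachable pairs are omitted.
#'
#' @param graph A [signaling_graph()].
#' @param sources,sinks Character vectors of node names, or `NULL` for the
#'   degree-based defaults.
#' @return List of character vectors (node paths, each >= 2 nodes).
#' @export
shortest_cascades <- function(graph, sources = NULL, sinks = NULL) {
  nm <- igraph::V(graph)$name
  if (is.null(sources)) sources <- nm[igraph::degree(graph, mode = "in") == 0]
  if (is.null(sinks)) sinks <- nm[igraph::degree(graph, mode = "out") == 0]
  if (length(sources) == 0L || length(sinks) == 0L) {
    stop("no sources or no sinks", call. = FALSE)
  }
  bad <- setdiff(c(sources, sinks), nm)
  if (length(bad) > 0L) stop("unknown node(s): ", paste(bad, collapse = ", "),
                             call. = FALSE)
  d <- igraph::distances(graph, mode = "out",
                         weights = igraph::E(graph)$weight)
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph), mode = "out")
  names(adj) <- nm
  paths <- list()
  tol <- 1e-9
  for (s in sort(sources)) {
    for (t in sort(sinks)) {
      if (s == t || !is.finite(d[s, t])) next
      path <- s
      cur <- s
      repeat {
        if (cur == t) break
        nb <- igraph::V(graph)$name[as.integer(adj[[cur]])]
        ew <- vapply(nb, function(v) {
          eid <- igraph::get_edge_ids(graph, c(cur, v))
          igraph::E(graph)$weight[eid]
        }, numeric(1))
        ok <- nb[abs(ew + d[nb, t] - d[cur, t]) < tol]
        cur <- sort(ok)[1L]
        path <- c(path, cur)
      }
      paths[[length(paths) + 1L]] <- path
    }
  }
  paths
}

#' Score a cascade with the MTW model
#'
#' Each path node contributes \eqn{IM_i + R_i + D_i \pm R_{avg} \pm
#' D_{avg}}: the \eqn{R_{avg}} correction is added when the node is a
#' pathogenic gene and subtracted otherwise, and the \eqn{D_{avg}}
#' correction is added when the node is a component target and subtracted
#' otherwise. The raw score is the sum over path nodes; the normalised
#' score divides by the node count so cascades of different lengths are
#' comparable.
#'
#' @param path Character vector of node names (>= 2, consecutive nodes must
#'   be connected by directed edges).
#' @param graph The [signaling_graph()] the path lives in.
#' @param context A [score_context()] computed on the same graph.
#' @return List of class `cascade_path`: `path`, `cascade` (the
#'   `"A--B--C"` rendering), `raw`, `score` (normalised), `n_nodes`.
#' @export
score_cascade <- function(path, graph, context) {
  stopifnot(inherits(context, "score_context"), length(path) >= 2L)
  idx <- match(path, igraph::V(graph)$name)
  if (anyNA(idx)) {
    stop("path node(s) absent from graph: ",
         paste(path[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  for (k in seq_len(length(idx) - 1L)) {
    if (igraph::get_edge_ids(graph, c(path[k], path[k + 1L])) == 0) {
      stop(sprintf("no directed edge %s -> %s", path[k], path[k + 1L]),
           call. = FALSE)
    }
  }
  im <- igraph::V(graph)$im[idx]
  if (anyNA(im)) stop("node missing im attribute: ",
                      path[which(is.na(im))[1L]], call. = FALSE)
  r <- normalize_evidence(igraph::V(graph)$nv[idx], context$pg_bounds)
  d <- normalize_regulation(igraph::V(graph)$nc[idx], context$tg_bounds)
  s_pg <- ifelse(igraph::V(graph)$in_pg[idx], 1, -1)
  s_tg <- ifelse(igraph::V(graph)$in_tg[idx], 1, -1)
  terms <- im + r + d + s_pg * context$r_avg + s_tg * context$d_avg
  raw <- sum(terms)
  structure(list(path = path, cascade = paste(path, collapse = "--"),
                 raw = raw, score = raw / length(path),
                 n_nodes = length(path)),
            class = "cascade_path")
}

#' Score all receptor-to-effector cascades
#'
#' Convenience wrapper: enumerates [shortest_cascades()] and scores each
#' with [score_cascade()].
#'
#' @param graph A [signaling_graph()].
#' @param sources,sinks Passed to [shortest_cascades()].
#' @return Data frame of class `cascade_table` with `cascade`, `raw`,
#'   `score`, `n_nodes`, sorted by decreasing normalised score.
#' @export
mtw_cascades <- function(graph, sources = NULL, sinks = NULL) {
  ctx <- score_context(graph)
  paths <- shortest_cascades(graph, sources, sinks)
  rows <- lapply(paths, function(p) {
    sc <- score_cascade(p, graph, ctx)
    data.frame(cascade = sc$cascade, raw = sc$raw, score = sc$score,
               n_nodes = sc$n_nodes, stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(cascade = character(0), raw = numeric(0), score = numeric(0),
               n_nodes = integer(0), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$cascade), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "context") <- ctx
  class(out) <- c("cascade_table", "data.frame")
  out
}

#' Retain high-scoring cascades
#'
#' Keeps cascades whose score is strictly greater than `threshold`, in
#' descending score order (stable for ties).
#'
#' @param cascades A `cascade_table` (or data frame with `cascade` and a
#'   score column).
#' @param threshold Retention cut-off (default 0.7).
#' @param score_column `"score"` (normalised, default) or `"raw"`.
#' @return The retained subset, same class as the input.
#' @export
retain_cascades <- function(cascades, threshold = 0.7,
                            score_column = c("score", "raw")) {
  score_column <- match.arg(score_column)
  keep <- cascades[[score_column]] > threshold
  out <- cascades[keep, , drop = FALSE]
  out <- out[order(-out[[score_column]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge retained cascades into targeting modules
#'
#' Unions the edges of the retained cascades into one directed graph and
#' reports its modules. A terminal effector shared by otherwise unrelated
#' signalling routes (a node that only ever appears as the last element of
#' a cascade) does not, by default, fuse those routes into one module: the
#' backbone components are found with such sinks set aside, and each sink
#' is then attached to every module feeding it. Set `bridge_sinks = TRUE`
#' for plain weakly-connected components.
#'
#' @param retained A `cascade_table` (with `cascade` strings) or a list of
#'   node-path character vectors.
#' @param graph Optional [signaling_graph()] supplying `in_tg`/`in_pg` for
#'   node role labels.
#' @param bridge_sinks Let shared terminal effectors merge modules.
#' @return List of class `cascade_modules`: `modules` (list of node-name
#'   vectors), `n_modules`, `graph` (the union `igraph`), `roles` (named
#'   character vector: `both`, `target_only`, `pathogenic_only`, `other`;
#'   only when `graph` is given).
#' @export
merge_modules <- function(retained, graph = NULL, bridge_sinks = FALSE) {
  paths <- if (is.data.frame(retained)) {
    strsplit(retained$cascade, "--", fixed = TRUE)
  } else {
    retained
  }
  if (length(paths) == 0L) stop("no retained cascades", call. = FALSE)
  edges <- do.call(rbind, lapply(paths, function(p) {
    cbind(p[-length(p)], p[-1L])
  }))
  edges <- unique(edges)
  ug <- igraph::graph_from_edgelist(edges, directed = TRUE)
  terminals <- unique(vapply(paths, function(p) p[length(p)], character(1)))
  interior <- unique(unlist(lapply(paths, function(p) p[-length(p)]),
                            use.names = FALSE))
  sink_only <- setdiff(terminals, interior)
  if (bridge_sinks || length(sink_only) == 0L) {
    comp <- igraph::components(ug, mode = "weak")
    modules <- split(names(comp$membership), comp$membership)
  } else {
    core <- igraph::delete_vertices(ug, sink_only)
    comp <- igraph::components(core, mode = "weak")
    modules <- split(names(comp$membership), comp$membership)
    # attach each sink to every module that feeds it
    for (s in sink_only) {
      feeders <- igraph::V(ug)$name[
        as.integer(igraph::adjacent_vertices(ug, s, mode = "in")[[1]])]
      for (mi in seq_along(modules)) {
        if (length(intersect(feeders, modules[[mi]])) > 0L) {
          modules[[mi]] <- c(modules[[mi]], s)
        }
      }
    }
  }
  modules <- lapply(unname(modules), function(m) sort(unique(m)))
  roles <- NULL
  if (!is.null(graph)) {
    nm <- igraph::V(ug)$name
    idx <- match(nm, igraph::V(graph)$name)
    tg <- igraph::V(graph)$in_tg[idx] %in% TRUE
    pg <- igraph::V(graph)$in_pg[idx] %in% TRUE
    roles <- stats::setNames(
      ifelse(tg & pg, "both",
             ifelse(tg, "target_only",
                    ifelse(pg, "pathogenic_only", "other"))), nm)
  }
  structure(list(modules = modules, n_modules = length(modules),
                 graph = ug, roles = roles),
            class = "cascade_modules")
}

#' @export
print.cascade_modules <- function(x, ...) {
  cat(sprintf("%d cascade targeting module(s):\n", x$n_modules))
  for (i in seq_along(x$modules)) {
    cat(sprintf("  module %d (%d nodes): %s\n", i, length(x$modules[[i]]),
                paste(utils::head(x$modules[[i]], 8), collapse = ", ")))
  }
  invisible(x)
}
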