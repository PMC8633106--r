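#' Coverage/contribution items for component selection
#'
#' For each component with at least one target inside the effective
#' intervention space (EIS), computes the knapsack item
#' \eqn{(w_i, v_i)}: `w` is the fraction of EIS nodes the component targets
#' (its network coverage) and `v` is the fraction of EIS pathogenic genes
#' within one EIS hop of those targets (its contribution rate to pathogenic
#' genes). Components with no EIS target are dropped with a message.
#'
#' @param eis An `eis` object.
#' @param ct_edges Data frame of component-target edges (`from` component,
#'   `to` gene).
#' @param pathogenic_set Character vector of pathogenic gene symbols.
#' @return Data frame with `component_id`, `w`, `v`, and a list column
#'   `eis_targets`.
#' @export
compute_items <- function(eis, ct_edges, pathogenic_set) {
  stopifnot(inherits(eis, "eis"))
  eis_nodes <- eis$nodes
  n_eis <- length(eis_nodes)
  if (n_eis == 0L) stop("empty EIS", call. = FALSE)
  pg_eis <- intersect(pathogenic_set, eis_nodes)
  if (length(pg_eis) == 0L) {
    stop("EIS contains no pathogenic genes; contribution rate undefined",
         call. = FALSE)
  }
  by_comp <- split(as.character(ct_edges$to), as.character(ct_edges$from))
  adj <- igraph::adjacent_vertices(eis$graph, igraph::V(eis$graph))
  adj <- lapply(adj, function(v) igraph::V(eis$graph)$name[as.integer(v)])
  names(adj) <- igraph::V(eis$graph)$name

  ids <- sort(names(by_comp))
  rows <- lapply(ids, function(cid) {
    tg <- intersect(unique(by_comp[[cid]]), eis_nodes)
    if (length(tg) == 0L) return(NULL)
    reach <- unique(c(tg, unlist(adj[tg], use.names = FALSE)))
    v <- length(intersect(reach, pg_eis)) / length(pg_eis)
    data.frame(component_id = cid, w = length(tg) / n_eis, v = v,
               stringsAsFactors = FALSE)
  })
  dropped <- ids[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0L) {
    message(length(dropped), " component(s) with no EIS target dropped")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    stop("no component targets any EIS node", call. = FALSE)
  }
  out$eis_targets <- lapply(out$component_id, function(cid) {
    sort(intersect(unique(by_comp[[cid]]), eis_nodes))
  })
  rownames(out) <- NULL
  out
}

#' 0/1 knapsack component selection
#'
#' Maximises the cumulative contribution \eqn{\sum v_i x_i} subject to the
#' coverage budget \eqn{\sum w_i x_i \le R}, \eqn{x_i \in \{0, 1\}}, by
#' dynamic programming over a discretised weight grid. Weights are scaled by
#' `resolution` and rounded half-up; with integer weights and
#' `resolution = 1` the solution is exact.
#'
#' @param items Data frame with `component_id`, `w` (> 0), `v` (> 0).
#' @param R Coverage budget (> 0), in the same units as `w`.
#' @param resolution Weight grid step (default 1/1000).
#' @return List of class `knapsack_result`: `selected` (component ids),
#'   `objective` (sum of selected `v`), `weight` (sum of selected `w`),
#'   `R`, `resolution`.
#' @export
knapsack_select <- function(items, R, resolution = 1 / 1000) {
  stopifnot(R >= 0, resolution > 0, all(items$w > 0), all(items$v > 0))
  wi <- as.integer(floor(items$w / resolution + 0.5))
  wi[wi < 1L] <- 1L
  cap <- as.integer(floor(R / resolution + 1e-9))
  n <- nrow(items)
  if (cap < 1L || n == 0L) {
    return(structure(list(selected = character(0), objective = 0,
                          weight = 0, R = R, resolution = resolution),
                     class = "knapsack_result"))
  }
  # dp[c+1] = best value at capacity c; keep[i, ] marks item i taken at c
  dp <- numeric(cap + 1L)
  keep <- matrix(FALSE, n, cap + 1L)
  for (i in seq_len(n)) {
    w <- wi[i]
    if (w > cap) next
    idx <- (w + 1L):(cap + 1L)
    cand <- dp[idx - w] + items$v[i]
    take <- cand > dp[idx]
    keep[i, idx] <- take
    dp[idx][take] <- cand[take]
  }
  # backtrack from full capacity
  sel <- logical(n)
  c_left <- cap
  for (i in rev(seq_len(n))) {
    if (c_left >= 0L && keep[i, c_left + 1L]) {
      sel[i] <- TRUE
      c_left <- c_left - wi[i]
    }
  }
  structure(list(selected = items$component_id[sel],
                 objective = sum(items$v[sel]),
                 weight = sum(items$w[sel]), R = R,
                 resolution = resolution),
            class = "knapsack_result")
}

#' Greedy accumulative coverage curve
#'
#' Orders components by largest marginal gain in EIS-node coverage
#' (|union of selected components' EIS targets| / |EIS|), ties broken
#' lexicographically by component id, and records the cumulative coverage
#' after each addition. This is the accumulative cumulative-contribution
#' curve from which the core group of functional components is read off.
#'
#' @param items Output of [compute_items()] (needs the `eis_targets` list
#'   column).
#' @param eis The `eis` object the items were computed on.
#' @return A data frame of class `cgfc_curve` with `step`, `component_id`,
#'   `marginal_gain`, `cumulative_coverage`; attribute `n_eis`.
#' @export
greedy_coverage_curve <- function(items, eis) {
  n_eis <- length(eis$nodes)
  remaining <- items
  covered <- character(0)
  steps <- vector("list", nrow(items))
  for (s in seq_len(nrow(items))) {
    gains <- vapply(remaining$eis_targets, function(tg) {
      length(setdiff(tg, covered))
    }, integer(1))
    best <- max(gains)
    pick <- which(gains == best)
    # deterministic: lexicographically smallest id among maximal gains
    pick <- pick[order(remaining$component_id[pick])][1L]
    covered <- union(covered, remaining$eis_targets[[pick]])
    steps[[s]] <- data.frame(step = s,
                             component_id = remaining$component_id[pick],
                             marginal_gain = best / n_eis,
                             cumulative_coverage = length(covered) / n_eis,
                             stringsAsFactors = FALSE)
    remaining <- remaining[-pick, , drop = FALSE]
  }
  out <- do.call(rbind, steps)
  attr(out, "n_eis") <- n_eis
  class(out) <- c("cgfc_curve", "data.frame")
  out
}

#' Select the core group of functional components
#'
#' Reads the shortest prefix of the greedy coverage curve whose cumulative
#' EIS coverage reaches `threshold`. If the threshold is unreachable, all
#' components with positive marginal gain are returned with a warning.
#'
#' @param curve A `cgfc_curve` from [greedy_coverage_curve()].
#' @param threshold Coverage target in (0, 1]; default 0.95.
#' @return A list of class `cgfc_selection`: `selected` (component ids, in
#'   greedy order), `coverage` (achieved cumulative coverage), `threshold`,
#'   `curve`.
#' @export
select_cgfc <- function(curve, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  hit <- which(curve$cumulative_coverage >= threshold)
  if (length(hit) == 0L) {
    warning(sprintf("threshold %.3f unreachable (max coverage %.3f); %s",
                    threshold, max(curve$cumulative_coverage),
                    "returning all contributing components"), call. = FALSE)
    sel <- curve[curve$marginal_gain > 0, , drop = FALSE]
  } else {
    sel <- curve[seq_len(hit[1L]), , drop = FALSE]
  }
  structure(list(selected = sel$component_id,
                 coverage = sel$cumulative_coverage[nrow(sel)],
                 threshold = threshold, curve = curve),
            class = "cgfc_selection")
}

#' @export
print.cgfc_selection <- function(x, ...) {
  cat(sprintf("CGFC: %d components, cumulative EIS coverage %.2f%% (threshold %.0f%%)\n",
              length(x$selected), 100 * x$coverage, 100 * x$threshold))
  cat("  first components:",
      paste(utils::head(x$selected, 8), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.knapsack_result <- function(x, ...) {
  cat(sprintf("knapsack selection: %d items, objective %.4f, weight %.4f / budget %.4f\n",
              length(x$selected), x$objective, x$weight, x$R))
  invisible(x)
}
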