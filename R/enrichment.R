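#' Hypergeometric over-representation analysis
#'
#' Tests each gene set of a collection for over-representation in a query
#' gene list. For a universe of N genes, a set of K genes and a query of n
#' genes with k overlapping, the p-value is the upper tail
#' \eqn{P(X \ge k)} of the hypergeometric distribution. Query genes outside
#' the universe are dropped with a warning. Benjamini-Hochberg adjusted
#' p-values are reported alongside; significance follows the raw p-value by
#' default (`adjust = FALSE`), the adjusted one otherwise.
#'
#' @param query Character vector of gene symbols.
#' @param collection A `gene_set_collection` (see [read_gmt()]).
#' @param universe Background gene symbols; defaults to the union of all
#'   collection genes.
#' @param alpha Significance cut-off (default 0.05).
#' @param adjust Use BH-adjusted p-values for the significance flag.
#' @return Data frame of class `enrichment_result` with `term`,
#'   `description`, `k`, `K`, `n`, `N`, `p`, `p_adj`, `significant`,
#'   ordered by increasing `p`.
#' @export
enrich <- function(query, collection, universe = NULL, alpha = 0.05,
                   adjust = FALSE) {
  if (is.null(universe)) {
    universe <- unique(unlist(collection, use.names = FALSE))
  }
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)
  descs <- attr(collection, "descriptions")
  rows <- lapply(names(collection), function(term) {
    set <- intersect(unique(collection[[term]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term,
               description = if (!is.null(descs)) descs[[term]] else term,
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- if (adjust) out$p_adj < alpha else out$p < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Term coverage of a candidate list over a reference list
#'
#' The fraction of reference terms also present in the candidate list:
#' `|reference intersect candidate| / |reference|`.
#'
#' @param reference Character vector of term ids (non-empty).
#' @param candidate Character vector of term ids.
#' @return A fraction in `[0, 1]`.
#' @export
term_coverage <- function(reference, candidate) {
  reference <- unique(as.character(reference))
  if (length(reference) == 0L) stop("empty reference term list", call. = FALSE)
  length(intersect(reference, unique(as.character(candidate)))) /
    length(reference)
}

#' Compare node-scoring methods by functional coverage
#'
#' Benchmarks the transit-path importance score against the baseline
#' centralities: each method scores the T-P graph, the above-median nodes
#' are kept, the kept genes are enriched against the collection, and the
#' significant terms are compared (as [term_coverage()]) with a reference
#' term list — the terms significantly enriched by *both* the full target
#' list and the pathogenic genes, i.e. the functional ground the
#' intervention is supposed to cover.
#'
#' @param tp_graph The T-P `igraph`.
#' @param methods Subset of `c("im", "degree", "betweenness", "closeness",
#'   "clustering", "neighborhood_connectivity")`.
#' @param target_genes Character vector: all component-target genes.
#' @param pathogenic_genes Character vector of pathogenic gene symbols.
#' @param collection A `gene_set_collection`.
#' @param alpha Significance cut-off for every enrichment run.
#' @return Data frame with `method`, `n_kept`, `n_terms`, `coverage`,
#'   ordered by decreasing coverage; attribute `reference_terms`.
#' @export
compare_importance_methods <- function(tp_graph,
                                       methods = c("im", "degree",
                                                   "betweenness", "closeness",
                                                   "clustering",
                                                   "neighborhood_connectivity"),
                                       target_genes, pathogenic_genes,
                                       collection, alpha = 0.05) {
  methods <- match.arg(methods, several.ok = TRUE)
  tab <- node_importance(tp_graph)
  sig_terms <- function(genes) {
    res <- enrich(genes, collection, alpha = alpha)
    res$term[res$significant]
  }
  reference <- intersect(
    sig_terms(intersect(target_genes, igraph::V(tp_graph)$name)),
    sig_terms(intersect(pathogenic_genes, igraph::V(tp_graph)$name))
  )
  if (length(reference) == 0L) {
    stop("no common significant terms between targets and pathogenic genes",
         call. = FALSE)
  }
  rows <- lapply(methods, function(m) {
    score <- tab[[m]]
    kept <- tab$node[score > stats::median(score)]
    terms <- if (length(kept) > 0L) sig_terms(kept) else character(0)
    data.frame(method = m, n_kept = length(kept), n_terms = length(terms),
               coverage = if (length(kept) > 0L)
                 term_coverage(reference, terms) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$coverage, out$method), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_terms") <- reference
  out
}
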