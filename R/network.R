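#' Build the component-target network
#'
#' Creates the bipartite component-target (C-T) layer of the CTPD network.
#' Every edge endpoint on the component side must exist in `components`;
#' targets are created from the edge list. Each target node carries `nc`,
#' the number of distinct components predicted to regulate it.
#'
#' @param components A `component_table` (or any data frame with an `id`
#'   column listing the screened components).
#' @param ct_edges A data frame with `from` (component id) and `to` (target
#'   gene symbol); see [read_edges()].
#' @return A `ctpd_network`: a list with the `igraph` object (`graph`),
#'   vertex roles as boolean attributes `is_component`, `is_target`,
#'   `is_pathogenic`, `is_disease`, and edge attribute `type` (here `"CT"`).
#' @export
build_ct_network <- function(components, ct_edges) {
  comp_ids <- unique(as.character(components$id))
  unknown <- setdiff(unique(ct_edges$from), comp_ids)
  if (length(unknown) > 0L) {
    stop("C-T edges reference unknown component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  edges <- unique(data.frame(from = as.character(ct_edges$from),
                             to = as.character(ct_edges$to),
                             stringsAsFactors = FALSE))
  overlap <- intersect(comp_ids, unique(edges$to))
  if (length(overlap) > 0L) {
    stop("id(s) used both as component and target: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  targets <- sort(unique(edges$to))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(comp_ids), name = comp_ids,
                            is_component = TRUE, is_target = FALSE,
                            is_pathogenic = FALSE, is_disease = FALSE)
  if (length(targets) > 0L) {
    g <- igraph::add_vertices(g, length(targets), name = targets,
                              is_component = FALSE, is_target = TRUE,
                              is_pathogenic = FALSE, is_disease = FALSE)
  }
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to), type = "CT")
  }
  nc <- table(edges$to)
  igraph::V(g)$nc <- as.integer(nc[igraph::V(g)$name])
  igraph::V(g)$nc[igraph::V(g)$is_component] <- NA_integer_
  igraph::V(g)$nv <- NA_real_
  structure(list(graph = g, disease = NULL,
                 n_components = length(comp_ids), n_targets = length(targets)),
            class = "ctpd_network")
}

#' Assemble the full CTPD network
#'
#' Overlays protein-protein interaction (PPI) edges and literature-supported
#' pathogenic genes onto a C-T layer and attaches a single disease node. PPI
#' edges are kept only when both endpoints are already present as target or
#' pathogenic gene nodes (set `expand_ppi = TRUE` to also admit first
#' neighbours of those genes); unmatched rows are counted, not fatal. Every
#' pathogenic gene is linked to the disease node by a gene-disease (GD)
#' edge. A gene may be both a target and a pathogenic gene; roles are
#' unioned. The graph is kept simple: a duplicate edge keeps the strongest
#' type by the precedence CT > GD > PPI.
#'
#' @param ct_net A `ctpd_network` from [build_ct_network()].
#' @param ppi_edges Data frame with `from`/`to` gene symbols (undirected).
#' @param pathogenic_genes Data frame with `symbol` and `nv` (evidence
#'   counts), see [read_pathogenic_table()].
#' @param disease_label Name for the disease node.
#' @param expand_ppi Admit PPI edges touching one known gene, creating the
#'   other endpoint as a plain gene node (off by default).
#' @return The augmented `ctpd_network`.
#' @export
assemble_ctpd <- function(ct_net, ppi_edges, pathogenic_genes,
                          disease_label = "disease", expand_ppi = FALSE) {
  stopifnot(inherits(ct_net, "ctpd_network"))
  g <- ct_net$graph
  if (disease_label %in% igraph::V(g)$name) {
    stop("disease label collides with an existing node", call. = FALSE)
  }
  path_syms <- as.character(pathogenic_genes$symbol)
  nv <- as.numeric(pathogenic_genes$nv)

  new_path <- setdiff(path_syms, igraph::V(g)$name)
  if (length(new_path) > 0L) {
    g <- igraph::add_vertices(g, length(new_path),
                              attr = list(name = new_path,
                                          is_component = FALSE,
                                          is_target = FALSE,
                                          is_pathogenic = FALSE,
                                          is_disease = FALSE,
                                          nc = NA_integer_, nv = NA_real_))
  }
  idx <- match(path_syms, igraph::V(g)$name)
  if (any(igraph::V(g)$is_component[idx])) {
    stop("pathogenic gene symbol collides with a component id", call. = FALSE)
  }
  g <- igraph::set_vertex_attr(g, "is_pathogenic", index = idx, value = TRUE)
  g <- igraph::set_vertex_attr(g, "nv", index = idx, value = nv)

  n_unmatched <- 0L
  if (!is.null(ppi_edges) && nrow(ppi_edges) > 0L) {
    pe <- data.frame(from = as.character(ppi_edges$from),
                     to = as.character(ppi_edges$to),
                     stringsAsFactors = FALSE)
    pe <- pe[pe$from != pe$to, , drop = FALSE]
    gene_names <- igraph::V(g)$name[igraph::V(g)$is_target |
                                    igraph::V(g)$is_pathogenic]
    known_f <- pe$from %in% gene_names
    known_t <- pe$to %in% gene_names
    keep <- if (expand_ppi) known_f | known_t else known_f & known_t
    n_unmatched <- sum(!keep)
    pe <- pe[keep, , drop = FALSE]
    if (expand_ppi && nrow(pe) > 0L) {
      extra <- setdiff(unique(c(pe$from, pe$to)), igraph::V(g)$name)
      if (length(extra) > 0L) {
        g <- igraph::add_vertices(g, length(extra),
                                  attr = list(name = extra,
                                              is_component = FALSE,
                                              is_target = FALSE,
                                              is_pathogenic = FALSE,
                                              is_disease = FALSE,
                                              nc = NA_integer_,
                                              nv = NA_real_))
      }
    }
    if (nrow(pe) > 0L) {
      # canonical undirected key for dedup against existing edges
      key <- paste(pmin(pe$from, pe$to), pmax(pe$from, pe$to), sep = "\r")
      pe <- pe[!duplicated(key), , drop = FALSE]
      key <- key[!duplicated(key)]
      ex <- igraph::as_edgelist(g)
      if (nrow(ex) > 0L) {
        exkey <- paste(pmin(ex[, 1], ex[, 2]), pmax(ex[, 1], ex[, 2]),
                       sep = "\r")
        pe <- pe[!(key %in% exkey), , drop = FALSE]
      }
      if (nrow(pe) > 0L) {
        g <- igraph::add_edges(g, rbind(pe$from, pe$to), type = "PPI")
      }
    }
  }

  g <- igraph::add_vertices(g, 1L,
                            attr = list(name = disease_label,
                                        is_component = FALSE,
                                        is_target = FALSE,
                                        is_pathogenic = FALSE,
                                        is_disease = TRUE,
                                        nc = NA_integer_, nv = NA_real_))
  if (length(path_syms) > 0L) {
    g <- igraph::add_edges(g, rbind(path_syms, rep(disease_label,
                                                   length(path_syms))),
                           type = "GD")
  }
  out <- ct_net
  out$graph <- g
  out$disease <- disease_label
  out$n_pathogenic <- length(path_syms)
  out$n_unmatched_ppi <- n_unmatched
  if (n_unmatched > 0L) {
    message(n_unmatched, " PPI edge(s) with unmatched endpoint(s) skipped")
  }
  out
}

#' Extract the target-pathogenic-gene subnetwork
#'
#' The T-P subnetwork is the induced subgraph on all genes that are targets
#' and/or pathogenic genes, keeping only PPI edges. Components and the
#' disease node are removed. Node importance (and hence the effective
#' intervention space) is computed on this graph.
#'
#' @param ctpd A `ctpd_network` from [assemble_ctpd()].
#' @return An `igraph` with the inherited `is_target`, `is_pathogenic`,
#'   `nv`, `nc` vertex attributes.
#' @export
extract_tp <- function(ctpd) {
  stopifnot(inherits(ctpd, "ctpd_network"))
  g <- ctpd$graph
  keep <- igraph::V(g)[igraph::V(g)$is_target | igraph::V(g)$is_pathogenic]
  if (length(keep) == 0L) stop("no gene layer: no target or pathogenic nodes",
                               call. = FALSE)
  sub <- igraph::induced_subgraph(g, keep)
  drop <- igraph::E(sub)[igraph::E(sub)$type != "PPI"]
  sub <- igraph::delete_edges(sub, drop)
  sub
}

#' Profile literature evidence across bins
#'
#' Bins pathogenic genes by their evidence count `nv` into disjoint
#' half-open intervals `[b_i, b_{i+1})` and reports, per bin, the gene count
#' and the mean number of gene-set terms (e.g. pathways or GO terms) that
#' contain each gene.
#'
#' @param pathogenic_genes Data frame with `symbol` and `nv`.
#' @param collection A `gene_set_collection` (may be empty `list()` wrapped
#'   by class, or `NULL` for counts only).
#' @param breaks Increasing numeric vector of bin edges; the last bin is
#'   `[breaks[k], Inf)` unless `Inf` is supplied explicitly.
#' @return Data frame with `bin`, `lower`, `upper`, `n_genes`, `mean_terms`.
#' @export
bin_evidence_profile <- function(pathogenic_genes, collection = NULL,
                                 breaks = c(1, 2, 3, 5, 10, 15, 20, 40, Inf)) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing (disjoint half-open bins)",
         call. = FALSE)
  }
  if (!is.infinite(breaks[length(breaks)])) breaks <- c(breaks, Inf)
  nv <- pathogenic_genes$nv
  if (any(nv < breaks[1])) {
    stop("evidence counts below the first bin edge", call. = FALSE)
  }
  bin_idx <- findInterval(nv, breaks)  # half-open [b_i, b_{i+1})
  term_count <- rep(0, nrow(pathogenic_genes))
  if (!is.null(collection) && length(collection) > 0L) {
    membership <- table(unlist(lapply(collection, unique), use.names = FALSE))
    hit <- membership[pathogenic_genes$symbol]
    term_count <- ifelse(is.na(hit), 0, as.numeric(hit))
  }
  k <- length(breaks) - 1L
  out <- data.frame(
    bin = sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1]),
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    n_genes = vapply(seq_len(k), function(i) sum(bin_idx == i), integer(1)),
    mean_terms = vapply(seq_len(k), function(i) {
      sel <- bin_idx == i
      if (!any(sel)) 0 else mean(term_count[sel])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  out
}

#' @export
print.ctpd_network <- function(x, ...) {
  g <- x$graph
  cat("CTPD network:", igraph::vcount(g), "nodes,", igraph::ecount(g),
      "edges\n")
  cat(sprintf("  components: %d  targets: %d  pathogenic: %d%s\n",
              sum(igraph::V(g)$is_component), sum(igraph::V(g)$is_target),
              sum(igraph::V(g)$is_pathogenic),
              if (!is.null(x$disease)) paste0("  disease: ", x$disease) else ""))
  if (igraph::ecount(g) > 0L) {
    tt <- table(igraph::E(g)$type)
    cat("  edges:", paste(sprintf("%s=%d", names(tt), tt), collapse = "  "),
        "\n")
  }
  invisible(x)
}
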