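#' Run the full screening-to-mechanism pipeline
#'
#' Chains every stage on a set of input files or on an in-memory
#' [generate_bundle()] object: ADME screening, C-T network assembly, CTPD
#' overlay, T-P extraction, node importance, effective intervention space,
#' greedy CGFC selection, MTW cascade scoring, and enrichment of the
#' intervention-response proteins. Any stage failure aborts with the stage
#' name; artefacts computed so far are kept in the returned (partial)
#' manifest environment's error message.
#'
#' @param input Either a `synthetic_bundle` or a named list of file paths:
#'   `components`, `ct_edges`, `ppi`, `pathogenic`, `gmt`, and optionally
#'   `signaling`, `signaling_tg`, `signaling_nc`.
#' @param rules An [adme_rules()] object.
#' @param disease Disease node label.
#' @param coverage_threshold CGFC stopping coverage (default 0.95).
#' @param mtw_threshold Cascade retention cut-off (default 0.7).
#' @param alpha Enrichment significance cut-off.
#' @param out_dir Optional directory; when given, the stage outputs and a
#'   run manifest are serialised there (TSV/JSON).
#' @return A list of class `netpharm_run` with every stage's result
#'   (`screen`, `ctpd`, `tp`, `importance`, `eis`, `categories`, `items`,
#'   `curve`, `cgfc`, `cascades`, `retained`, `modules`, `enrichment`)
#'   and a `manifest` of per-stage counts.
#' @export
run_pipeline <- function(input, rules = adme_rules(), disease = "disease",
                         coverage_threshold = 0.95, mtw_threshold = 0.7,
                         alpha = 0.05, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (inherits(input, "synthetic_bundle")) {
    comp <- input$components
    class(comp) <- c("component_table", "data.frame")
    ct_edges <- input$ct_edges
    ppi <- input$ppi_edges
    pathogenic <- input$pathogenic
    collection <- input$collection
    sig_edges <- input$signaling
    sig_tg <- input$signaling_tg
    sig_nc <- input$signaling_nc
    sig_pg <- input$signaling_pg
  } else {
    needed <- c("components", "ct_edges", "ppi", "pathogenic", "gmt")
    missing <- setdiff(needed, names(input))
    if (length(missing) > 0L) {
      stop("input list missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    for (f in unlist(input[names(input) != ""])) {
      if (is.character(f) && !file.exists(f)) {
        stop("input file not found: ", f, call. = FALSE)
      }
    }
    comp <- stage("read", read_component_table(input$components))
    ct_edges <- stage("read", read_edges(input$ct_edges))
    ppi <- stage("read", read_edges(input$ppi))
    pathogenic <- stage("read", read_pathogenic_table(input$pathogenic))
    collection <- stage("read", read_gmt(input$gmt))
    sig_edges <- if (!is.null(input$signaling))
      stage("read", read_edges(input$signaling)) else NULL
    sig_tg <- if (!is.null(input$signaling_tg))
      readLines(input$signaling_tg, warn = FALSE) else NULL
    sig_nc <- if (!is.null(input$signaling_nc)) {
      df <- read_tsv_checked(input$signaling_nc)
      df$nc <- as.numeric(df$nc)
      df
    } else NULL
    sig_pg <- pathogenic
  }

  scr <- stage("screen", screen_components(comp, rules))
  kept_ids <- scr$kept$id
  ct_kept <- ct_edges[ct_edges$from %in% kept_ids, , drop = FALSE]

  ctnet <- stage("build-net", build_ct_network(scr$kept, ct_kept))
  ctpd <- stage("build-net",
                assemble_ctpd(ctnet, ppi, pathogenic, disease_label = disease))
  tp <- stage("build-net", extract_tp(ctpd))

  imp <- stage("importance", node_importance(tp))
  eis <- stage("eis", extract_eis(tp, imp))
  target_genes <- unique(ct_kept$to)
  categories <- stage("eis", categorize_nodes(eis, target_genes,
                                              pathogenic$symbol))

  items <- stage("cgfc", compute_items(eis, ct_kept, pathogenic$symbol))
  curve <- stage("cgfc", greedy_coverage_curve(items, eis))
  cgfc <- stage("cgfc", select_cgfc(curve, coverage_threshold))

  cascades <- retained <- modules <- NULL
  if (!is.null(sig_edges)) {
    sg <- stage("mtw", signaling_graph(
      sig_edges,
      tg = sig_tg %||% target_genes,
      pg = sig_pg[, c("symbol", "nv")],
      nc = sig_nc))
    cascades <- stage("mtw", mtw_cascades(sg))
    retained <- stage("mtw", retain_cascades(cascades, mtw_threshold))
    if (nrow(retained) > 0L) {
      modules <- stage("mtw", merge_modules(retained, graph = sg))
    }
  }

  enr <- stage("enrich", enrich(eis$nodes, collection, alpha = alpha))

  manifest <- list(
    n_components = nrow(comp),
    n_kept = nrow(scr$kept),
    n_ct_edges = nrow(ct_kept),
    ctpd_nodes = igraph::vcount(ctpd$graph),
    ctpd_edges = igraph::ecount(ctpd$graph),
    tp_nodes = igraph::vcount(tp),
    tp_edges = igraph::ecount(tp),
    effective_diameter = attr(imp, "diameter"),
    im_median = attr(imp, "im_median"),
    eis_nodes = igraph::vcount(eis$graph),
    eis_edges = igraph::ecount(eis$graph),
    category_counts = as.list(table(categories)),
    n_items = nrow(items),
    cgfc_size = length(cgfc$selected),
    cgfc_coverage = cgfc$coverage,
    n_cascades = if (is.null(cascades)) 0L else nrow(cascades),
    n_retained = if (is.null(retained)) 0L else nrow(retained),
    n_modules = if (is.null(modules)) 0L else modules$n_modules,
    n_significant_terms = sum(enr$significant),
    parameters = list(coverage_threshold = coverage_threshold,
                      mtw_threshold = mtw_threshold, alpha = alpha)
  )
  run <- structure(list(screen = scr, ctpd = ctpd, tp = tp,
                        importance = imp, eis = eis,
                        categories = categories, items = items,
                        curve = curve, cgfc = cgfc, cascades = cascades,
                        retained = retained, modules = modules,
                        enrichment = enr, manifest = manifest),
                   class = "netpharm_run")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(imp, file.path(out_dir, "importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(nodes = eis$nodes,
                              threshold = eis$threshold,
                              categories = as.list(categories)),
                         file.path(out_dir, "eis.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(selected = cgfc$selected,
                              coverage = cgfc$coverage,
                              curve = cgfc$curve),
                         file.path(out_dir, "cgfc.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(retained)) {
      jsonlite::write_json(retained, file.path(out_dir, "cascades.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.netpharm_run <- function(x, ...) {
  m <- x$manifest
  cat("netpharm pipeline run\n")
  cat(sprintf("  screen:     %d / %d components kept\n", m$n_kept,
              m$n_components))
  cat(sprintf("  CTPD:       %d nodes, %d edges (T-P: %d / %d)\n",
              m$ctpd_nodes, m$ctpd_edges, m$tp_nodes, m$tp_edges))
  cat(sprintf("  EIS:        %d nodes, %d edges (median IM %.4g)\n",
              m$eis_nodes, m$eis_edges, m$im_median))
  cat(sprintf("  CGFC:       %d components, coverage %.2f%%\n",
              m$cgfc_size, 100 * m$cgfc_coverage))
  if (m$n_cascades > 0) {
    cat(sprintf("  MTW:        %d cascades, %d retained, %d module(s)\n",
                m$n_cascades, m$n_retained, m$n_modules))
  }
  cat(sprintf("  enrichment: %d significant term(s)\n",
              m$n_significant_terms))
  invisible(x)
}
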