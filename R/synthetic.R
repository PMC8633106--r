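#' Parameters for the synthetic formula-to-disease bundle
#'
#' Collects the knobs of [generate_bundle()]. The defaults produce a small
#' but complete toy system — seven herbs, 200 components, 300 genes — so
#' the full pipeline runs in seconds. The gene layer is a hub-and-spoke
#' protein-interaction graph (a planted core-periphery structure whose
#' degree distribution is heavy-tailed, the feature of real interactomes
#' the pipeline is sensitive to): `n_hubs` hub genes on a backbone path,
#' each carrying `leaves_per_hub` spoke genes. Hubs are the planted
#' intervention-response proteins. A designated set of `cover_size`
#' components partitions the hubs between them (the planted minimal
#' cover); decoy components target spoke genes and, for a few of them, one
#' hub of the largest cover group, so the greedy selection has ties and
#' zero-gain steps to resolve.
#'
#' @param n_herbs Number of herbs in the formula.
#' @param n_components Number of components across herbs.
#' @param n_hubs Number of hub genes (planted intervention-response set).
#' @param leaves_per_hub Spoke genes per hub.
#' @param cover_size Number of components in the planted minimal cover.
#' @param pathogenic_frac Fraction of genes carrying disease evidence.
#' @param nv_alpha Pareto tail exponent for evidence counts (> 1; smaller
#'   means heavier tail).
#' @param adme_violation_rate Per-rule fraction of screenable components
#'   given a violating property value (planted outside the cover set).
#' @param n_noise_sets Random gene sets added to the planted per-hub-module
#'   terms in the GMT collection.
#' @param targets_per_decoy Spoke genes targeted by each non-cover
#'   component.
#' @param chain_length Nodes in the planted high-score signalling chain.
#' @param n_background_signaling Nodes in the background signalling DAG.
#' @return A list of class `bundle_params`.
#' @export
bundle_params <- function(n_herbs = 7, n_components = 200, n_hubs = 15,
                          leaves_per_hub = 19, cover_size = 7,
                          pathogenic_frac = 0.4, nv_alpha = 2.5,
                          adme_violation_rate = 0.1, n_noise_sets = 10,
                          targets_per_decoy = 6, chain_length = 5,
                          n_background_signaling = 30) {
  p <- as.list(environment())
  if (p$cover_size > p$n_components) {
    stop("cover_size exceeds n_components", call. = FALSE)
  }
  if (p$cover_size > p$n_hubs) {
    stop("cover_size exceeds n_hubs: cannot partition hubs", call. = FALSE)
  }
  if (p$nv_alpha <= 1) stop("nv_alpha must be > 1", call. = FALSE)
  structure(p, class = "bundle_params")
}

# One global seed fans out to independent per-section seeds so adding a
# section never perturbs the draws of earlier ones.
derive_seed <- function(seed, section) {
  (as.integer(seed) * 257L + section * 1009L) %% 2147483647L
}

# Discrete Pareto-ish evidence counts, >= 1.
rnv <- function(n, alpha) {
  pmin(100L, as.integer(floor(stats::runif(n)^(-1 / (alpha - 1)))))
}

#' Generate a synthetic formula-to-disease bundle
#'
#' Produces every input layer the pipeline reads — component property
#' table, herb membership, component-target edges, protein-interaction
#' edges, pathogenic-gene evidence table, a GMT collection, and a directed
#' signalling graph — together with a ledger of all planted ground truths
#' (the hub set, the minimal cover, the per-hub module memberships, the
#' top signalling chain, and per-component ADME violations). Regenerating
#' with the same seed and parameters is deterministic; when `dir` is given
#' the bundle is also written as the same TSV/GMT files the readers
#' consume, byte-identically across runs.
#'
#' @param params A [bundle_params()] list.
#' @param seed Integer seed.
#' @param dir Optional output directory (created if missing).
#' @return A list of class `synthetic_bundle` with elements `components`,
#'   `ct_edges`, `ppi_edges`, `pathogenic`, `collection`, `signaling`
#'   (edge table), `signaling_tg`, `signaling_pg`, `signaling_nc`, and
#'   `ledger`.
#' @export
generate_bundle <- function(params = bundle_params(), seed = 1, dir = NULL) {
  stopifnot(inherits(params, "bundle_params"))

  ## gene layer: hub backbone path + spokes -------------------------------
  hubs <- sprintf("HUB%02d", seq_len(params$n_hubs))
  leaves <- unlist(lapply(seq_len(params$n_hubs), function(h) {
    sprintf("G%02dL%02d", h, seq_len(params$leaves_per_hub))
  }), use.names = FALSE)
  genes <- c(hubs, leaves)
  ppi <- rbind(
    if (params$n_hubs > 1)
      data.frame(from = hubs[-params$n_hubs], to = hubs[-1],
                 stringsAsFactors = FALSE)
    else NULL,
    data.frame(from = rep(hubs, each = params$leaves_per_hub), to = leaves,
               stringsAsFactors = FALSE)
  )

  ## pathogenic genes ------------------------------------------------------
  set.seed(derive_seed(seed, 1L))
  n_path <- max(1L, round(params$pathogenic_frac * length(genes)))
  # all hubs carry evidence (they are the planted disease core); the rest
  # of the pathogenic set is drawn from the spokes
  n_leaf_path <- max(0L, n_path - length(hubs))
  path_syms <- c(hubs, sort(sample(leaves, min(n_leaf_path, length(leaves)))))
  pathogenic <- data.frame(symbol = path_syms,
                           nv = rnv(length(path_syms), params$nv_alpha),
                           stringsAsFactors = FALSE)

  ## components, herbs, ADME properties ------------------------------------
  set.seed(derive_seed(seed, 2L))
  comp_ids <- sprintf("CMP%03d", seq_len(params$n_components))
  cover_ids <- comp_ids[seq_len(params$cover_size)]
  herbs <- sprintf("HB%d", seq_len(params$n_herbs))
  herb_of <- vapply(seq_len(params$n_components), function(i) {
    k <- sample(1:2, 1)
    paste(sort(sample(herbs, k)), collapse = ",")
  }, character(1))
  n <- params$n_components
  comp <- data.frame(
    id = comp_ids,
    name = paste0("compound-", comp_ids),
    herbs = herb_of,
    mw = round(stats::runif(n, 150, 480), 2),
    hdon = sample(0:5, n, replace = TRUE),
    hacc = sample(0:10, n, replace = TRUE),
    rbn = sample(0:10, n, replace = TRUE),
    logp = round(stats::runif(n, -1.9, 4.9), 2),
    ob = round(stats::runif(n, 30, 100), 2),
    gi_class = sample(c("high", "unknown"), n, replace = TRUE,
                      prob = c(0.9, 0.1)),
    herg_class = sample(c("low", "medium", "unknown"), n, replace = TRUE,
                        prob = c(0.7, 0.2, 0.1)),
    carcinogenicity = sample(c("negative", "unknown"), n, replace = TRUE,
                             prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE
  )
  # plant per-rule violations on non-cover components only, so the planted
  # cover always survives screening
  violators <- list()
  eligible <- setdiff(comp_ids, cover_ids)
  n_violate <- round(params$adme_violation_rate * n)
  plant <- function(rule, column, values) {
    ids <- sort(sample(eligible, min(n_violate, length(eligible))))
    comp[[column]][match(ids, comp$id)] <<- values(length(ids))
    violators[[rule]] <<- ids
  }
  if (n_violate > 0L && length(eligible) > 0L) {
    plant("mw", "mw", function(k) round(stats::runif(k, 510, 900), 2))
    plant("hdon", "hdon", function(k) sample(6:10, k, replace = TRUE))
    plant("hacc", "hacc", function(k) sample(11:15, k, replace = TRUE))
    plant("rbn", "rbn", function(k) sample(11:18, k, replace = TRUE))
    plant("logp", "logp", function(k) round(stats::runif(k, 5.1, 8), 2))
    plant("ob", "ob", function(k) round(stats::runif(k, 1, 29.5), 2))
  }
  violated_any <- sort(unique(unlist(violators, use.names = FALSE)))
  kept_ids <- setdiff(comp_ids, violated_any)

  ## component-target edges -------------------------------------------------
  set.seed(derive_seed(seed, 3L))
  # planted cover: partition hubs into cover_size groups with decreasing size
  grp <- sort(rep_len(seq_len(params$cover_size), params$n_hubs))
  hub_groups <- split(hubs, grp)
  sizes <- lengths(hub_groups)
  hub_groups <- hub_groups[order(-sizes, names(hub_groups))]
  ct <- list()
  for (i in seq_len(params$cover_size)) {
    tg <- c(hub_groups[[i]],
            sample(leaves, params$targets_per_decoy))
    ct[[length(ct) + 1L]] <- data.frame(from = cover_ids[i], to = unique(tg),
                                        stringsAsFactors = FALSE)
  }
  decoys <- setdiff(kept_ids, cover_ids)
  biggest_group <- hub_groups[[1]]
  for (j in seq_along(decoys)) {
    tg <- sample(leaves, params$targets_per_decoy)
    if (j <= 5L) tg <- c(tg, sample(biggest_group, 1))  # hub-targeting decoys
    ct[[length(ct) + 1L]] <- data.frame(from = decoys[j], to = unique(tg),
                                        stringsAsFactors = FALSE)
  }
  ct_edges <- do.call(rbind, ct)

  ## GMT collection: one planted term per hub module + noise ----------------
  set.seed(derive_seed(seed, 4L))
  sets <- lapply(seq_len(params$n_hubs), function(h) {
    c(hubs[h], leaves[((h - 1) * params$leaves_per_hub + 1):
                      (h * params$leaves_per_hub)])
  })
  names(sets) <- sprintf("MODULE%02d", seq_len(params$n_hubs))
  noise <- lapply(seq_len(params$n_noise_sets), function(i) {
    sort(sample(genes, sample(8:25, 1)))
  })
  names(noise) <- sprintf("NOISE%02d", seq_len(params$n_noise_sets))
  sets <- c(sets, noise)
  collection <- structure(sets,
                          descriptions = stats::setNames(
                            paste("synthetic set", names(sets)), names(sets)),
                          collection = "synthetic", class = "gene_set_collection")

  ## signalling graph -------------------------------------------------------
  signaling <- generate_signaling(params, seed)

  ledger <- list(
    seed = seed,
    n_genes = length(genes),
    n_ppi_edges = nrow(ppi),
    planted_hubs = hubs,
    planted_cover = cover_ids,
    planted_modules = stats::setNames(
      lapply(seq_len(params$n_hubs), function(h) sets[[h]]),
      names(sets)[seq_len(params$n_hubs)]),
    adme_violators = violators,
    adme_kept = kept_ids,
    planted_cover_coverage = 1.0,
    planted_chain = signaling$planted_chain,
    pathogenic_symbols = pathogenic$symbol
  )

  bundle <- structure(list(components = comp, ct_edges = ct_edges,
                           ppi_edges = ppi, pathogenic = pathogenic,
                           collection = collection,
                           signaling = signaling$edges,
                           signaling_tg = signaling$tg,
                           signaling_pg = signaling$pg,
                           signaling_nc = signaling$nc,
                           params = params, ledger = ledger),
                      class = "synthetic_bundle")
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' Generate a directed signalling graph with a planted top cascade
#'
#' Builds a background DAG plus one planted receptor-to-effector chain
#' whose nodes are all both component targets and pathogenic genes, with
#' maximal evidence (`nv`) and regulation (`nc`) counts. By construction
#' every per-node score term of the planted chain exceeds every background
#' term, so the planted chain attains the highest normalised
#' maximum-targeting-weight score among all source-sink cascades.
#'
#' @param params A [bundle_params()] list (uses `chain_length` and
#'   `n_background_signaling`).
#' @param seed Integer seed.
#' @return A list: `edges` (directed edge table), `tg` (target genes),
#'   `pg` (pathogenic table with `nv`), `nc` (regulation counts),
#'   `planted_chain` (node names in order).
#' @export
generate_signaling <- function(params = bundle_params(), seed = 1) {
  set.seed(derive_seed(seed, 5L))
  L <- params$chain_length
  chain <- sprintf("SIG%02d", seq_len(L))
  nb <- params$n_background_signaling
  bg <- sprintf("BG%02d", seq_len(nb))
  # background DAG: forward edges over a random topological order
  edges <- data.frame(from = chain[-L], to = chain[-1],
                      stringsAsFactors = FALSE)
  for (i in seq_len(nb - 1L)) {
    kids <- which(seq_len(nb) > i)
    kids <- kids[stats::runif(length(kids)) < 2.5 / nb]
    if (i < nb && length(kids) == 0L && stats::runif(1) < 0.5) {
      kids <- i + 1L
    }
    if (length(kids) > 0L) {
      edges <- rbind(edges, data.frame(from = bg[i], to = bg[kids],
                                       stringsAsFactors = FALSE))
    }
  }
  nodes <- c(chain, bg)
  nv_max <- 40L
  nc_max <- 25L
  # background genes: a few are weak targets/pathogenic so the membership
  # corrections actually discriminate
  bg_tg <- bg[seq_len(min(5L, nb))]
  bg_pg <- bg[seq(from = min(6L, nb), length.out = min(5L, nb))]
  pg_tab <- data.frame(symbol = c(chain, bg_pg),
                       nv = c(rep(nv_max, L),
                              sample(1:3, length(bg_pg), replace = TRUE)),
                       stringsAsFactors = FALSE)
  nc_tab <- data.frame(node = c(chain, bg_tg),
                       nc = c(rep(nc_max, L),
                              sample(1:3, length(bg_tg), replace = TRUE)),
                       stringsAsFactors = FALSE)
  list(edges = data.frame(edges, weight = 1),
       tg = c(chain, bg_tg), pg = pg_tab, nc = nc_tab,
       planted_chain = chain, nodes = nodes)
}

#' Write a synthetic bundle to a directory
#'
#' Emits `components.tsv`, `ct_edges.tsv`, `ppi_edges.tsv`,
#' `pathogenic.tsv`, `sets.gmt`, `signaling_edges.tsv`, `signaling_tg.txt`,
#' `signaling_nc.tsv` and `ledger.json` — the same formats the package's
#' readers consume.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  w(bundle$components, "components.tsv")
  w(bundle$ct_edges, "ct_edges.tsv")
  w(bundle$ppi_edges, "ppi_edges.tsv")
  w(bundle$pathogenic, "pathogenic.tsv")
  write_gmt(bundle$collection, file.path(dir, "sets.gmt"))
  w(bundle$signaling, "signaling_edges.tsv")
  writeLines(bundle$signaling_tg, file.path(dir, "signaling_tg.txt"))
  w(bundle$signaling_nc, "signaling_nc.tsv")
  jsonlite::write_json(bundle$ledger, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("synthetic bundle (seed %d): %d components, %d genes, %d C-T edges, %d PPI edges\n",
              x$ledger$seed, nrow(x$components), x$ledger$n_genes,
              nrow(x$ct_edges), nrow(x$ppi_edges)))
  cat(sprintf("  planted: %d hubs, cover of %d, signalling chain of %d\n",
              length(x$ledger$planted_hubs), length(x$ledger$planted_cover),
              length(x$ledger$planted_chain)))
  invisible(x)
}
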