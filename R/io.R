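#' Read a component property table
#'
#' Reads a tab-separated table of formula components with their ADME-relevant
#' physicochemical properties. Required columns are `id`, `mw` (molecular
#' weight, Da), `hdon` (H-bond donors), `hacc` (H-bond acceptors), `rbn`
#' (rotatable bonds), `logp` and `ob` (oral bioavailability, percent).
#' Optional columns: `name`, `herbs` (comma-separated herb codes), `smiles`,
#' and the categorical predictor outputs `gi_class` (high/low/unknown),
#' `herg_class` (high/medium/low/unknown), `carcinogenicity`
#' (positive/negative/unknown). Missing optional class columns are filled
#' with `"unknown"`; they are never treated as a pass or a fail on their own.
#'
#' @param path Path to a UTF-8, tab-separated file with a header row.
#' @return A `data.frame` of class `component_table`, one row per component,
#'   in file order.
#' @export
read_component_table <- function(path) {
  df <- read_tsv_checked(path)
  required <- c("id", "mw", "hdon", "hacc", "rbn", "logp", "ob")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("component table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- c("mw", "hdon", "hacc", "rbn", "logp", "ob")
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(trimws(df[[col]])))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                   col, bad[1L], df[[col]][bad[1L]]), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in required numeric column '%s' at data row %d",
                   col, which(is.na(v))[1L]), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (anyDuplicated(df$id)) {
    stop("duplicated component id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) > 0L) {
    if (any(df$mw <= 0)) stop("mw must be > 0", call. = FALSE)
    counts <- c("hdon", "hacc", "rbn")
    for (col in counts) {
      if (any(df[[col]] < 0) || any(df[[col]] != round(df[[col]]))) {
        stop(sprintf("column '%s' must hold non-negative integers", col),
             call. = FALSE)
      }
    }
    if (any(df$ob < 0)) stop("ob must be >= 0", call. = FALSE)
  }
  if (is.null(df$name)) df$name <- df$id
  if (is.null(df$herbs)) df$herbs <- rep("", nrow(df))
  if (is.null(df$smiles)) df$smiles <- rep(NA_character_, nrow(df))
  for (col in c("gi_class", "herg_class", "carcinogenicity")) {
    if (is.null(df[[col]])) {
      df[[col]] <- rep("unknown", nrow(df))
    } else {
      df[[col]][is.na(df[[col]]) | !nzchar(df[[col]])] <- "unknown"
    }
  }
  class(df) <- c("component_table", "data.frame")
  df
}

#' Read a pathogenic-gene evidence table
#'
#' Two required columns: `symbol` (gene identifier, case-sensitive) and `nv`
#' (number of supporting literature reports, a positive integer).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `data.frame` with columns `symbol` and `nv`.
#' @export
read_pathogenic_table <- function(path) {
  df <- read_tsv_checked(path)
  missing <- setdiff(c("symbol", "nv"), names(df))
  if (length(missing) > 0L) {
    stop("pathogenic-gene table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  nv <- suppressWarnings(as.numeric(df$nv))
  if (anyNA(nv)) {
    stop("non-numeric nv at data row ", which(is.na(nv))[1L], call. = FALSE)
  }
  if (any(nv < 1)) stop("nv must be >= 1 for every gene", call. = FALSE)
  if (anyDuplicated(df$symbol)) {
    stop("duplicated gene symbol(s): ",
         paste(unique(df$symbol[duplicated(df$symbol)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(symbol = df$symbol, nv = nv, stringsAsFactors = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one gene set per line, fields tab-separated — term id,
#' description, then one or more gene symbols. Duplicate genes within a line
#' are collapsed; duplicate term ids across lines are an error.
#'
#' @param path Path to a GMT file.
#' @param name Collection name attached to the result.
#' @return An object of class `gene_set_collection`: a named list of character
#'   vectors with a parallel `descriptions` attribute.
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); at least 3 required",
                   i, length(fields)), call. = FALSE)
    }
    ids[[i]] <- fields[[1]]
    descs[[i]] <- fields[[2]]
    genes <- unique(fields[-c(1L, 2L)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop(sprintf("GMT line %d ('%s') contains no genes", i, ids[[i]]),
           call. = FALSE)
    }
    sets[[i]] <- genes
  }
  if (anyDuplicated(ids)) {
    stop("duplicated term id(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- ids
  structure(sets, descriptions = stats::setNames(descs, ids),
            collection = name, class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#'
#' @param collection A `gene_set_collection` (see [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  descs <- attr(collection, "descriptions")
  if (is.null(descs)) descs <- stats::setNames(names(collection), names(collection))
  lines <- vapply(names(collection), function(id) {
    paste(c(id, descs[[id]], collection[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an edge table
#'
#' Tab-separated, header optional. The first two columns are endpoint ids;
#' an optional third column is an edge type label and an optional fourth a
#' non-negative weight (default 1).
#'
#' @param path Path to the file.
#' @param header Whether the first line is a header (default `TRUE`).
#' @return A `data.frame` with columns `from`, `to`, `type`, `weight`.
#' @export
read_edges <- function(path, header = TRUE) {
  df <- utils::read.delim(path, header = header, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2L) {
    stop("edge table needs at least two columns (line 1)", call. = FALSE)
  }
  out <- data.frame(from = df[[1]], to = df[[2]], stringsAsFactors = FALSE)
  out$type <- if (ncol(df) >= 3L) df[[3]] else NA_character_
  if (ncol(df) >= 4L) {
    w <- suppressWarnings(as.numeric(df[[4]]))
    if (anyNA(w)) {
      stop("malformed weight at data row ", which(is.na(w))[1L], call. = FALSE)
    }
    if (any(w < 0)) stop("edge weights must be >= 0", call. = FALSE)
    out$weight <- w
  } else {
    out$weight <- 1
  }
  bad <- which(!nzchar(out$from) | !nzchar(out$to))
  if (length(bad) > 0L) {
    stop("malformed edge row ", bad[1L], ": empty endpoint", call. = FALSE)
  }
  out
}

#' Write an edge table
#'
#' Inverse of [read_edges()]: writes `from`, `to`, `type`, `weight` as TSV.
#'
#' @param edges A data frame with at least `from` and `to`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  out <- data.frame(from = edges$from, to = edges$to,
                    type = if (is.null(edges$type)) NA_character_ else edges$type,
                    weight = if (is.null(edges$weight)) 1 else edges$weight,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Shared strict TSV reader: header required, all columns read as character so
# numeric validation can report row numbers itself.
read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("gene_set_collection '%s': %d sets, %d distinct genes\n",
              attr(x, "collection"), length(x),
              length(unique(unlist(x, use.names = FALSE)))))
  if (length(x) > 0L) {
    cat(sprintf("  set sizes: min %d, median %g, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  }
  invisible(x)
}
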