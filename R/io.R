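#' Construct a PPI network from an edge table
#'
#' Builds the canonical undirected, simple interaction graph used throughout
#' the package. Self-loops are dropped (with a warning giving the count) and
#' duplicate edges are collapsed; when the input carries confidence weights,
#' a collapsed edge keeps the maximum of the colliding weights, the
#' conservative merge for confidence scores.
#'
#' @param from,to character vectors of protein identifiers (same length).
#'   Identifiers are case-sensitive opaque strings; no aliasing is applied.
#' @param weight optional numeric vector of confidence weights in `[0, 1]`.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers to retain.
#' @return an [igraph::igraph] object; weighted iff `weight` was supplied.
#' @export
ppi_network <- function(from, to, weight = NULL, nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("'from' and 'to' must have the same length")
  }
  if (!is.null(weight)) {
    if (length(weight) != length(from)) {
      stop("'weight' must match the number of edges")
    }
    if (anyNA(weight) || any(weight < 0 | weight > 1)) {
      stop("edge weights must lie in [0, 1]")
    }
  }
  all_nodes <- sort(unique(c(from, to, as.character(nodes))))
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    from <- from[!loops]
    to <- to[!loops]
    if (!is.null(weight)) weight <- weight[!loops]
  }
  ed <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (!is.null(weight)) ed$weight <- weight
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = all_nodes)
  # collapse parallel edges; keep the max weight when weighted
  comb <- if (!is.null(weight)) list(weight = "max") else "ignore"
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = comb)
}

#' @rdname ppi_network
#' @param g an igraph object.
#' @export
is_weighted_ppi <- function(g) {
  "weight" %in% igraph::edge_attr_names(g)
}

# canonical unordered-pair key used by edge weight maps
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

# edge endpoints of a graph as a 2-column character matrix
edge_ends <- function(g) {
  igraph::as_edgelist(g, names = TRUE)
}

#' Read a PPI edge list
#'
#' Parses a whitespace/tab-separated edge list with columns
#' `node1 node2 [weight]`. Lines starting with `#` are comments. A first
#' line of a 3-column file whose third token is non-numeric is treated as a
#' header and skipped.
#'
#' @param path path to the edge-list file.
#' @return a [ppi_network()] graph (weighted iff a third column is present).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges in ", path)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    stop(sprintf("malformed line %d in %s: fewer than 2 fields",
                 idx[which(nt < 2L)[1L]], path))
  }
  # header auto-detection for 3-column files
  if (nt[1L] >= 3L && is.na(suppressWarnings(as.numeric(toks[[1L]][3L])))) {
    toks <- toks[-1L]
    idx <- idx[-1L]
    nt <- nt[-1L]
    if (length(toks) == 0L) stop("no edges in ", path)
  }
  from <- vapply(toks, `[`, character(1L), 1L)
  to <- vapply(toks, `[`, character(1L), 2L)
  weight <- NULL
  if (any(nt >= 3L)) {
    if (!all(nt >= 3L)) {
      stop(sprintf("malformed line %d in %s: missing weight column",
                   idx[which(nt < 3L)[1L]], path))
    }
    wtok <- vapply(toks, `[`, character(1L), 3L)
    weight <- suppressWarnings(as.numeric(wtok))
    if (anyNA(weight)) {
      stop(sprintf("non-numeric weight on line %d in %s",
                   idx[which(is.na(weight))[1L]], path))
    }
    if (any(weight < 0 | weight > 1)) {
      stop(sprintf("weight outside [0, 1] on line %d in %s",
                   idx[which(weight < 0 | weight > 1)[1L]], path))
    }
  }
  ppi_network(from, to, weight)
}

#' Write a PPI edge list
#'
#' @param g a PPI graph.
#' @param path output path; tab-separated `node1 node2 [weight]`, weights
#'   printed with 6 decimals.
#' @export
write_edge_list <- function(g, path) {
  el <- edge_ends(g)
  if (is_weighted_ppi(g)) {
    out <- sprintf("%s\t%s\t%.6f", el[, 1L], el[, 2L],
                   igraph::E(g)$weight)
  } else {
    out <- sprintf("%s\t%s", el[, 1L], el[, 2L])
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a gene-expression matrix
#'
#' Each row is a gene identifier followed by `T` numeric expression values
#' (one per time point), tab/whitespace-separated. All rows must have the
#' same number of values and `T >= 2`; a gene identifier seen again
#' overrides the earlier row with a warning.
#'
#' @param path path to the expression file.
#' @return numeric matrix, one row per gene (rownames = gene IDs), `T`
#'   columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no expression rows in ", path)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nt <- lengths(toks)
  if (length(unique(nt)) != 1L) {
    bad <- which(nt != nt[1L])[1L]
    stop(sprintf("ragged row on line %d in %s: %d fields, expected %d",
                 idx[bad], path, nt[bad], nt[1L]))
  }
  tp <- nt[1L] - 1L
  if (tp < 2L) stop("expression profiles need at least 2 time points")
  ids <- vapply(toks, `[`, character(1L), 1L)
  vals <- vapply(toks, function(x) {
    v <- suppressWarnings(as.numeric(x[-1L]))
    v
  }, numeric(tp))
  vals <- t(vals)
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1L, any))[1L]
    stop(sprintf("non-numeric expression value on line %d in %s",
                 idx[bad], path))
  }
  if (anyDuplicated(ids)) {
    warning(sprintf("%d duplicate gene ID(s): later rows override earlier",
                    sum(duplicated(ids))))
    last <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[last]
    vals <- vals[last, , drop = FALSE]
  }
  rownames(vals) <- ids
  colnames(vals) <- paste0("t", seq_len(tp))
  vals
}

#' Write a gene-expression matrix
#'
#' @param expr numeric matrix with gene IDs as rownames.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  out <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i], format(expr[i, ], digits = 10,
                                      trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1L))
  writeLines(out, path)
  invisible(path)
}

#' Complex sets
#'
#' An ordered collection of protein-ID sets: either a benchmark catalogue
#' (CYC2008/MIPS-style) or the predictions of a detection run.
#'
#' @param complexes list of character vectors; each is one complex and must
#'   be non-empty. Member IDs are de-duplicated within a complex. Identical
#'   complexes are permitted (a warning flags them).
#' @param label free-text label, e.g. `"predicted"` or `"benchmark"`.
#' @return object of class `complex_set`.
#' @export
complex_set <- function(complexes, label = "") {
  complexes <- lapply(complexes, function(x) sort(unique(as.character(x))))
  if (any(lengths(complexes) == 0L)) stop("empty complex not allowed")
  keys <- vapply(complexes, paste, character(1L), collapse = "\t")
  if (anyDuplicated(keys)) {
    warning(sprintf("%d duplicate complex(es) in set", sum(duplicated(keys))))
  }
  structure(list(complexes = complexes, label = as.character(label)[1L]),
            class = "complex_set")
}

#' @export
length.complex_set <- function(x) length(x$complexes)

#' @export
print.complex_set <- function(x, ...) {
  sz <- lengths(x$complexes)
  cat(sprintf("complex_set%s: %d complexes, %d proteins (sizes %s)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(sz), length(unique(unlist(x$complexes))),
              if (length(sz)) paste0(min(sz), "-", max(sz)) else "-"))
  invisible(x)
}

#' Read / write complex sets
#'
#' One complex per line, whitespace-separated protein IDs (the format used
#' by CYC2008/MIPS-style catalogue distributions). Empty lines are skipped
#' with a warning. `write_complexes()` followed by `read_complexes()`
#' reproduces the set.
#'
#' @param path path to the file.
#' @param label label for the returned set.
#' @return `read_complexes()`: a [complex_set()].
#' @export
read_complexes <- function(path, label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  empty <- grepl("^\\s*$", lines)
  if (any(empty)) {
    warning(sprintf("skipped %d empty line(s)", sum(empty)))
    lines <- lines[!empty]
  }
  if (length(lines) == 0L) stop("no complexes in ", path)
  complex_set(strsplit(trimws(lines), "\\s+"), label = label)
}

#' @rdname read_complexes
#' @param cs a [complex_set()].
#' @export
write_complexes <- function(cs, path) {
  stopifnot(inherits(cs, "complex_set"))
  writeLines(vapply(cs$complexes, paste, character(1L), collapse = " "),
             path)
  invisible(path)
}
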