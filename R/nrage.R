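#' Detect protein complexes in a confidence-weighted PPI network
#'
#' The full pipeline: (1) weight the interaction network by blending the
#' resource-allocation index with the Pearson correlation of expression
#' profiles, removing negatively co-expressed pairs
#' ([build_weighted_network()]); (2) mine complex cores under the weighted
#' density floor `lambda` and hop-diameter cap `delta`
#' ([detect_cores()]); (3) expand each core with second-order-neighbor
#' attachments ([expand_core()]); (4) drop redundant clusters
#' ([deduplicate()]). The run is deterministic: identical inputs and
#' parameters give identical output.
#'
#' @param net an unweighted PPI graph (see [read_edge_list()]).
#' @param expr expression matrix, genes x time points (see
#'   [read_expression()]).
#' @param params a [detection_params()] object; `params$ra = FALSE`
#'   weights by expression alone and `params$sns = FALSE` skips the
#'   attachment phase (the two ablations).
#' @return object of class `nrage_wpn` with elements `complexes` (the
#'   predicted [complex_set()]), `cores` and `clusters` (lists of
#'   `ppi_cluster`), `network` (the weighted graph), `params`, and `stats`
#'   (edge/cluster counts at each stage).
#' @seealso [score_complexes()] to evaluate the prediction against a
#'   benchmark catalogue.
#' @examples
#' sim <- generate_synthetic(synth_config(n_complexes = 4, seed = 7,
#'                                        n_background_nodes = 10))
#' fit <- nrage_wpn(sim$network, sim$expression)
#' fit
#' score_complexes(sim$truth, fit$complexes)$f_measure_plus
#' @export
nrage_wpn <- function(net, expr, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  n_edges_in <- igraph::ecount(net)
  wnet <- build_weighted_network(net, expr, alpha = params$alpha,
                                 ra = params$ra,
                                 include_endpoints = params$include_endpoints)
  cores <- detect_cores(wnet, params)
  clusters <- if (params$sns) {
    lapply(cores, expand_core, graph = wnet, params = params)
  } else {
    cores
  }
  pred <- deduplicate(clusters, params)
  n_attach <- sum(lengths(lapply(clusters, `[[`, "members"))) -
    sum(lengths(lapply(cores, `[[`, "members")))
  structure(list(
    complexes = pred,
    cores = cores,
    clusters = clusters,
    network = wnet,
    params = params,
    stats = list(n_edges_input = n_edges_in,
                 n_edges_weighted = igraph::ecount(wnet),
                 n_edges_filtered = n_edges_in - igraph::ecount(wnet),
                 n_cores = length(cores),
                 n_attached = n_attach,
                 n_duplicates_dropped = length(clusters) - length(pred),
                 n_complexes = length(pred))),
    class = "nrage_wpn")
}

#' @export
print.nrage_wpn <- function(x, ...) {
  s <- x$stats
  cat("Protein complex detection (RA + co-expression weighted network)\n")
  cat(sprintf("  edges: %d input, %d retained after negative-PCC filter\n",
              s$n_edges_input, s$n_edges_weighted))
  cat(sprintf("  cores: %d (lambda=%.2f, delta=%d); attachments added: %d\n",
              s$n_cores, x$params$lambda, x$params$delta, s$n_attached))
  cat(sprintf("  complexes: %d after dropping %d redundant cluster(s)\n",
              s$n_complexes, s$n_duplicates_dropped))
  invisible(x)
}

#' @export
summary.nrage_wpn <- function(object, ...) {
  sz <- lengths(object$complexes$complexes)
  out <- list(params = object$params, stats = object$stats,
              size_summary = if (length(sz)) summary(sz) else NULL)
  class(out) <- "summary.nrage_wpn"
  out
}

#' @export
print.summary.nrage_wpn <- function(x, ...) {
  print(x$params)
  for (nm in names(x$stats)) {
    cat(sprintf("  %-22s %d\n", nm, x$stats[[nm]]))
  }
  if (!is.null(x$size_summary)) {
    cat("  complex sizes:\n")
    print(x$size_summary)
  }
  invisible(x)
}

#' Plot a detection result
#'
#' Draws the weighted network with nodes colored by predicted complex
#' membership (grey for unassigned nodes) and edge width proportional to
#' confidence weight.
#'
#' @param x an `nrage_wpn` object.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.nrage_wpn <- function(x, ...) {
  g <- x$network
  nms <- igraph::V(g)$name
  memb <- rep(NA_integer_, length(nms))
  for (k in seq_along(x$complexes$complexes)) {
    memb[nms %in% x$complexes$complexes[[k]]] <- k
  }
  pal <- grDevices::rainbow(max(1L, length(x$complexes$complexes)))
  col <- ifelse(is.na(memb), "grey80", pal[memb])
  w <- if (is_weighted_ppi(g)) igraph::E(g)$weight else
    rep(1, igraph::ecount(g))
  igraph::plot.igraph(g, vertex.color = col, vertex.size = 6,
                      vertex.label = NA, edge.width = 0.5 + 2.5 * w, ...)
  invisible(x)
}
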