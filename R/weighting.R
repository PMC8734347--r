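#' Resource-allocation edge weights
#'
#' Scores each interaction by the resource-allocation (RA) index: a node is
#' assumed to spread one unit of resource equally among its neighborhood, so
#' an interacting pair supported by many low-degree common partners receives
#' a high weight,
#' \deqn{WRA_{ij} = \sum_{u \in N(i) \cap N(j)} \frac{1}{|N(u)|},}
#' where \eqn{N(x)} is the closed neighborhood of \eqn{x} (its neighbors and
#' \eqn{x} itself), hence \eqn{|N(u)| = deg(u) + 1}. Under the closed
#' convention the endpoints \eqn{i, j} of an edge always lie in the
#' intersection, so by default their terms are counted: a bridge edge with
#' no third-party common partner still scores
#' \eqn{1/(deg(i)+1) + 1/(deg(j)+1)} — it carries all the resource flow
#' between its two sides — and every edge of a clique scores exactly 1.
#' Set `include_endpoints = FALSE` to sum over third-party common
#' neighbors only (the open-intersection variant, under which a bridge
#' scores 0).
#'
#' @param net a PPI graph with at least one edge.
#' @param include_endpoints logical; include the edge endpoints' own terms
#'   in the summation (default `TRUE`, the literal closed-neighborhood
#'   reading).
#' @return named numeric vector keyed by canonical unordered edge pair, one
#'   entry per edge of `net`. Raw values are non-negative and may exceed 1;
#'   see [normalize_weight_map()].
#' @export
compute_wra <- function(net, include_endpoints = TRUE) {
  if (igraph::ecount(net) == 0L) stop("network has no edges")
  nms <- igraph::V(net)$name
  adj <- igraph::as_adj_list(net, mode = "all")
  adj <- lapply(adj, function(v) nms[as.integer(v)])
  names(adj) <- nms
  deg <- igraph::degree(net)
  names(deg) <- nms
  el <- edge_ends(net)
  vals <- vapply(seq_len(nrow(el)), function(k) {
    i <- el[k, 1L]; j <- el[k, 2L]
    common <- intersect(adj[[i]], adj[[j]])
    common <- setdiff(common, c(i, j))
    s <- sum(1 / (deg[common] + 1))
    if (include_endpoints) s <- s + 1 / (deg[i] + 1) + 1 / (deg[j] + 1)
    s
  }, numeric(1L))
  names(vals) <- pair_key(el[, 1L], el[, 2L])
  vals
}

#' Pearson correlation of expression profiles for protein pairs
#'
#' Computes the exact sample Pearson correlation coefficient (PCC) between
#' the expression vectors of each requested pair. Co-expressed genes tend to
#' encode interacting proteins, so a high PCC raises confidence in an
#' interaction. Pairs with a gene absent from `expr`, or with a
#' zero-variance profile (PCC undefined), are recorded as `NA` with a
#' warning — absence of expression evidence is deliberately distinct from a
#' correlation of 0.
#'
#' @param expr numeric matrix of expression profiles (rownames = gene IDs,
#'   columns = time points, at least 2).
#' @param pairs two-column character matrix of gene-ID pairs.
#' @return named numeric vector in `[-1, 1]` (or `NA`), keyed by canonical
#'   unordered pair.
#' @export
compute_pcc <- function(expr, pairs) {
  if (ncol(expr) < 2L) stop("expression profiles need at least 2 time points")
  pairs <- cbind(as.character(pairs[, 1L]), as.character(pairs[, 2L]))
  have <- rownames(expr)
  sds <- apply(expr, 1L, stats::sd)
  ok_var <- sds > 0
  missing_n <- 0L
  flat_n <- 0L
  vals <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, 1L]; b <- pairs[k, 2L]
    if (!(a %in% have) || !(b %in% have)) {
      missing_n <<- missing_n + 1L
      return(NA_real_)
    }
    if (!ok_var[a] || !ok_var[b]) {
      flat_n <<- flat_n + 1L
      return(NA_real_)
    }
    stats::cor(expr[a, ], expr[b, ])
  }, numeric(1L))
  if (missing_n > 0L) {
    warning(sprintf("%d pair(s) with a gene absent from expression data: PCC set to NA",
                    missing_n))
  }
  if (flat_n > 0L) {
    warning(sprintf("%d pair(s) with a zero-variance profile: PCC undefined, set to NA",
                    flat_n))
  }
  names(vals) <- pair_key(pairs[, 1L], pairs[, 2L])
  vals
}

#' Remove negatively co-expressed interactions
#'
#' Drops every edge whose expression correlation is strictly negative; a
#' negative PCC is read as evidence against a functional interaction.
#' Edges at PCC = 0 are kept (no correlation, not anti-correlation), as are
#' edges with missing PCC (no expression evidence either way). The node set
#' is unchanged, so filtering may leave isolated nodes.
#'
#' @param net a PPI graph.
#' @param pcc edge weight map from [compute_pcc()] covering `net`'s edges.
#' @return the filtered graph.
#' @export
filter_negative_pcc <- function(net, pcc) {
  el <- edge_ends(net)
  if (nrow(el) == 0L) return(net)
  keys <- pair_key(el[, 1L], el[, 2L])
  if (!all(keys %in% names(pcc))) {
    stop("pcc map does not cover all network edges")
  }
  v <- pcc[keys]
  drop <- !is.na(v) & v < 0
  igraph::delete_edges(net, which(drop))
}

#' Min-max normalize an edge weight map
#'
#' Rescales to `[0, 1]` by `(x - min) / (max - min)`. If all (non-missing)
#' values coincide — within a spread of `1e-12`, so that floating-point
#' noise in otherwise identical scores is not amplified to the full unit
#' interval — the range is degenerate and every value is set to 1.
#' Missing entries stay missing.
#'
#' @param w named numeric edge weight map.
#' @return normalized map with the same names.
#' @export
normalize_weight_map <- function(w) {
  if (length(w) == 0L) stop("empty weight map")
  v <- w[!is.na(w)]
  if (length(v) == 0L) return(w)
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1e-12) {
    w[!is.na(w)] <- 1
    return(w)
  }
  (w - lo) / (hi - lo)
}

#' Blend topological and expression edge weights
#'
#' Convex combination \eqn{W = \alpha W_p + (1 - \alpha) W_N} of the
#' expression-correlation map and the resource-allocation map (both on the
#' unit scale), followed by a final min-max normalization to `[0, 1]`. A
#' small
#' \eqn{\alpha} leans on network topology, a large one on co-expression.
#' Edges whose PCC is missing contribute 0 from the \eqn{W_p} term and keep
#' their full \eqn{(1-\alpha) W_N} share.
#'
#' @param wn resource-allocation map on `[0, 1]`.
#' @param wp expression map restricted to `[0, 1]` (post negative-filter);
#'   `NA` allowed.
#' @param alpha blend parameter in `[0, 1]`.
#' @return normalized blended map over the same edges.
#' @export
combine_weights <- function(wn, wp, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("'alpha' must be a single number in [0, 1]")
  }
  if (!setequal(names(wn), names(wp)) || length(wn) != length(wp)) {
    stop("weight map domains differ")
  }
  wp <- wp[names(wn)]
  if (any(!is.na(wn) & (wn < 0 | wn > 1))) stop("wn not normalized to [0, 1]")
  if (any(!is.na(wp) & (wp < 0 | wp > 1))) stop("wp outside [0, 1]")
  wpc <- ifelse(is.na(wp), 0, wp)
  w <- alpha * wpc + (1 - alpha) * wn
  normalize_weight_map(w)
}

#' Build the blended confidence-weighted PPI network
#'
#' Full weighting pipeline: compute PCC over the edges, remove negatively
#' co-expressed pairs, compute the resource-allocation index on the
#' filtered network, blend with the retained (non-negative) PCC values at
#' `alpha`, and min-max normalize the blended result. Under the closed
#' neighborhood convention the RA index lies in `[0, 1]` up to rare
#' configurations with many degree-2 common partners, where it can
#' marginally exceed 1; such values are capped at 1 before blending so
#' both sources enter the blend on the same unit scale, and only the
#' blended map
#' is normalized. With `ra = FALSE` the topological term is skipped and
#' the weights are the normalized PCC values alone (missing PCC
#' contributes 0), which is the expression-only ablation.
#'
#' @param net an unweighted PPI graph.
#' @param expr expression matrix (see [read_expression()]).
#' @param alpha blend parameter in `[0, 1]`; 0 = topology only, 1 =
#'   co-expression only.
#' @param ra logical; include the resource-allocation term (default `TRUE`).
#' @param include_endpoints passed to [compute_wra()].
#' @return a weighted PPI graph over the PCC-filtered edge set. Edges with
#'   final weight 0 are retained: a zero-confidence edge is not the same as
#'   an absent one.
#' @export
build_weighted_network <- function(net, expr, alpha = 0.3, ra = TRUE,
                                   include_endpoints = TRUE) {
  if (is_weighted_ppi(net)) {
    net <- igraph::delete_edge_attr(net, "weight")
  }
  if (igraph::ecount(net) == 0L) stop("network has no edges")
  el <- edge_ends(net)
  pcc <- compute_pcc(expr, el)
  net2 <- filter_negative_pcc(net, pcc)
  if (igraph::ecount(net2) == 0L) {
    warning("all edges removed by the negative-PCC filter")
    return(net2)
  }
  el2 <- edge_ends(net2)
  keys <- pair_key(el2[, 1L], el2[, 2L])
  wp <- pcc[keys]
  if (ra) {
    wn <- pmin(compute_wra(net2, include_endpoints = include_endpoints), 1)
    w <- combine_weights(wn[keys], wp, alpha)
  } else {
    w <- normalize_weight_map(ifelse(is.na(wp), 0, wp))
    names(w) <- keys
  }
  igraph::set_edge_attr(net2, "weight", value = unname(w[keys]))
}
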