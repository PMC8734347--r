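#' Detection parameters
#'
#' Bundles every tunable of the weighting + detection pipeline. The
#' defaults are the reference configuration: blend `alpha = 0.3`, density
#' floor `lambda = 0.7`, diameter cap `delta = 2`, neighborhood-affinity
#' match threshold `t = 0.2`.
#'
#' @param alpha blend of expression vs topology weights, in `[0, 1]`.
#' @param lambda minimum weighted density of a core, in `(0, 1]`.
#' @param delta maximum hop diameter of a core (positive integer).
#' @param min_core_size smallest admissible core (>= 2; default 3 — the
#'   density of a 2-node cluster is just its edge weight, which makes the
#'   density floor a trivial filter).
#' @param attach_ratio attachment threshold as a fraction of the core's
#'   mean internal weighted degree, in `(0, 1]`.
#' @param dedup_na neighborhood-affinity level at which two output clusters
#'   are considered redundant, in `(0, 1]`.
#' @param t neighborhood-affinity threshold used when scoring predictions.
#' @param ra logical; use the resource-allocation term when weighting
#'   (`FALSE` gives the expression-only ablation).
#' @param sns logical; expand cores with second-order-neighbor attachments
#'   (`FALSE` gives the cores-only ablation).
#' @param include_endpoints passed to [compute_wra()].
#' @return object of class `detection_params`.
#' @export
detection_params <- function(alpha = 0.3, lambda = 0.7, delta = 2L,
                             min_core_size = 3L, attach_ratio = 0.5,
                             dedup_na = 0.8, t = 0.2, ra = TRUE,
                             sns = TRUE, include_endpoints = TRUE) {
  stopifnot(alpha >= 0, alpha <= 1,
            lambda > 0, lambda <= 1,
            delta >= 1, delta == as.integer(delta),
            min_core_size >= 2,
            attach_ratio > 0, attach_ratio <= 1,
            dedup_na > 0, dedup_na <= 1,
            t > 0, t <= 1,
            is.logical(ra), is.logical(sns))
  structure(list(alpha = alpha, lambda = lambda, delta = as.integer(delta),
                 min_core_size = as.integer(min_core_size),
                 attach_ratio = attach_ratio, dedup_na = dedup_na, t = t,
                 ra = ra, sns = sns, include_endpoints = include_endpoints),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(
    "detection_params: alpha=%.2f lambda=%.2f delta=%d min_core=%d attach=%.2f dedup_na=%.2f t=%.2f ra=%s sns=%s\n",
    x$alpha, x$lambda, x$delta, x$min_core_size, x$attach_ratio,
    x$dedup_na, x$t, x$ra, x$sns))
  invisible(x)
}

# sum of weights of edges induced by `members` (weight 1 when unweighted)
induced_weight_sum <- function(graph, members) {
  sub <- igraph::induced_subgraph(graph, members)
  if (igraph::ecount(sub) == 0L) return(0)
  if (is_weighted_ppi(sub)) sum(igraph::E(sub)$weight)
  else igraph::ecount(sub)
}

#' Weighted density of a node set
#'
#' Mean pairwise edge weight of the induced subgraph:
#' \eqn{2m / (|N| (|N| - 1))} with \eqn{m} the sum of induced edge weights
#' and \eqn{|N|} the number of members. Equals 1 for a unit-weight clique.
#'
#' @param graph a (weighted) PPI graph.
#' @param members character vector of at least 2 node IDs in `graph`.
#' @return density in `[0, 1]` for weights in `[0, 1]`.
#' @export
weighted_density <- function(graph, members) {
  members <- unique(as.character(members))
  k <- length(members)
  if (k < 2L) stop("density needs at least 2 members")
  2 * induced_weight_sum(graph, members) / (k * (k - 1))
}

#' Hop diameter of a node set
#'
#' Longest shortest path, in unweighted hops, between any two members
#' within the induced subgraph. `Inf` if the induced subgraph is
#' disconnected; 0 for a singleton.
#'
#' @inheritParams weighted_density
#' @return integer hop count, or `Inf`.
#' @export
hop_diameter <- function(graph, members) {
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("empty member set")
  if (length(members) == 1L) return(0)
  sub <- igraph::induced_subgraph(graph, members)
  max(igraph::distances(sub, weights = NA))
}

new_cluster <- function(graph, members, stage) {
  members <- sort(unique(as.character(members)))
  structure(list(members = members,
                 density = if (length(members) >= 2L)
                   weighted_density(graph, members) else 0,
                 diameter = hop_diameter(graph, members),
                 stage = stage),
            class = "ppi_cluster")
}

#' @export
print.ppi_cluster <- function(x, ...) {
  cat(sprintf("ppi_cluster [%s] n=%d density=%.3f diameter=%s: %s\n",
              x$stage, length(x$members), x$density,
              format(x$diameter), paste(x$members, collapse = " ")))
  invisible(x)
}

#' Detect complex cores under density and diameter constraints
#'
#' Greedy seeded search for dense, compact cores. Nodes are visited as
#' seeds in decreasing weighted-degree order (ties broken lexicographically
#' by ID). A seed starts a candidate core together with its highest-weight
#' neighbor; the core then repeatedly absorbs the adjacent node that
#' maximizes the resulting weighted density, as long as the grown core
#' keeps density >= `lambda` and hop diameter <= `delta`. A grown core is
#' accepted if it has at least `min_core_size` members and satisfies both
#' constraints; seeds already covered by an accepted core are skipped.
#' The procedure is fully deterministic.
#'
#' @param graph a weighted PPI graph (weights in `[0, 1]`).
#' @param params a [detection_params()] object.
#' @return list of `ppi_cluster` objects with `stage = "core"`, in
#'   discovery order.
#' @export
detect_cores <- function(graph, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  if (igraph::vcount(graph) == 0L || igraph::ecount(graph) == 0L) {
    return(list())
  }
  nms <- igraph::V(graph)$name
  wts <- if (is_weighted_ppi(graph)) igraph::E(graph)$weight
         else rep(1, igraph::ecount(graph))
  el <- edge_ends(graph)
  ekey <- pair_key(el[, 1L], el[, 2L])
  wmap <- stats::setNames(wts, ekey)
  adj <- igraph::as_adj_list(graph, mode = "all")
  adj <- lapply(adj, function(v) nms[as.integer(v)])
  names(adj) <- nms
  strength <- stats::setNames(igraph::strength(
    graph, weights = wts), nms)
  seeds <- nms[order(-strength, nms)]
  covered <- character(0)
  cores <- list()
  for (v in seeds) {
    if (v %in% covered) next
    nb <- adj[[v]]
    if (length(nb) == 0L) next
    wnb <- wmap[pair_key(v, nb)]
    best <- nb[order(-wnb, nb)][1L]
    memb <- c(v, best)
    repeat {
      cand <- setdiff(unique(unlist(adj[memb], use.names = FALSE)), memb)
      if (length(cand) == 0L) break
      cand <- sort(cand)
      dens <- vapply(cand, function(u)
        weighted_density(graph, c(memb, u)), numeric(1L))
      dia <- vapply(cand, function(u)
        hop_diameter(graph, c(memb, u)), numeric(1L))
      ok <- dens >= params$lambda & dia <= params$delta
      if (!any(ok)) break
      pick <- cand[ok][order(-dens[ok], cand[ok])][1L]
      memb <- c(memb, pick)
    }
    if (length(memb) >= params$min_core_size &&
        weighted_density(graph, memb) >= params$lambda &&
        hop_diameter(graph, memb) <= params$delta) {
      cores[[length(cores) + 1L]] <- new_cluster(graph, memb, "core")
      covered <- union(covered, memb)
    }
  }
  cores
}

#' Expand a core with second-order-neighbor attachments
#'
#' Implements the attachment phase of the core-attachment model: candidate
#' attachments are the nodes within 2 hops of any core member (in the full
#' graph) that are not already in the core. A candidate is attached when
#' its total edge weight into the core reaches `attach_ratio` times the
#' core members' average internal weighted degree. Every candidate is
#' judged against the original core — attachment does not chain — so the
#' result is independent of evaluation order.
#'
#' @param graph a weighted PPI graph.
#' @param core a `ppi_cluster` from [detect_cores()].
#' @param params a [detection_params()] object.
#' @return a `ppi_cluster` with `stage = "expanded"`; the core members are
#'   always a subset of the result.
#' @export
expand_core <- function(graph, core, params = detection_params()) {
  memb <- core$members
  nms <- igraph::V(graph)$name
  reach <- unique(unlist(lapply(igraph::ego(graph, order = 2, nodes = memb),
                                function(v) nms[as.integer(v)])))
  cand <- setdiff(reach, memb)
  if (length(cand) == 0L) return(new_cluster(graph, memb, "expanded"))
  wts <- if (is_weighted_ppi(graph)) igraph::E(graph)$weight
         else rep(1, igraph::ecount(graph))
  el <- edge_ends(graph)
  wmap <- stats::setNames(wts, pair_key(el[, 1L], el[, 2L]))
  conn_to_core <- function(p) {
    k <- pair_key(p, memb)
    sum(wmap[k], na.rm = TRUE)
  }
  int_deg <- vapply(memb, function(x)
    sum(wmap[pair_key(x, setdiff(memb, x))], na.rm = TRUE), numeric(1L))
  threshold <- params$attach_ratio * mean(int_deg)
  conn <- vapply(cand, conn_to_core, numeric(1L))
  attached <- cand[conn >= threshold & conn > 0]
  new_cluster(graph, c(memb, attached), "expanded")
}

#' Drop redundant clusters
#'
#' Post-processing of the expanded clusters: processed in decreasing size
#' order (ties broken lexicographically by membership), a cluster is
#' dropped when its neighborhood affinity with an already-kept cluster
#' reaches `dedup_na`. Exact duplicates (affinity 1) are always dropped;
#' genuine overlaps below the threshold survive, since shared subunits
#' between complexes are biologically real.
#'
#' @param clusters list of `ppi_cluster` objects.
#' @param params a [detection_params()] object.
#' @return a [complex_set()] labelled `"predicted"`.
#' @export
deduplicate <- function(clusters, params = detection_params()) {
  if (length(clusters) == 0L) {
    return(structure(list(complexes = list(), label = "predicted"),
                     class = "complex_set"))
  }
  membs <- lapply(clusters, `[[`, "members")
  keys <- vapply(membs, paste, character(1L), collapse = "\t")
  ord <- order(-lengths(membs), keys)
  kept <- list()
  for (i in ord) {
    a <- membs[[i]]
    redundant <- any(vapply(kept, function(b) {
      ov <- length(intersect(a, b))
      ov * ov / (length(a) * length(b)) >= params$dedup_na
    }, logical(1L)))
    if (!redundant) kept[[length(kept) + 1L]] <- a
  }
  suppressWarnings(complex_set(kept, label = "predicted"))
}
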