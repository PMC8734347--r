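#' Synthetic-data configuration
#'
#' Parameters of the planted-complex generator. The defaults emulate the
#' structure the detection model assumes: a PPI network containing dense,
#' compact protein complexes over a sparse background, together with an
#' expression time course (36 points over three cycles, mirroring a yeast
#' metabolic-cycle design) in which complex co-members share a latent
#' periodic profile.
#'
#' @param n_complexes number of planted complexes.
#' @param size_range integer `c(min, max)` complex sizes; `min >= 3`.
#' @param p_in within-complex edge probability.
#' @param p_out background edge probability (between any pair not inside
#'   the same complex); must be `< p_in`.
#' @param n_background_nodes extra nodes belonging to no complex.
#' @param n_timepoints expression time points `T` (default 36).
#' @param rho target within-complex expression correlation in `[0, 1]`
#'   (share of a member profile's variance carried by the complex's latent
#'   profile).
#' @param noise_sd standard deviation of additive observation noise on
#'   every expression value.
#' @param seed RNG seed; the generator is fully reproducible from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_complexes = 20L, size_range = c(4L, 8L),
                         p_in = 0.95, p_out = 0.005,
                         n_background_nodes = 40L, n_timepoints = 36L,
                         rho = 0.8, noise_sd = 0.3, seed = 1L) {
  stopifnot(n_complexes >= 1, length(size_range) == 2L,
            size_range[1L] >= 3, size_range[2L] >= size_range[1L],
            p_out >= 0, p_out < p_in, p_in <= 1,
            n_background_nodes >= 0, n_timepoints >= 2,
            rho >= 0, rho <= 1, noise_sd >= 0)
  structure(list(n_complexes = as.integer(n_complexes),
                 size_range = as.integer(size_range),
                 p_in = p_in, p_out = p_out,
                 n_background_nodes = as.integer(n_background_nodes),
                 n_timepoints = as.integer(n_timepoints),
                 rho = rho, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# internal edge draw for one complex; members must form a connected
# subgraph of hop diameter <= 2 so that planted complexes are detectable
# in principle — draws violating this are rejected and redrawn
draw_complex_edges <- function(members, p_in, max_tries = 200L) {
  k <- length(members)
  pairs <- t(utils::combn(members, 2L))
  for (try in seq_len(max_tries)) {
    keep <- stats::runif(nrow(pairs)) < p_in
    if (!any(keep)) next
    sub <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE],
                                       directed = FALSE)
    if (igraph::vcount(sub) == k && igraph::is_connected(sub) &&
        igraph::diameter(sub, weights = NA) <= 2) {
      return(pairs[keep, , drop = FALSE])
    }
  }
  stop("could not draw a connected diameter-2 complex; raise p_in")
}

#' Generate a synthetic PPI network with planted complexes
#'
#' Plants `n_complexes` disjoint complexes with sizes uniform in
#' `size_range`. Within-complex edges appear independently with
#' probability `p_in` (redrawn until each complex is connected with hop
#' diameter at most 2); all remaining node pairs get background edges with
#' probability `p_out`. Each complex receives a latent sinusoidal
#' expression profile with random phase, three cycles across the time
#' course; a member's profile mixes that latent signal (variance share
#' `rho`) with an independent component, plus observation noise of
#' standard deviation `noise_sd`. Background nodes get independent
#' profiles.
#'
#' @param config a [synth_config()].
#' @return list with `network` (unweighted [ppi_network()]), `expression`
#'   (matrix, genes x time points) and `truth` (the planted
#'   [complex_set()], labelled `"truth"`).
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  sizes <- config$size_range[1L] +
    sample.int(config$size_range[2L] - config$size_range[1L] + 1L,
               config$n_complexes, replace = TRUE) - 1L
  n_total <- sum(sizes) + config$n_background_nodes
  ids <- sprintf("P%04d", seq_len(n_total))
  assign_ix <- rep(0L, n_total)  # 0 = background
  assign_ix[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)
  truth <- lapply(seq_along(sizes), function(k) ids[assign_ix == k])

  edges <- do.call(rbind, lapply(truth, draw_complex_edges,
                                 p_in = config$p_in))
  # background edges over all pairs not inside the same complex
  all_pairs <- t(utils::combn(n_total, 2L))
  same <- assign_ix[all_pairs[, 1L]] == assign_ix[all_pairs[, 2L]] &
    assign_ix[all_pairs[, 1L]] != 0L
  bg_pairs <- all_pairs[!same, , drop = FALSE]
  bg_keep <- stats::runif(nrow(bg_pairs)) < config$p_out
  if (any(bg_keep)) {
    bg <- cbind(ids[bg_pairs[bg_keep, 1L]], ids[bg_pairs[bg_keep, 2L]])
    edges <- rbind(edges, bg)
  }
  net <- ppi_network(edges[, 1L], edges[, 2L], nodes = ids)

  tp <- config$n_timepoints
  phase <- stats::runif(config$n_complexes, 0, 2 * pi)
  tgrid <- 2 * pi * 3 * seq_len(tp) / tp
  expr <- matrix(0, n_total, tp, dimnames = list(ids, paste0("t", 1:tp)))
  for (k in seq_along(sizes)) {
    latent <- sin(tgrid + phase[k])
    latent <- as.numeric(scale(latent))
    for (id in truth[[k]]) {
      indep <- as.numeric(scale(stats::rnorm(tp)))
      expr[id, ] <- sqrt(config$rho) * latent +
        sqrt(1 - config$rho) * indep
    }
  }
  bg_ids <- ids[assign_ix == 0L]
  if (length(bg_ids)) {
    expr[bg_ids, ] <- stats::rnorm(length(bg_ids) * tp)
  }
  expr <- expr + stats::rnorm(length(expr), sd = config$noise_sd)

  list(network = net, expression = expr,
       truth = complex_set(truth, label = "truth"))
}

#' Randomly rewire a network
#'
#' Removes a fraction of the edges uniformly at random and adds random
#' non-edges, emulating the false negatives and false positives of
#' high-throughput interaction screens. Exactly
#' `round(remove_frac * |E|)` edges are removed and
#' `round(add_frac * |E|)` non-adjacent pairs (of the input graph) are
#' added, so the resulting edge count is
#' `|E| - round(remove_frac * |E|) + round(add_frac * |E|)`.
#'
#' @param net a PPI graph.
#' @param add_frac,remove_frac fractions in `[0, 1)` of the input edge
#'   count.
#' @param seed RNG seed.
#' @return the perturbed graph (same node set). If `net` is weighted,
#'   added edges get weight 1.
#' @export
perturb_network <- function(net, add_frac = 0, remove_frac = 0,
                            seed = 1L) {
  stopifnot(add_frac >= 0, add_frac < 1, remove_frac >= 0, remove_frac < 1)
  set.seed(seed)
  ne <- igraph::ecount(net)
  n_rm <- round(remove_frac * ne)
  n_add <- round(add_frac * ne)
  out <- net
  if (n_rm > 0) {
    out <- igraph::delete_edges(out, sample(seq_len(ne), n_rm))
  }
  if (n_add > 0) {
    nms <- igraph::V(net)$name
    all_pairs <- t(utils::combn(length(nms), 2L))
    adj_key <- {
      el <- edge_ends(net)
      pair_key(el[, 1L], el[, 2L])
    }
    pk <- pair_key(nms[all_pairs[, 1L]], nms[all_pairs[, 2L]])
    non_edges <- which(!(pk %in% adj_key))
    if (length(non_edges) < n_add) {
      stop("not enough non-edges to add")
    }
    pick <- all_pairs[sample(non_edges, n_add), , drop = FALSE]
    new_edges <- as.vector(t(cbind(nms[pick[, 1L]], nms[pick[, 2L]])))
    if (is_weighted_ppi(out)) {
      out <- igraph::add_edges(out, new_edges, weight = 1)
    } else {
      out <- igraph::add_edges(out, new_edges)
    }
  }
  out
}
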