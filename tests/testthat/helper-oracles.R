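# Independent oracles and random fixtures. Every oracle here deliberately
# uses a different code path from the package implementation it checks.

# Erdos-Renyi PPI graph with optional uniform random weights
random_ppi <- function(n, p, seed, weighted = FALSE) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample(length(keep), 2L)] <- TRUE
  pairs <- pairs[keep, , drop = FALSE]
  w <- if (weighted) stats::runif(nrow(pairs)) else NULL
  ppi_network(pairs[, 1L], pairs[, 2L], weight = w, nodes = ids)
}

# brute-force resource-allocation index via the adjacency matrix
oracle_wra <- function(g, include_endpoints = FALSE) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A <- A > 0
  nms <- rownames(A)
  deg <- rowSums(A)
  el <- igraph::as_edgelist(g, names = TRUE)
  out <- numeric(nrow(el))
  for (k in seq_len(nrow(el))) {
    i <- el[k, 1L]; j <- el[k, 2L]
    s <- 0
    for (u in nms) {
      if (u == i || u == j) next
      if (A[i, u] && A[j, u]) s <- s + 1 / (deg[u] + 1)
    }
    if (include_endpoints) s <- s + 1 / (deg[i] + 1) + 1 / (deg[j] + 1)
    out[k] <- s
  }
  names(out) <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]),
                      sep = "\t")
  out
}

# textbook two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  sum((x - xm) * (y - ym)) /
    (sqrt(sum((x - xm)^2)) * sqrt(sum((y - ym)^2)))
}

# hop diameter of an induced subgraph via hand-rolled BFS
oracle_diameter <- function(g, members) {
  members <- sort(unique(members))
  if (length(members) == 1L) return(0)
  el <- igraph::as_edgelist(g, names = TRUE)
  inset <- el[, 1L] %in% members & el[, 2L] %in% members
  adj <- lapply(stats::setNames(members, members), function(v) {
    c(el[inset & el[, 1L] == v, 2L], el[inset & el[, 2L] == v, 1L])
  })
  worst <- 0
  for (src in members) {
    dist <- stats::setNames(rep(Inf, length(members)), members)
    dist[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in adj[[v]]) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          queue <- c(queue, u)
        }
      }
    }
    worst <- max(worst, max(dist))
  }
  worst
}

# weighted density by looping over member pairs against the edge list
oracle_density <- function(g, members) {
  members <- sort(unique(members))
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight
       else rep(1, nrow(el))
  k <- length(members)
  m <- 0
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      hit <- (el[, 1L] == members[a] & el[, 2L] == members[b]) |
             (el[, 1L] == members[b] & el[, 2L] == members[a])
      if (any(hit)) m <- m + sum(w[hit])
    }
  }
  2 * m / (k * (k - 1))
}

# exhaustive maximum-weight matching optimum by bitmask dynamic programming
# over every injective benchmark->prediction assignment (n, m small)
oracle_mmr <- function(na_mat) {
  n <- nrow(na_mat); m <- ncol(na_mat)
  stopifnot(m <= 20)
  dp <- rep(-Inf, 2^m)
  dp[1L] <- 0
  for (i in seq_len(n)) {
    nd <- dp  # skipping row i is always allowed
    for (mask in 0:(2^m - 1L)) {
      if (is.infinite(dp[mask + 1L])) next
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0L) {
          v <- dp[mask + 1L] + na_mat[i, j]
          if (v > nd[mask + bit + 1L]) nd[mask + bit + 1L] <- v
        }
      }
    }
    dp <- nd
  }
  max(dp) / n
}

# random complex set over an alphabet of protein IDs
random_complex_set <- function(n_complexes, alphabet, seed,
                               size_range = c(2L, 6L)) {
  set.seed(seed)
  complexes <- lapply(seq_len(n_complexes), function(i) {
    k <- sample(seq(size_range[1L], size_range[2L]), 1L)
    sample(alphabet, min(k, length(alphabet)))
  })
  suppressWarnings(complex_set(complexes))
}

# random set of pairwise-disjoint complexes (a partial partition of the
# alphabet); disjointness is what makes PPV and SEP reach 1 when a set is
# scored against itself
random_disjoint_complex_set <- function(n_complexes, alphabet, seed,
                                        size_range = c(2L, 6L)) {
  set.seed(seed)
  pool <- sample(alphabet)
  complexes <- list()
  for (i in seq_len(n_complexes)) {
    k <- sample(seq(size_range[1L], size_range[2L]), 1L)
    if (length(pool) < k) break
    complexes[[length(complexes) + 1L]] <- pool[seq_len(k)]
    pool <- pool[-seq_len(k)]
  }
  complex_set(complexes)
}

# small expression fixture: named profiles as a matrix
expr_fixture <- function(profiles) {
  do.call(rbind, profiles)
}
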