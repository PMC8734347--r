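#' Overlap, affinity and Jaccard matrices between two complex sets
#'
#' For a benchmark set \eqn{R} (n complexes) and a predicted set \eqn{P}
#' (m clusters), computes the n x m matrix of overlap counts
#' \eqn{T_{ij} = |R_i \cap P_j|}, the neighborhood-affinity matrix
#' \eqn{NA_{ij} = T_{ij}^2 / (|R_i| |P_j|)} and the Jaccard matrix
#' \eqn{J_{ij} = T_{ij} / |R_i \cup P_j|}.
#'
#' @param ref benchmark [complex_set()] (non-empty).
#' @param pred predicted [complex_set()] (non-empty).
#' @return object of class `match_matrix` with fields `overlap`, `na`,
#'   `jaccard` (n x m matrices), `n`, `m`, `ref_sizes`, `pred_sizes`.
#' @export
build_match_matrix <- function(ref, pred) {
  stopifnot(inherits(ref, "complex_set"), inherits(pred, "complex_set"))
  n <- length(ref$complexes)
  m <- length(pred$complexes)
  if (n == 0L || m == 0L) stop("empty complex set: metrics undefined")
  rs <- lengths(ref$complexes)
  ps <- lengths(pred$complexes)
  ov <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    ri <- ref$complexes[[i]]
    for (j in seq_len(m)) {
      ov[i, j] <- length(intersect(ri, pred$complexes[[j]]))
    }
  }
  na_mat <- ov^2 / outer(rs, ps)
  jac <- ov / (outer(rs, ps, `+`) - ov)
  structure(list(overlap = ov, na = na_mat, jaccard = jac,
                 n = n, m = m, ref_sizes = rs, pred_sizes = ps),
            class = "match_matrix")
}

#' Sensitivity, positive predictive value and accuracy
#'
#' \deqn{Sn = \frac{\sum_i \max_j T_{ij}}{\sum_i |R_i|}, \quad
#'       PPV = \frac{\sum_j \max_i T_{ij}}{\sum_j \sum_i T_{ij}}, \quad
#'       ACC = \sqrt{Sn \cdot PPV}.}
#' `PPV` is 0 when its denominator is 0 (no overlap anywhere).
#'
#' @param mm a [build_match_matrix()] result.
#' @return named numeric vector `c(sn, ppv, acc)`.
#' @export
sn_ppv_acc <- function(mm) {
  sn <- sum(apply(mm$overlap, 1L, max)) / sum(mm$ref_sizes)
  denom <- sum(mm$overlap)
  ppv <- if (denom > 0) sum(apply(mm$overlap, 2L, max)) / denom else 0
  c(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

# shared precision/recall machinery over a boolean match matrix
prf_from_matches <- function(match, n, m) {
  precision <- sum(apply(match, 2L, any)) / m
  recall <- sum(apply(match, 1L, any)) / n
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f = f)
}

#' Jaccard-based precision, recall and f-measure
#'
#' A predicted cluster matches a benchmark complex when their Jaccard
#' similarity is strictly greater than 0.5. Precision is the fraction of
#' matched predictions, recall the fraction of matched benchmark
#' complexes, f-measure their harmonic mean (0 when both are 0).
#'
#' @param mm a [build_match_matrix()] result.
#' @return named vector `c(precision, recall, f_measure)`.
#' @export
jaccard_prf <- function(mm) {
  v <- prf_from_matches(mm$jaccard > 0.5, mm$n, mm$m)
  c(precision = unname(v["precision"]), recall = unname(v["recall"]),
    f_measure = unname(v["f"]))
}

#' Neighborhood-affinity precision+, recall+ and f-measure+
#'
#' A pair matches when the neighborhood affinity
#' \eqn{|R_i \cap P_j|^2 / (|R_i| |P_j|)} reaches the threshold `t`
#' (inclusive, i.e. affinity >= t).
#'
#' @param mm a [build_match_matrix()] result.
#' @param t affinity threshold in `(0, 1]` (default 0.2).
#' @return named vector `c(precision_plus, recall_plus, f_measure_plus)`.
#' @export
plus_prf <- function(mm, t = 0.2) {
  stopifnot(t > 0, t <= 1)
  v <- prf_from_matches(mm$na >= t, mm$n, mm$m)
  c(precision_plus = unname(v["precision"]),
    recall_plus = unname(v["recall"]),
    f_measure_plus = unname(v["f"]))
}

#' Maximum matching ratio
#'
#' Total neighborhood affinity of a maximum-weight one-to-one matching
#' between benchmark complexes and predicted clusters, divided by the
#' number of benchmark complexes n. Each benchmark complex and each
#' prediction is used at most once, so redundant predictions cannot
#' inflate the score.
#'
#' @param mm a [build_match_matrix()] result.
#' @return MMR in `[0, 1]`.
#' @export
mmr <- function(mm) {
  pos <- which(mm$na > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(0)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, mm$n), rep(TRUE, mm$m)),
    edges = as.vector(t(cbind(pos[, 1L], mm$n + pos[, 2L]))))
  match <- igraph::max_bipartite_match(
    g, weights = mm$na[pos])
  match$matching_weight / mm$n
}

#' Fraction match
#'
#' Fraction of benchmark complexes having at least one predicted cluster
#' with neighborhood affinity at or above `threshold` (0.25 by
#' convention).
#'
#' @param mm a [build_match_matrix()] result.
#' @param threshold affinity level defining a match.
#' @return FRM in `[0, 1]`.
#' @export
frm <- function(mm, threshold = 0.25) {
  mean(apply(mm$na >= threshold, 1L, any))
}

#' Separation
#'
#' Row/column-normalized overlap products
#' \deqn{sep_{ij} = \frac{T_{ij}}{\sum_{j'} T_{ij'}} \cdot
#'                  \frac{T_{ij}}{\sum_{i'} T_{i'j}}}
#' (0 where a denominator is 0), averaged complex-wise
#' (\eqn{\sum sep_{ij} / n}) and cluster-wise (\eqn{\sum sep_{ij} / m});
#' SEP is the geometric mean of the two averages. High separation means
#' overlaps concentrate in an unambiguous one-to-one correspondence.
#'
#' @param mm a [build_match_matrix()] result.
#' @return SEP in `[0, 1]`.
#' @export
separation <- function(mm) {
  rsum <- rowSums(mm$overlap)
  csum <- colSums(mm$overlap)
  rnorm_t <- sweep(mm$overlap, 1L, ifelse(rsum > 0, rsum, 1), `/`)
  cnorm_t <- sweep(mm$overlap, 2L, ifelse(csum > 0, csum, 1), `/`)
  sep_ij <- rnorm_t * cnorm_t
  total <- sum(sep_ij)
  sqrt((total / mm$n) * (total / mm$m))
}

#' Score a prediction against a benchmark with the full metric battery
#'
#' Computes every complex-prediction quality measure on one pair of
#' complex sets: Sn/PPV/ACC, Jaccard precision/recall/f-measure,
#' neighborhood-affinity precision+/recall+/f-measure+, MMR, FRM, SEP,
#' and the composites `f_mmr = mmr + f_measure_plus` and
#' `cs = mmr + frm + sep + acc + f_measure`.
#'
#' @param ref benchmark [complex_set()].
#' @param pred predicted [complex_set()].
#' @param t neighborhood-affinity match threshold (default 0.2).
#' @param frm_threshold affinity level used by [frm()] (default 0.25).
#' @return object of class `metric_report`: a named list of scalars.
#' @export
score_complexes <- function(ref, pred, t = 0.2, frm_threshold = 0.25) {
  mm <- build_match_matrix(ref, pred)
  spa <- sn_ppv_acc(mm)
  jac <- jaccard_prf(mm)
  plus <- plus_prf(mm, t = t)
  mmr_v <- mmr(mm)
  frm_v <- frm(mm, threshold = frm_threshold)
  sep_v <- separation(mm)
  rep <- c(as.list(spa), as.list(jac), as.list(plus),
           list(mmr = mmr_v, frm = frm_v, sep = sep_v))
  rep$f_mmr <- rep$mmr + rep$f_measure_plus
  rep$cs <- rep$mmr + rep$frm + rep$sep + rep$acc + rep$f_measure
  rep$t <- t
  rep$n <- mm$n
  rep$m <- mm$m
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report (n=%d benchmark, m=%d predicted, t=%.2f)\n",
              x$n, x$m, x$t))
  flds <- c("sn", "ppv", "acc", "precision", "recall", "f_measure",
            "precision_plus", "recall_plus", "f_measure_plus",
            "mmr", "frm", "sep", "f_mmr", "cs")
  for (f in flds) cat(sprintf("  %-15s %.4f\n", f, x[[f]]))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  flds <- c("sn", "ppv", "acc", "precision", "recall", "f_measure",
            "precision_plus", "recall_plus", "f_measure_plus",
            "mmr", "frm", "sep", "f_mmr", "cs", "t", "n", "m")
  as.data.frame(x[flds], ...)
}
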