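#' Sweep the blend parameter alpha
#'
#' Runs detection and evaluation once per value of the topology/expression
#' blend parameter and tabulates the full metric battery, the experiment
#' used to pick the default `alpha = 0.3` (f-measure+ plateaus from about
#' 0.3 and accuracy peaks there on the reference data).
#'
#' @param net unweighted PPI graph.
#' @param expr expression matrix.
#' @param truth benchmark [complex_set()].
#' @param alphas grid of alpha values (default 0.1 to 0.9 by 0.1).
#' @param params base [detection_params()]; `alpha` is overridden per row.
#' @return data.frame, one row per alpha, columns `alpha` plus all
#'   [score_complexes()] fields.
#' @export
bench_alpha <- function(net, expr, truth, alphas = seq(0.1, 0.9, by = 0.1),
                        params = detection_params()) {
  rows <- lapply(alphas, function(a) {
    p <- params
    p$alpha <- a
    fit <- nrage_wpn(net, expr, p)
    rep <- score_or_zero(truth, fit$complexes, p$t)
    cbind(data.frame(alpha = a), as.data.frame(rep))
  })
  do.call(rbind, rows)
}

#' Sweep the neighborhood-affinity match threshold t
#'
#' Detection is run once (t does not affect detection) and the prediction
#' is re-scored at each threshold, probing robustness of the
#' affinity-based precision/recall to the match definition.
#'
#' @inheritParams bench_alpha
#' @param thresholds grid of t values (default the nine thresholds 0.1 to
#'   0.9).
#' @return data.frame, one row per threshold.
#' @export
bench_threshold <- function(net, expr, truth,
                            thresholds = seq(0.1, 0.9, by = 0.1),
                            params = detection_params()) {
  fit <- nrage_wpn(net, expr, params)
  rows <- lapply(thresholds, function(tt) {
    rep <- score_or_zero(truth, fit$complexes, tt)
    cbind(data.frame(threshold = tt), as.data.frame(rep))
  })
  do.call(rbind, rows)
}

#' Paired ablation runs
#'
#' Runs the pipeline twice on identical input — once with a component
#' enabled and once disabled — and reports both metric rows plus their
#' difference (on minus off). `which = "ra"` toggles the
#' resource-allocation term of the edge weights; `which = "sns"` toggles
#' the second-order-neighbor attachment phase.
#'
#' @inheritParams bench_alpha
#' @param which `"ra"` or `"sns"`.
#' @return data.frame with rows `on`, `off`, `delta`.
#' @export
bench_ablation <- function(net, expr, truth, which = c("ra", "sns"),
                           params = detection_params()) {
  which <- match.arg(which)
  p_on <- params
  p_off <- params
  p_off[[which]] <- FALSE
  p_on[[which]] <- TRUE
  fit_on <- nrage_wpn(net, expr, p_on)
  fit_off <- nrage_wpn(net, expr, p_off)
  r_on <- as.data.frame(score_or_zero(truth, fit_on$complexes, params$t))
  r_off <- as.data.frame(score_or_zero(truth, fit_off$complexes, params$t))
  delta <- r_on - r_off
  out <- rbind(r_on, r_off, delta)
  cbind(data.frame(component = which, run = c("on", "off", "delta")), out)
}

# scoring helper tolerant of empty predictions (all-zero report)
score_or_zero <- function(truth, pred, t) {
  if (length(pred) == 0L) {
    zero <- complex_set(list("__none__"), label = "predicted")
    rep <- score_complexes(truth, zero, t = t)
    rep$m <- 0L
    return(rep)
  }
  score_complexes(truth, pred, t = t)
}
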