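#' Per-edge curvature differences between two networks
#'
#' For two curvature tables computed with the same order and mode on the
#' same node set, returns the difference control minus disease over the
#' union of the two edge sets; a pair absent from one table contributes
#' curvature 0 there (pairs absent from both have difference 0 and are not
#' listed).
#'
#' @param table1,table2 [curvature_map()] results on networks sharing the
#'   node label universe (`table1` is the reference, e.g. control).
#' @return data frame with columns `u`, `v`, `curv_control`,
#'   `curv_disease`, `delta`, one row per edge in either network.
#' @export
curvature_delta <- function(table1, table2) {
  for (t in list(table1, table2))
    if (!inherits(t, "curvature_table")) stop("inputs must be curvature tables")
  if (!identical(attr(table1, "labels"), attr(table2, "labels")))
    stop("curvature tables computed on different node sets")
  if (attr(table1, "d") != attr(table2, "d") ||
      attr(table1, "mode") != attr(table2, "mode"))
    stop("curvature tables computed with different d or mode")
  k1 <- paste(table1$u, table1$v, sep = "\r")
  k2 <- paste(table2$u, table2$v, sep = "\r")
  keys <- union(k1, k2)
  c1 <- table1$curvature[match(keys, k1)]
  c2 <- table2$curvature[match(keys, k2)]
  c1[is.na(c1)] <- 0
  c2[is.na(c2)] <- 0
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  labels <- attr(table1, "labels")
  out <- data.frame(u = parts[, 1L], v = parts[, 2L],
                    curv_control = c1, curv_disease = c2,
                    delta = c1 - c2, stringsAsFactors = FALSE)
  out[order(match(out$u, labels), match(out$v, labels)), , drop = FALSE]
}

#' Location, spread and histogram of a set of curvature differences
#'
#' @param deltas numeric vector of differences (or a data frame with a
#'   `delta` column).
#' @param bins approximate number of fixed-width histogram bins.
#' @return list with `mean`, `sd` (population standard deviation: the
#'   differences are treated as the full population of node pairs, not a
#'   sample), `breaks` and `counts`.
#' @export
delta_stats <- function(deltas, bins = 30) {
  x <- if (is.data.frame(deltas)) deltas$delta else as.numeric(deltas)
  if (!length(x)) stop("empty set of differences")
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  rng <- range(x)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  counts <- as.vector(table(cut(x, breaks, include.lowest = TRUE)))
  list(mean = mu, sd = sdev, breaks = breaks, counts = counts)
}

#' Outlier edges by absolute curvature difference
#'
#' @param deltas data frame as returned by [curvature_delta()] (needs
#'   columns `u`, `v`, `delta`).
#' @param cutoff positive threshold on `|delta|`, or `"auto"` for twice
#'   the population standard deviation.
#' @return the rows with `|delta| > cutoff`, ordered by decreasing
#'   `|delta|` with ties broken lexicographically by label pair; the
#'   cutoff used is attached as attribute `"cutoff"`.
#' @export
outlier_edges <- function(deltas, cutoff = "auto") {
  if (identical(cutoff, "auto")) {
    cutoff <- 2 * delta_stats(deltas)$sd
  } else if (!is.numeric(cutoff) || cutoff <= 0) {
    stop("cutoff must be a positive number or \"auto\"")
  }
  keep <- abs(deltas$delta) > cutoff
  out <- deltas[keep, , drop = FALSE]
  out <- out[order(-abs(out$delta), out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Normalise curvature differences to the range \[-1, 1\]
#'
#' Applies the linear map
#' \eqn{\eta(\Delta) = (2\Delta - high - low) / (high - low)} with `high`
#' and `low` the maximum and minimum difference over all edges, so that
#' curvature differences become comparable with plain edge-weight
#' differences (which already live in \[-1, 1\]).  When all differences
#' are equal the map is degenerate and every value is sent to 0.
#'
#' @param deltas numeric vector or data frame with a `delta` column.
#' @return numeric vector of normalised values, same length/order.
#' @export
normalize_deltas <- function(deltas) {
  x <- if (is.data.frame(deltas)) deltas$delta else as.numeric(deltas)
  if (!length(x)) stop("empty set of differences")
  hi <- max(x); lo <- min(x)
  if (hi == lo) return(rep(0, length(x)))
  (2 * x - hi - lo) / (hi - lo)
}

#' Edge-weight difference between two networks
#'
#' The baseline statistic: plain difference of edge weights, control minus
#' disease, with absent edges counting as weight 0.
#'
#' @param net1,net2 [weighted_network()] objects on the same labels.
#' @param e optional single edge (pair of labels/indices); when `NULL`,
#'   differences for the union of the two edge sets are returned.
#' @return a scalar (single edge) or data frame `u`, `v`, `weight_delta`.
#' @export
weight_delta <- function(net1, net2, e = NULL) {
  if (!identical(net1$labels, net2$labels)) stop("label mismatch")
  D <- net1$weights - net2$weights
  if (!is.null(e)) {
    idx <- .edge_idx(net1, e)
    return(D[idx[1L], idx[2L]])
  }
  present <- (net1$weights > 0) | (net2$weights > 0)
  idx <- which(upper.tri(D) & present, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(u = net1$labels[idx[, 1L]], v = net1$labels[idx[, 2L]],
             weight_delta = D[idx], stringsAsFactors = FALSE)
}

#' Curvature-based anomaly detection between two network snapshots
#'
#' The main entry point: given a control and a disease snapshot of a
#' network on the same nodes, computes the order-d 2-complex curvature of
#' every edge in both networks, their differences
#' \eqn{\Delta_e = C_{control}(e) - C_{disease}(e)}, summary statistics,
#' the outlier edge set (\eqn{|\Delta_e|} above the cutoff), normalised
#' differences, and the edge-weight-difference baseline.  Optionally
#' attaches null-model z-scores (see [null_delta_ensemble()]) for the
#' strongest outliers.
#'
#' @param control,disease [weighted_network()] objects on identical labels.
#' @param d face order (3, 4 or 5; default 5).
#' @param mode face mode, see [enumerate_faces()].
#' @param tau optional sparsification threshold applied to both inputs
#'   first (e.g. 0.4 for raw correlation matrices); `NULL` for
#'   already-thresholded inputs.
#' @param cutoff outlier cutoff on `|delta|`, or `"auto"` (twice the
#'   population standard deviation).
#' @param top_k number of top outliers to z-score when `replicates > 0`.
#' @param extra_edges optional list of additional edges (label pairs) to
#'   z-score alongside the top outliers.
#' @param replicates null-model replicates per scored edge (0 disables
#'   z-scoring; the customary choice is 100).
#' @param swap_factor edge swaps per replicate, as a multiple of the edge
#'   count.
#' @param seed integer seed for the null model.
#' @return an object of class `curvature_anomaly`: a list with components
#'   `records` (data frame: `edge_u`, `edge_v`, `curv_control`,
#'   `curv_disease`, `delta`, `norm_delta`, `weight_delta`, `z`; ordered
#'   by decreasing `|delta|`), `stats` (mean/sd of the deltas), `cutoff`,
#'   `n_outliers`, `d`, `mode`, `control`, `disease`, `call`.
#' @examples
#' pair <- planted_pair(n = 20, p = 0.25, effect = 1.5, k = 2, seed = 42)
#' fit <- curvature_anomaly(pair$control, pair$disease)
#' print(fit)
#' head(summary(fit))
#' @export
curvature_anomaly <- function(control, disease, d = 5,
                              mode = c("chordal", "all_cycles"), tau = NULL,
                              cutoff = "auto", top_k = 5, extra_edges = NULL,
                              replicates = 0, swap_factor = 5, seed = NULL) {
  mode <- match.arg(mode)
  if (!identical(control$labels, disease$labels))
    stop("control and disease networks must share the node label universe")
  if (!is.null(tau)) {
    control <- sparsify(control, tau)
    disease <- sparsify(disease, tau)
  }
  t1 <- curvature_map(control, d = d, mode = mode)
  t2 <- curvature_map(disease, d = d, mode = mode)
  dl <- curvature_delta(t1, t2)
  st <- delta_stats(dl)
  out <- outlier_edges(dl, cutoff)
  wd <- weight_delta(control, disease)
  kd <- paste(dl$u, dl$v, sep = "\r")
  kw <- paste(wd$u, wd$v, sep = "\r")
  records <- data.frame(edge_u = dl$u, edge_v = dl$v,
                        curv_control = dl$curv_control,
                        curv_disease = dl$curv_disease,
                        delta = dl$delta,
                        norm_delta = normalize_deltas(dl),
                        weight_delta = wd$weight_delta[match(kd, kw)],
                        z = NA_real_, stringsAsFactors = FALSE)
  records <- records[order(-abs(records$delta), records$edge_u,
                           records$edge_v), , drop = FALSE]
  rownames(records) <- NULL
  if (replicates >= 2) {
    score <- records[seq_len(min(top_k, nrow(records))), c("edge_u", "edge_v")]
    score <- unique(rbind(score,
      if (length(extra_edges)) do.call(rbind, lapply(extra_edges, function(e)
        data.frame(edge_u = e[1L], edge_v = e[2L], stringsAsFactors = FALSE)))))
    for (r in seq_len(nrow(score))) {
      ens <- null_delta_ensemble(control, disease,
                                 c(score$edge_u[r], score$edge_v[r]),
                                 d = d, mode = mode, R = replicates,
                                 swap_factor = swap_factor,
                                 seed = .derive_seed(if (is.null(seed)) 0L else seed, r))
      hit <- records$edge_u == score$edge_u[r] & records$edge_v == score$edge_v[r]
      records$z[hit] <- ens$z
    }
  }
  structure(list(records = records, stats = st,
                 cutoff = attr(out, "cutoff"), n_outliers = nrow(out),
                 d = d, mode = mode, control = control, disease = disease,
                 call = match.call()),
            class = "curvature_anomaly")
}

#' @export
print.curvature_anomaly <- function(x, ...) {
  cat(sprintf("curvature_anomaly (d = %d, mode = %s)\n", x$d, x$mode))
  cat(sprintf("  edges compared: %d\n", nrow(x$records)))
  cat(sprintf("  delta: mean %.4g, population sd %.4g\n",
              x$stats$mean, x$stats$sd))
  cat(sprintf("  outliers (|delta| > %.4g): %d\n", x$cutoff, x$n_outliers))
  top <- utils::head(x$records, 5L)
  if (nrow(top)) {
    cat("  strongest differences:\n")
    print(top, digits = 4)
  }
  invisible(x)
}

#' @export
summary.curvature_anomaly <- function(object, ...) {
  out <- object$records[abs(object$records$delta) > object$cutoff, ,
                        drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stats") <- object$stats
  attr(out, "cutoff") <- object$cutoff
  out
}

#' Histogram of curvature differences
#'
#' Plots the distribution of per-edge curvature differences of a
#' [curvature_anomaly()] fit, with the outlier cutoff marked.
#'
#' @param x a `curvature_anomaly` object.
#' @param ... passed to [graphics::hist()].
#' @export
plot.curvature_anomaly <- function(x, ...) {
  graphics::hist(x$records$delta, breaks = 30,
                 main = "Curvature differences (control - disease)",
                 xlab = expression(Delta[e]), ...)
  graphics::abline(v = c(-1, 1) * x$cutoff, lty = 2, col = "firebrick")
  invisible(x)
}
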