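#' Weighted undirected network
#'
#' Construct a weighted undirected network from a symmetric weight matrix.
#' Nodes are identified by unique character labels; an edge \{u, v\} exists
#' exactly when its weight is strictly positive.  The diagonal is always
#' forced to zero (self-correlations carry no information here).  Negative
#' entries, as found in raw correlation matrices, are tolerated at
#' construction time and are expected to be removed by [sparsify()] before
#' any curvature computation.
#'
#' @param weights square numeric matrix of edge weights;
#'   `weights[i, j]` must equal `weights[j, i]` up to `tol`.
#' @param labels character vector of node labels, one per row of
#'   `weights`.  Defaults to `"n000"`, `"n001"`, ... when missing.
#' @param symmetrize if `TRUE`, replace the matrix by `(W + t(W)) / 2`
#'   instead of rejecting asymmetric input.  Off by default so that
#'   malformed data fails loudly.
#' @param tol absolute tolerance for the symmetry check.
#' @return an object of class `weighted_network`: a list with components
#'   `labels` and `weights` (matrix with label dimnames).
#' @seealso [read_network()], [sparsify()], [mean_network()]
#' @export
weighted_network <- function(weights, labels = NULL, symmetrize = FALSE,
                             tol = 1e-9) {
  weights <- as.matrix(weights)
  if (!is.numeric(weights)) stop("weights must be numeric")
  if (nrow(weights) != ncol(weights))
    stop(sprintf("non-square matrix: %d x %d", nrow(weights), ncol(weights)))
  n <- nrow(weights)
  asym <- max(abs(weights - t(weights)), 0)
  if (asym > tol) {
    if (symmetrize) {
      weights <- (weights + t(weights)) / 2
    } else {
      stop(sprintf("asymmetric matrix (max |W - t(W)| = %.3g); use symmetrize = TRUE to average", asym))
    }
  } else {
    weights <- (weights + t(weights)) / 2  # remove sub-tolerance asymmetry
  }
  diag(weights) <- 0
  if (is.null(labels)) labels <- sprintf("n%03d", seq_len(n) - 1L)
  labels <- as.character(labels)
  if (length(labels) != n)
    stop(sprintf("label count mismatch: %d labels for %d nodes", length(labels), n))
  if (anyDuplicated(labels)) stop("node labels must be unique")
  dimnames(weights) <- list(labels, labels)
  structure(list(labels = labels, weights = weights),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  m <- n_edges(x)
  cat(sprintf("weighted_network: %d nodes, %d edges\n", length(x$labels), m))
  w <- x$weights[upper.tri(x$weights)]
  w <- w[w > 0]
  if (length(w))
    cat(sprintf("  edge weights: min %.4g, median %.4g, max %.4g\n",
                min(w), stats::median(w), max(w)))
  invisible(x)
}

#' Number of edges of a network
#'
#' @param net a [weighted_network()].
#' @return integer count of unordered node pairs with positive weight.
#' @export
n_edges <- function(net) {
  sum(net$weights[upper.tri(net$weights)] > 0)
}

#' List the edges of a network
#'
#' @param net a [weighted_network()].
#' @return data frame with columns `u`, `v` (labels, `u` before `v` in node
#'   order) and `weight`, one row per existing edge.
#' @export
edge_list <- function(net) {
  W <- net$weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(u = net$labels[idx[, 1L]],
             v = net$labels[idx[, 2L]],
             weight = W[idx],
             stringsAsFactors = FALSE)
}

# Resolve an edge given as a pair of labels or node indices to sorted
# integer indices.  Does not require the edge to exist.
.edge_idx <- function(net, e) {
  if (length(e) != 2L) stop("an edge is a pair of nodes")
  if (is.numeric(e)) {
    i <- as.integer(e)
    if (any(i < 1L | i > length(net$labels))) stop("node index out of range")
  } else {
    i <- match(as.character(e), net$labels)
    if (anyNA(i))
      stop("unknown node label(s): ", paste(e[is.na(i)], collapse = ", "))
  }
  if (i[1L] == i[2L]) stop("self-loops are not edges")
  sort(i)
}

# Internal: adjacency (logical) matrix.
.adj <- function(net) net$weights > 0

#' Read a connectivity matrix from a delimited text file
#'
#' Reads a plain-text square matrix (no header) as produced by
#' connectivity-matrix repositories.  The delimiter is sniffed from the
#' first line: a comma anywhere selects CSV, otherwise whitespace
#' delimiting is assumed.  An optional labels file supplies one node label
#' per line; otherwise labels default to `"n000"`, `"n001"`, ...
#'
#' @param matrix_path path to the matrix file.
#' @param labels_path optional path to a label file (one label per line,
#'   same length as the matrix dimension).
#' @param symmetrize,tol passed to [weighted_network()].
#' @return a [weighted_network()].  Negative entries are preserved; apply
#'   [sparsify()] to obtain the non-negative thresholded network used for
#'   curvature.
#' @export
read_network <- function(matrix_path, labels_path = NULL, symmetrize = FALSE,
                         tol = 1e-9) {
  first <- readLines(matrix_path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- utils::read.table(matrix_path, header = FALSE, sep = sep,
                           strip.white = TRUE,
                           colClasses = "numeric")
  W <- as.matrix(tab)
  dimnames(W) <- NULL
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- readLines(labels_path)
    labels <- labels[nzchar(trimws(labels))]
    labels <- trimws(labels)
    if (length(labels) != nrow(W))
      stop(sprintf("label count mismatch: %d labels for a %d x %d matrix",
                   length(labels), nrow(W), ncol(W)))
  }
  weighted_network(W, labels = labels, symmetrize = symmetrize, tol = tol)
}

#' Write a network as matrix and label files
#'
#' Inverse of [read_network()]: weights are printed at full precision so
#' that a write/read round trip reproduces them bit-identically.
#'
#' @param net a [weighted_network()].
#' @param matrix_path output path for the whitespace-delimited matrix.
#' @param labels_path optional output path for the label list.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, matrix_path, labels_path = NULL) {
  txt <- apply(net$weights, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = " "))
  writeLines(txt, matrix_path)
  if (!is.null(labels_path)) writeLines(net$labels, labels_path)
  invisible(net)
}

#' Element-wise mean of a cohort of networks
#'
#' Averages the weight matrices of several subjects measured on the same
#' node set, e.g. to build the mean control connectome of a cohort.
#'
#' @param nets list of [weighted_network()] objects with identical label
#'   ordering.
#' @return a [weighted_network()] whose weights are the element-wise
#'   arithmetic mean.
#' @export
mean_network <- function(nets) {
  if (!length(nets)) stop("empty list of networks")
  labs <- nets[[1L]]$labels
  for (k in seq_along(nets)) {
    if (!inherits(nets[[k]], "weighted_network"))
      stop("all elements must be weighted_network objects")
    if (!identical(nets[[k]]$labels, labs))
      stop(sprintf("label mismatch between network 1 and network %d", k))
  }
  W <- Reduce(`+`, lapply(nets, `[[`, "weights")) / length(nets)
  weighted_network(W, labels = labs)
}

#' Threshold-sparsify a network
#'
#' Sets every entry strictly below `tau` to zero.  Negative correlations
#' are thereby removed for any `tau > 0`, which restores the non-negative
#' weight function the curvature definition requires.  The returned
#' network carries the surviving edge count in attribute
#' `"surviving_edges"`.
#'
#' @param net a [weighted_network()].
#' @param tau threshold; entries `< tau` become 0 (default 0.4, the usual
#'   working point for fMRI correlation networks of this kind).
#' @return a new [weighted_network()].
#' @export
sparsify <- function(net, tau = 0.4) {
  if (tau <= 0)
    warning("tau <= 0 only clamps negative entries; the network keeps all positive edges")
  W <- net$weights
  W[W < tau] <- 0
  out <- weighted_network(W, labels = net$labels)
  attr(out, "surviving_edges") <- n_edges(out)
  out
}

#' Write a table of per-edge anomaly records
#'
#' Writes a TSV with header `edge_u`, `edge_v`, `curv_control`,
#' `curv_disease`, `delta`, `norm_delta`, `weight_delta`, `z`, rows ordered
#' by decreasing `|delta|` (ties broken lexicographically by label pair).
#'
#' @param records data frame with (at least) the columns above, as found in
#'   the `records` component of a [curvature_anomaly()] fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_anomaly_table <- function(records, path) {
  cols <- c("edge_u", "edge_v", "curv_control", "curv_disease",
            "delta", "norm_delta", "weight_delta", "z")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  records <- records[cols]
  if (nrow(records))
    records <- records[order(-abs(records$delta), records$edge_u,
                             records$edge_v), , drop = FALSE]
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
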