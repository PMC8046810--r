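#' Order-d 2-complex Forman-Ricci curvature of one edge
#'
#' Computes, for an edge e = \{u, v\} with weight w(e) > 0,
#' \deqn{C(e) = \omega(e)\Big[\sum_{f \ni e} \frac{\omega(e)}{\omega(f)}
#'   + \sum_{x \sim e} \frac{\omega(x)}{\omega(e)}
#'   - \sum_{(e', f):\, e, e' \in f,\ e \cap e' = \emptyset}
#'     \frac{\sqrt{\omega(e)\omega(e')}}{\omega(f)}\Big]}
#' where f runs over the 2-faces having e as a boundary edge, x over the
#' two endpoints, and the negative sum over parallel (disjoint) boundary
#' edge pairs within each face.  This is the within-face reduction of the
#' full curvature (see [forman_curvature_full()]); the two coincide
#' whenever e has no hanging edges.  A pair with zero weight has curvature
#' 0 by convention.
#'
#' @param net a [weighted_network()]; edge weights must be non-negative.
#' @param e an edge as a pair of labels or node indices.
#' @param d maximal face order (3, 4 or 5).
#' @param mode face enumeration mode, see [enumerate_faces()].
#' @param faces optional precomputed [enumerate_faces()] result (must
#'   match `d` and `mode`); when missing, the chordal faces through `e`
#'   are enumerated locally.
#' @return a numeric scalar.
#' @export
forman_curvature <- function(net, e, d = 5, mode = c("chordal", "all_cycles"),
                             faces = NULL) {
  mode <- match.arg(mode)
  idx <- .edge_idx(net, e)
  W <- net$weights
  if (any(W < 0)) stop("negative weights present; sparsify() the network first")
  we <- W[idx[1L], idx[2L]]
  if (we == 0) return(0)
  fl <- .faces_of_edge(net, idx, d, mode, faces)
  nw <- node_weight(net)
  .edge_curvature(W, idx, we, fl, unname(nw[idx[1L]] + nw[idx[2L]]))
}

# faces (as list of records) that contain edge idx as boundary edge
.faces_of_edge <- function(net, idx, d, mode, faces) {
  if (!is.null(faces)) {
    if (!inherits(faces, "face_set"))
      stop("faces must be an enumerate_faces() result")
    if (faces$d != d || faces$mode != mode || faces$n != length(net$labels))
      stop("face set was computed with different d, mode or network")
    fids <- faces$edge_faces[[.ekey(idx[1L], idx[2L])]]
    return(faces$faces[fids])
  }
  if (mode == "chordal") {
    A <- net$weights > 0
    .faces_through_edge(A, net$weights, idx[1L], idx[2L], d)
  } else {
    fs <- enumerate_faces(net, d = d, mode = "all_cycles")
    fs$faces[fs$edge_faces[[.ekey(idx[1L], idx[2L])]]]
  }
}

# within-face curvature given the faces through the edge
.edge_curvature <- function(W, idx, we, faces_e, nw_sum) {
  sumF <- 0; sumP <- 0
  for (f in faces_e) {
    if (f$weight <= 0)
      stop("face with non-positive weight encountered; weights are corrupt")
    sumF <- sumF + we / f$weight
    be <- .boundary_edges(f$boundary)
    for (r in seq_len(nrow(be))) {
      ep <- be[r, ]
      if (!any(ep %in% idx)) {
        sumP <- sumP + sqrt(we * W[ep[1L], ep[2L]]) / f$weight
      }
    }
  }
  we * (sumF - sumP) + nw_sum
}

#' Full-formula order-d curvature of one edge
#'
#' The unreduced curvature takes the parallel sum over *all* edges e'
#' parallel to e in the 2-complex (shared endpoint XOR shared face), each
#' contributing the absolute value of its net face-minus-endpoint term:
#' \deqn{C(e) = \omega(e)\Big[\sum_{f \ni e}\frac{\omega(e)}{\omega(f)}
#'   + \sum_{x \sim e}\frac{\omega(x)}{\omega(e)}
#'   - \sum_{e' \parallel e}\Big|\sum_{f \ni e, e'}
#'     \frac{\sqrt{\omega(e)\omega(e')}}{\omega(f)}
#'   - \sum_{x \sim e,\, x \sim e'}
#'     \frac{\omega(x)}{\sqrt{\omega(e)\omega(e')}}\Big|\Big]}
#' Because an edge pair sharing both an endpoint and a face is not
#' parallel, exactly one of the two inner sums is non-zero for each
#' parallel e'.  Intended for small graphs: the global parallel relation
#' is expensive.
#'
#' @inheritParams forman_curvature
#' @return a numeric scalar.
#' @seealso [curvature_agreement()] for the hanging-edge condition under
#'   which this equals [forman_curvature()].
#' @export
forman_curvature_full <- function(net, e, d = 5,
                                  mode = c("chordal", "all_cycles"),
                                  faces = NULL) {
  mode <- match.arg(mode)
  idx <- .edge_idx(net, e)
  W <- net$weights
  if (any(W < 0)) stop("negative weights present; sparsify() the network first")
  we <- W[idx[1L], idx[2L]]
  if (we == 0) return(0)
  faces_e <- .faces_of_edge(net, idx, d, mode, faces)
  nw <- node_weight(net)
  sumF <- 0
  # per-candidate face sums: A_{e'} = sum over shared faces
  Aterm <- new.env(parent = emptyenv())
  for (f in faces_e) {
    if (f$weight <= 0)
      stop("face with non-positive weight encountered; weights are corrupt")
    sumF <- sumF + we / f$weight
    be <- .boundary_edges(f$boundary)
    for (r in seq_len(nrow(be))) {
      ep <- sort(be[r, ])
      if (identical(ep, idx)) next
      k <- .ekey(ep[1L], ep[2L])
      prev <- if (is.null(Aterm[[k]])) 0 else Aterm[[k]]
      Aterm[[k]] <- prev + sqrt(we * W[ep[1L], ep[2L]]) / f$weight
    }
  }
  # candidates: edges sharing a face (keys of Aterm) plus adjacent edges
  adj <- new.env(parent = emptyenv())
  A <- W > 0
  for (swp in 1:2) {
    s <- idx[swp]
    for (o in which(A[s, ])) {
      if (o == idx[3L - swp]) next
      adj[[.ekey(s, o)]] <- s   # the shared endpoint
    }
  }
  keys <- union(ls(Aterm), ls(adj))
  par_sum <- 0
  for (k in sort(keys)) {
    has_face <- !is.null(Aterm[[k]])
    has_node <- !is.null(adj[[k]])
    if (has_face == has_node) next   # not parallel (both or neither)
    if (has_face) {
      par_sum <- par_sum + abs(Aterm[[k]])
    } else {
      ep <- as.integer(strsplit(k, ":", fixed = TRUE)[[1L]])
      s <- adj[[k]]
      wep <- W[ep[1L], ep[2L]]
      par_sum <- par_sum + abs(nw[s] / sqrt(we * wep))
    }
  }
  unname(we * (sumF - par_sum) + (nw[idx[1L]] + nw[idx[2L]]))
}

#' Curvature of every edge of a network
#'
#' Computes the order-d 2-complex curvature for all existing edges with a
#' single shared face enumeration.  Node pairs without an edge have
#' curvature 0 by convention and are not listed.
#'
#' @inheritParams forman_curvature
#' @param faces optional precomputed [enumerate_faces()] result.
#' @return an object of class `curvature_table`: a data frame with columns
#'   `u`, `v`, `curvature` (one row per edge, node order), carrying
#'   attributes `d`, `mode` and `labels`.
#' @export
curvature_map <- function(net, d = 5, mode = c("chordal", "all_cycles"),
                          faces = NULL) {
  mode <- match.arg(mode)
  W <- net$weights
  if (any(W < 0)) stop("negative weights present; sparsify() the network first")
  n <- nrow(W)
  if (is.null(faces)) faces <- enumerate_faces(net, d = d, mode = mode)
  else if (!inherits(faces, "face_set") || faces$d != d ||
           faces$mode != mode || faces$n != n)
    stop("face set was computed with different d, mode or network")
  FI <- matrix(0, n, n)   # sum of 1/omega(f) over boundary faces
  PM <- matrix(0, n, n)   # parallel sums sqrt(w(e) w(e')) / omega(f)
  for (f in faces$faces) {
    if (f$weight <= 0)
      stop("face with non-positive weight encountered; weights are corrupt")
    be <- .boundary_edges(f$boundary)
    k <- nrow(be)
    for (r in seq_len(k)) {
      i <- be[r, 1L]; j <- be[r, 2L]
      FI[i, j] <- FI[i, j] + 1 / f$weight
      FI[j, i] <- FI[i, j]
    }
    dp <- .disjoint_positions(k)
    for (r in seq_len(nrow(dp))) {
      e1 <- be[dp[r, 1L], ]; e2 <- be[dp[r, 2L], ]
      w1 <- W[e1[1L], e1[2L]]; w2 <- W[e2[1L], e2[2L]]
      g <- sqrt(w1 * w2) / f$weight
      PM[e1[1L], e1[2L]] <- PM[e1[1L], e1[2L]] + g
      PM[e1[2L], e1[1L]] <- PM[e1[1L], e1[2L]]
      PM[e2[1L], e2[2L]] <- PM[e2[1L], e2[2L]] + g
      PM[e2[2L], e2[1L]] <- PM[e2[1L], e2[2L]]
    }
  }
  nw <- node_weight(net)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  curv <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    we <- W[i, j]
    curv[r] <- we * we * FI[i, j] + (nw[i] + nw[j]) - we * PM[i, j]
  }
  out <- data.frame(u = net$labels[idx[, 1L]], v = net$labels[idx[, 2L]],
                    curvature = unname(curv), stringsAsFactors = FALSE)
  structure(out, d = d, mode = mode, labels = net$labels,
            class = c("curvature_table", "data.frame"))
}

#' @export
print.curvature_table <- function(x, ...) {
  cat(sprintf("curvature_table (d = %d, mode = %s): %d edges\n",
              attr(x, "d"), attr(x, "mode"), nrow(x)))
  if (nrow(x))
    cat(sprintf("  curvature: min %.4g, mean %.4g, max %.4g\n",
                min(x$curvature), mean(x$curvature), max(x$curvature)))
  NextMethod()
}

#' Agreement of the full and reduced curvature formulas
#'
#' The full parallel-edge curvature and its within-face reduction agree on
#' an edge whenever the graph has no hanging edges with respect to it.
#' This check runs in `"all_cycles"` mode, where faces exist for every
#' short cycle, so that the implication can be exercised on triangle-free
#' graphs as well (face weights do not affect the equality).
#'
#' @param net a [weighted_network()].
#' @param e an existing edge.
#' @param d face order (3, 4 or 5).
#' @param tol tolerance for declaring the two values equal.
#' @return a list with fields `has_hanging` (logical), `full`, `reduced`
#'   (the two curvature values) and `equal`.
#' @export
curvature_agreement <- function(net, e, d = 5, tol = 1e-9) {
  fs <- enumerate_faces(net, d = d, mode = "all_cycles")
  full <- forman_curvature_full(net, e, d = d, mode = "all_cycles", faces = fs)
  reduced <- forman_curvature(net, e, d = d, mode = "all_cycles", faces = fs)
  hang <- hanging_edges(net, e, d = d)
  equal <- abs(full - reduced) <= tol
  if (nrow(hang) == 0L && !equal)
    warning("no hanging edges, yet the two formulas disagree; please report")
  list(has_hanging = nrow(hang) > 0L, full = full, reduced = reduced,
       equal = equal)
}
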