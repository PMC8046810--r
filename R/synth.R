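# Seeded evaluation that leaves the caller's RNG stream untouched.
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Counter-based derivation of replicate seeds from a root seed; keeps
# values in the positive 32-bit integer range.
.derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                counter * 69621 + 1) %% 2147483647)
}

#' Random thresholded correlation network
#'
#' Generates an Erdos-Renyi graph G(n, p) with i.i.d. uniform edge weights
#' in `[weight_range[1], weight_range[2])`.  The default weight range
#' `[0.4, 1)` mirrors a correlation network after thresholding at 0.4, so
#' [sparsify()] at the default threshold is a no-op on these networks.
#'
#' @param n node count.
#' @param p edge probability in (0, 1].
#' @param weight_range length-2 numeric, `0 <= low < high <= 1`.
#' @param seed optional integer seed; the same seed reproduces the same
#'   network without disturbing the global RNG stream.
#' @param labels optional node labels (default `"n000"`, ...).
#' @return a [weighted_network()].
#' @export
random_weighted_network <- function(n, p, weight_range = c(0.4, 1),
                                    seed = NULL, labels = NULL) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  if (!(weight_range[1L] >= 0 && weight_range[1L] < weight_range[2L] &&
        weight_range[2L] <= 1))
    stop("need 0 <= weight_low < weight_high <= 1")
  .with_seed(seed, function() {
    W <- matrix(0, n, n)
    m <- n * (n - 1L) / 2
    on_edges <- stats::runif(m) < p
    w <- ifelse(on_edges,
                stats::runif(m, weight_range[1L], weight_range[2L]), 0)
    W[upper.tri(W)] <- w
    W <- W + t(W)
    weighted_network(W, labels = labels)
  })
}

#' Paired control/disease networks with a planted local anomaly
#'
#' Starts from a random control network and perturbs the neighbourhood of
#' one target edge to emulate a disease network: every edge incident to an
#' endpoint of the target (including the target itself) has its weight
#' multiplied by `effect` (clamped into the valid weight range), and up to
#' `k` triangle-closing edges through the target edge are added, so that
#' the target's face set -- and hence its 2-complex curvature -- changes
#' while the rest of the network is untouched.  The perturbation acts on
#' faces rather than on the bare edge weight because that is the regime in
#' which curvature differences detect what plain edge-weight differences
#' miss.
#'
#' The planted change must be attributable to the target edge for the
#' recovery task to be well posed, and in this curvature the positive
#' triangle terms of a new face are easily washed out by the parallel
#' (negative) terms of glued higher-order faces.  The default target is
#' therefore chosen as an edge with no pre-existing common neighbours (and
#' small endpoint degrees) for which enough *clean* recruits exist, and the
#' `k` recruited triangle-closing nodes are preferred to have no links into
#' the target's radius-1 neighbourhood and to be pairwise non-adjacent.
#' New edges take weights in the lowest decile of the weight range, the
#' signature of freshly appeared correlations just above threshold -- this
#' also keeps the planted triangles light, which maximises the target's
#' curvature response while barely moving its own edge weight (the regime
#' in which weight differences are blind but curvature differences are
#' not).
#'
#' @param n,p,weight_range,seed as in [random_weighted_network()].
#' @param target optional target edge (pair of labels or indices); must
#'   exist in the control network.  By default chosen as described above.
#' @param effect multiplicative effect size for the radius-1 weight
#'   perturbation; `effect = 1` leaves weights unchanged.
#' @param k number of triangle-closing node recruits: for each, the
#'   missing edges to the two target endpoints are added.
#' @return a list with components `control`, `disease` (both
#'   [weighted_network()]), `target` (character label pair) and
#'   `recruits` (labels of the recruited nodes).
#' @export
planted_pair <- function(n = 30, p = 0.2, target = NULL, effect = 1.5,
                         k = 3, weight_range = c(0.4, 1), seed = NULL) {
  .with_seed(seed, function() {
    control <- random_weighted_network(n, p, weight_range)
    W <- control$weights
    A <- W > 0
    el <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    if (nrow(el) == 0L) stop("control network has no edges; increase p")
    if (is.null(target)) {
      tgt <- .select_plant_target(A, el, k)
    } else {
      tgt <- .edge_idx(control, target)
      if (W[tgt[1L], tgt[2L]] <= 0) stop("target edge absent from control network")
    }
    u <- tgt[1L]; v <- tgt[2L]
    D <- W
    if (effect != 1) {
      hi <- weight_range[2L] - 1e-9
      for (s in c(u, v)) {
        nb <- which(D[s, ] > 0)
        D[s, nb] <- pmin(pmax(D[s, nb] * effect, weight_range[1L]), hi)
        D[nb, s] <- D[s, nb]
      }
    }
    pick <- integer(0)
    if (k > 0L) {
      pick <- .select_recruits(A, u, v, k)
      lo <- weight_range[1L]
      span <- 0.1 * (weight_range[2L] - weight_range[1L])
      for (w_ in pick) {
        for (s in c(u, v)) {
          if (D[s, w_] <= 0) {
            D[s, w_] <- stats::runif(1L, lo, lo + span)
            D[w_, s] <- D[s, w_]
          }
        }
      }
    }
    list(control = control,
         disease = weighted_network(D, labels = control$labels),
         target = control$labels[tgt],
         recruits = control$labels[pick])
  })
}

# Greedy set of up to k recruits for edge (u, v): nodes non-adjacent to
# both endpoints, ordered by number of links into the closed radius-1
# neighbourhood (clean recruits first), pairwise non-adjacent.
.select_recruits <- function(A, u, v, k) {
  nbhd <- c(which(A[u, ] | A[v, ]), u, v)
  cand <- setdiff(which(!A[u, ] & !A[v, ]), c(u, v))
  if (!length(cand)) cand <- setdiff(which(!(A[u, ] & A[v, ])), c(u, v))
  if (!length(cand)) return(integer(0))
  cross <- vapply(cand, function(w_) sum(A[w_, nbhd]), 0)
  cand <- cand[order(cross, sample.int(length(cand)))]
  pick <- integer(0)
  pool <- cand
  while (length(pool) && length(pick) < k) {
    w_ <- pool[1L]
    pick <- c(pick, w_)
    pool <- pool[!A[w_, pool] & pool != w_]
  }
  pick
}

# Default plant location: prefer edges with a full complement of clean
# recruits, then no common neighbours, then small endpoint degree.
.select_plant_target <- function(A, el, k) {
  deg <- colSums(A)
  cn <- vapply(seq_len(nrow(el)), function(r)
    sum(A[el[r, 1L], ] & A[el[r, 2L], ]), 0)
  clean <- vapply(seq_len(nrow(el)), function(r) {
    u <- el[r, 1L]; v <- el[r, 2L]
    nbhd <- c(which(A[u, ] | A[v, ]), u, v)
    cand <- setdiff(which(!A[u, ] & !A[v, ]), c(u, v))
    cand <- cand[vapply(cand, function(w_) sum(A[w_, nbhd]), 0) == 0]
    cnt <- 0L; pool <- cand
    while (length(pool) && cnt < k) {
      w_ <- pool[1L]; cnt <- cnt + 1L
      pool <- pool[!A[w_, pool] & pool != w_]
    }
    cnt
  }, 0L)
  score <- -pmin(clean, max(k, 1L)) * 1e6 + cn * 1e3 +
    deg[el[, 1L]] + deg[el[, 2L]]
  lo <- which(score == min(score))
  r <- lo[sample.int(length(lo), 1L)]
  c(el[r, 1L], el[r, 2L])
}

#' Named unit-weight fixture graphs
#'
#' Small graphs with known curvature behaviour, used throughout the test
#' suite and useful as worked examples: complete graphs, a star, a chorded
#' 4-cycle, a double star (two 3-stars joined at their centres), hypercubes
#' and complete multipartite graphs.  All edges have unit weight.
#'
#' @param name one of `"K3"`, `"K4"`, `"star13"`, `"chorded_C4"`,
#'   `"double_star"`, `"Q3"`, `"Q4"`, `"K22"`, `"K33"`, `"K222"`.
#' @return a [weighted_network()].
#' @export
fixture_network <- function(name) {
  edges <- switch(name,
    K3 = list(n = 3L, e = rbind(c(1, 2), c(1, 3), c(2, 3))),
    K4 = list(n = 4L, e = t(utils::combn(4L, 2L))),
    star13 = list(n = 4L, e = rbind(c(1, 2), c(1, 3), c(1, 4))),
    chorded_C4 = list(n = 4L,
                      e = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3))),
    double_star = list(n = 6L,
                       e = rbind(c(1, 2), c(1, 3), c(1, 4), c(4, 5), c(4, 6))),
    Q3 = .hypercube_edges(3L),
    Q4 = .hypercube_edges(4L),
    K22 = .multipartite_edges(c(2L, 2L)),
    K33 = .multipartite_edges(c(3L, 3L)),
    K222 = .multipartite_edges(c(2L, 2L, 2L)),
    stop("unknown fixture: ", name))
  W <- matrix(0, edges$n, edges$n)
  W[edges$e] <- 1
  W[edges$e[, c(2L, 1L)]] <- 1
  weighted_network(W, labels = sprintf("%s_%d", name, seq_len(edges$n) - 1L))
}

.hypercube_edges <- function(k) {
  n <- 2L^k
  pairs <- t(utils::combn(n, 2L))
  xo <- bitwXor(pairs[, 1L] - 1L, pairs[, 2L] - 1L)
  keep <- bitwAnd(xo, xo - 1L) == 0L   # xor is a power of two
  list(n = n, e = pairs[keep, , drop = FALSE])
}

.multipartite_edges <- function(parts) {
  n <- sum(parts)
  grp <- rep(seq_along(parts), parts)
  pairs <- t(utils::combn(n, 2L))
  keep <- grp[pairs[, 1L]] != grp[pairs[, 2L]]
  list(n = n, e = pairs[keep, , drop = FALSE])
}
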