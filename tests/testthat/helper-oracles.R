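# Independent oracles for the curvature computation, written deliberately
# without reusing the package's enumeration code paths.

# all permutations of a vector (tiny inputs only)
perms_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in perms_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  out
}

# every simple cycle of length 3..d, canonical (min node first, second
# node < last node), by brute-force subset + Hamiltonian permutation
oracle_cycles <- function(A, d) {
  n <- nrow(A)
  out <- list()
  if (n < 3L) return(out)
  for (k in 3:min(d, n)) {
    for (sub in utils::combn(n, k, simplify = FALSE)) {
      for (pm in perms_of(sub[-1L])) {
        cyc <- c(sub[1L], pm)
        if (cyc[2L] > cyc[k]) next
        if (all(A[cbind(cyc, c(cyc[-1L], cyc[1L]))])) {
          out[[length(out) + 1L]] <- cyc
        }
      }
    }
  }
  out
}

# all triangulations of a polygon (cycle node sequence) whose chords exist
# in A; anchored on the closing edge (last, first), unlike the package
oracle_triangulations <- function(poly, A) {
  k <- length(poly)
  if (k == 3L) return(list(list(sort(poly))))
  out <- list()
  pa <- poly[k]; pb <- poly[1L]
  for (m in 2:(k - 1L)) {
    pm <- poly[m]
    ok1 <- (m == 2L) || A[pb, pm]
    ok2 <- (m == k - 1L) || A[pm, pa]
    if (!ok1 || !ok2) next
    left <- poly[1:m]
    right <- poly[m:k]
    lt <- if (m >= 3L) oracle_triangulations(left, A) else list(list())
    rt <- if (k - m + 1L >= 3L) oracle_triangulations(right, A) else list(list())
    for (l in lt) for (r in rt) {
      out[[length(out) + 1L]] <- c(list(sort(c(pa, pb, pm))), l, r)
    }
  }
  out
}

# chordal-complex faces: one face per (cycle, triangulation) pair
oracle_chordal_faces <- function(net, d) {
  A <- net$weights > 0
  W <- net$weights
  tw <- function(t) (W[t[1L], t[2L]] + W[t[1L], t[3L]] + W[t[2L], t[3L]]) / 3
  faces <- list()
  for (cyc in oracle_cycles(A, d)) {
    k <- length(cyc)
    if (k == 3L) {
      faces[[length(faces) + 1L]] <-
        list(boundary = cyc, weight = tw(cyc))
    } else {
      for (tg in oracle_triangulations(cyc, A)) {
        faces[[length(faces) + 1L]] <-
          list(boundary = cyc, weight = sum(vapply(tg, tw, 0)))
      }
    }
  }
  faces
}

# literal term-by-term evaluation of the within-face curvature formula
oracle_curvature_map <- function(net, d) {
  W <- net$weights
  deg <- colSums(W > 0)
  nw <- ifelse(deg > 0, colSums(W) / pmax(deg, 1), 0)
  faces <- oracle_chordal_faces(net, d)
  el <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  out <- numeric(nrow(el))
  for (r in seq_len(nrow(el))) {
    u <- el[r, 1L]; v <- el[r, 2L]
    we <- W[u, v]
    sF <- 0; sP <- 0
    for (f in faces) {
      cyc <- f$boundary
      k <- length(cyc)
      bedges <- cbind(cyc, c(cyc[-1L], cyc[1L]))
      inface <- any((bedges[, 1L] == u & bedges[, 2L] == v) |
                      (bedges[, 1L] == v & bedges[, 2L] == u))
      if (!inface) next
      sF <- sF + we / f$weight
      for (q in seq_len(k)) {
        ep <- bedges[q, ]
        if (u %in% ep || v %in% ep) next
        sP <- sP + sqrt(we * W[ep[1L], ep[2L]]) / f$weight
      }
    }
    out[r] <- we * (sF + (nw[u] + nw[v]) / we - sP)
  }
  data.frame(u = net$labels[el[, 1L]], v = net$labels[el[, 2L]],
             curvature = out, stringsAsFactors = FALSE)
}

# exact transportation cost via the simplex method (boot), used as the
# independent oracle for the package's augmenting-path solver
lp_transport_cost <- function(cost, a, b) {
  m <- length(a); n <- length(b)
  A3 <- matrix(0, m + n, m * n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    A3[i, (j - 1L) * m + i] <- 1
    A3[m + j, (j - 1L) * m + i] <- 1
  }
  A3 <- A3[-(m + n), , drop = FALSE]   # drop the redundant balance row
  res <- boot::simplex(a = as.vector(cost), A3 = A3,
                       b3 = c(a, b)[-(m + n)], maxi = FALSE)
  unname(res$value)
}

# reweight a unit-weight fixture with random weights in [0.4, 1)
reweight <- function(net, seed) {
  W <- net$weights
  m <- sum(upper.tri(W) & W > 0)
  set.seed(seed)
  W[upper.tri(W) & W > 0] <- runif(m, 0.4, 1)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  weighted_network(W, labels = net$labels)
}

# compare two curvature tables edge-by-edge
expect_same_curvatures <- function(tab, ref, tol = 1e-9) {
  k1 <- paste(tab$u, tab$v)
  k2 <- paste(ref$u, ref$v)
  expect_setequal(k1, k2)
  expect_lt(max(abs(tab$curvature - ref$curvature[match(k1, k2)]), 0), tol)
}

tempfile_with_lines <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
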