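#' Node weight for curvature computations
#'
#' The weight of a node is the average weight of its incident edges;
#' isolated nodes get weight 0.
#'
#' @param net a [weighted_network()].
#' @param v node label or index; if `NULL`, the vector of all node weights
#'   is returned (named by label).
#' @return numeric scalar or named numeric vector.
#' @export
node_weight <- function(net, v = NULL) {
  W <- net$weights
  deg <- colSums(W > 0)
  str <- colSums(W)
  nw <- ifelse(deg > 0, str / pmax(deg, 1L), 0)
  names(nw) <- net$labels
  if (is.null(v)) return(nw)
  i <- if (is.numeric(v)) as.integer(v) else match(as.character(v), net$labels)
  if (anyNA(i) || any(i < 1L | i > length(net$labels)))
    stop("unknown node: ", paste(v, collapse = ", "))
  unname(nw[i])
}

# mean weight of a triangle given node indices
.tri_weight <- function(W, a, b, c) (W[a, b] + W[a, c] + W[b, c]) / 3

# canonical character key for an edge given two indices
.ekey <- function(i, j) {
  if (!length(i)) return(character(0))   # paste0 would coerce to ":"
  paste0(pmin(i, j), ":", pmax(i, j))
}

#' Enumerate the 2-faces of a network
#'
#' Builds the set of two-dimensional faces of order at most `d` used by the
#' order-d 2-complex curvature.  In `"chordal"` mode (the empirical
#' default) a face of order k > 3 is a simple boundary cycle of k nodes
#' together with a triangulation obtained by gluing k - 2 triangles of the
#' network along shared internal chords; a cycle that can be triangulated
#' in several ways yields one face per triangulation (set
#' `dedupe_cycles = TRUE` to keep only the lexicographically smallest
#' triangulation per boundary).  In `"all_cycles"` mode every simple cycle
#' of length at most `d` appears exactly once as a face, whether or not it
#' is chordal; this mode exists so that curvature identities that do not
#' depend on face weights can be checked on triangle-free graphs.
#'
#' Face weights: a triangle weighs the mean of its three edge weights; a
#' chordal face of higher order weighs the sum of its triangulation's
#' triangle weights; a non-chordal face (possible only in `"all_cycles"`
#' mode) weighs the mean of its boundary edge weights.
#'
#' An edge is incident to a face exactly when it is a *boundary* edge of
#' that face; internal chords contribute only through the face weight.
#'
#' @param net a [weighted_network()]; all existing edges must have positive
#'   weight (guaranteed by construction).
#' @param d maximal face order, one of 3, 4, 5.  Larger orders are refused:
#'   the enumeration cost grows as O(n^d).
#' @param mode `"chordal"` (default) or `"all_cycles"`, see above.
#' @param dedupe_cycles in chordal mode, keep a single face per boundary
#'   cycle (the one with the lexicographically smallest triangulation).
#' @return an object of class `face_set`: a list with elements `d`, `mode`,
#'   `n`, `faces` (list of faces, each with `order`, `boundary` (node index
#'   cycle), `tris` (list of index triples; empty for non-chordal faces)
#'   and `weight`) and `edge_faces` (named list mapping edge keys
#'   `"i:j"` with i < j to integer face ids, boundary incidence only).
#' @export
enumerate_faces <- function(net, d = 5, mode = c("chordal", "all_cycles"),
                            dedupe_cycles = FALSE) {
  mode <- match.arg(mode)
  if (!(d %in% 3:5))
    stop("d must be 3, 4 or 5: the cycle enumeration cost grows as O(n^d)")
  W <- net$weights
  A <- W > 0
  faces <- if (mode == "chordal") {
    .faces_chordal(A, W, d)
  } else {
    .faces_all_cycles(A, W, d)
  }
  if (dedupe_cycles && mode == "chordal") faces <- .dedupe_faces(faces)
  structure(list(d = d, mode = mode, n = nrow(W),
                 faces = faces, edge_faces = .edge_face_index(faces)),
            class = "face_set")
}

#' @export
print.face_set <- function(x, ...) {
  ords <- vapply(x$faces, `[[`, 0, "order")
  cat(sprintf("face_set (d = %d, mode = %s): %d faces\n",
              x$d, x$mode, length(x$faces)))
  if (length(ords)) print(table(order = ords))
  invisible(x)
}

# boundary edge matrix (k x 2) of a face, consecutive pairs of the cycle
.boundary_edges <- function(boundary) {
  k <- length(boundary)
  cbind(boundary, boundary[c(2:k, 1L)], deparse.level = 0L)
}

# index pairs of disjoint (non-adjacent) boundary edge positions, by order
.disjoint_positions <- function(k) {
  switch(as.character(k),
         "3" = matrix(integer(0), ncol = 2L),
         "4" = rbind(c(1L, 3L), c(2L, 4L)),
         "5" = rbind(c(1L, 3L), c(1L, 4L), c(2L, 4L), c(2L, 5L), c(3L, 5L)),
         stop("unsupported face order"))
}

.edge_face_index <- function(faces) {
  if (!length(faces)) return(list())
  keys <- character(0); ids <- integer(0)
  for (fi in seq_along(faces)) {
    be <- .boundary_edges(faces[[fi]]$boundary)
    keys <- c(keys, .ekey(be[, 1L], be[, 2L]))
    ids <- c(ids, rep.int(fi, nrow(be)))
  }
  split(ids, keys)
}

.new_face <- function(order, boundary, tris, weight) {
  list(order = order, boundary = boundary, tris = tris, weight = weight)
}

# ---- chordal enumeration: triangles merged along shared edges ------------

# All triangles (i < j < k) of the adjacency matrix, as a 3-column matrix.
.triangles <- function(A) {
  n <- nrow(A)
  out <- list()
  for (i in seq_len(n - 2L)) {
    ni <- which(A[i, ])
    ni <- ni[ni > i]
    if (length(ni) < 2L) next
    for (j in ni) {
      ks <- ni[ni > j & A[j, ni]]
      for (k in ks) out[[length(out) + 1L]] <- c(i, j, k)
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 3L))
  do.call(rbind, out)
}

.faces_chordal <- function(A, W, d) {
  faces <- list()
  tris <- .triangles(A)
  for (r in seq_len(nrow(tris))) {
    t <- tris[r, ]
    faces[[length(faces) + 1L]] <-
      .new_face(3L, t, list(t), .tri_weight(W, t[1L], t[2L], t[3L]))
  }
  if (d >= 4L) {
    # order-4 face: chord {a,b} plus two distinct apexes in CN(a, b);
    # boundary cycle a-x-b-y, triangulation {axb, ayb}
    n <- nrow(A)
    for (a in seq_len(n - 1L)) {
      nb <- which(A[a, ]); nb <- nb[nb > a]
      for (b in nb) {
        cn <- which(A[a, ] & A[b, ])
        if (length(cn) < 2L) next
        for (xi in seq_len(length(cn) - 1L)) {
          for (yi in seq.int(xi + 1L, length(cn))) {
            x <- cn[xi]; y <- cn[yi]
            w <- .tri_weight(W, a, b, x) + .tri_weight(W, a, b, y)
            faces[[length(faces) + 1L]] <-
              .new_face(4L, c(a, x, b, y),
                        list(sort(c(a, b, x)), sort(c(a, b, y))), w)
          }
        }
      }
    }
  }
  if (d >= 5L) {
    # order-5 face: middle triangle (h, s, t) with hub h shared by both
    # internal chords (h,s) and (h,t); apex x glued on (h,s), apex y on
    # (h,t); boundary cycle x-s-t-y-h
    for (r in seq_len(nrow(tris))) {
      tri <- tris[r, ]
      for (hi in 1:3) {
        h <- tri[hi]; mids <- tri[-hi]
        s <- mids[1L]; t <- mids[2L]   # s < t by triangle ordering
        xs <- which(A[h, ] & A[s, ])
        xs <- xs[!(xs %in% tri)]
        if (!length(xs)) next
        ys <- which(A[h, ] & A[t, ])
        ys <- ys[!(ys %in% tri)]
        for (x in xs) {
          for (y in ys) {
            if (y == x) next
            w <- .tri_weight(W, h, s, x) + .tri_weight(W, h, s, t) +
              .tri_weight(W, h, t, y)
            faces[[length(faces) + 1L]] <-
              .new_face(5L, c(x, s, t, y, h),
                        list(sort(c(h, s, x)), sort(c(h, s, t)),
                             sort(c(h, t, y))), w)
          }
        }
      }
    }
  }
  faces
}

.dedupe_faces <- function(faces) {
  if (!length(faces)) return(faces)
  bkey <- vapply(faces, function(f) .cycle_key(f$boundary), "")
  tkey <- vapply(faces, function(f)
    paste(vapply(f$tris, paste, "", collapse = "."), collapse = "|"), "")
  keep <- !logical(length(faces))
  for (grp in split(seq_along(faces), bkey)) {
    if (length(grp) > 1L) keep[grp[-which.min(rank(tkey[grp]))]] <- FALSE
  }
  faces[keep]
}

# canonical key of a cycle up to rotation and reflection
.cycle_key <- function(boundary) {
  k <- length(boundary)
  i0 <- which.min(boundary)
  fwd <- boundary[((i0 - 1L + seq_len(k) - 1L) %% k) + 1L]
  rev_ <- boundary[((i0 - 1L - (seq_len(k) - 1L)) %% k) + 1L]
  a <- paste(fwd, collapse = ",")
  b <- paste(rev_, collapse = ",")
  if (a < b) a else b
}

# ---- all-cycles enumeration ---------------------------------------------

# Every simple cycle of length 3..d, once, in canonical orientation
# (minimal node first, second node smaller than last).
.simple_cycles <- function(A, d) {
  n <- nrow(A)
  res <- list()
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ]))
  for (s in seq_len(n)) {
    path <- integer(d)
    path[1L] <- s
    inpath <- logical(n); inpath[s] <- TRUE
    dfs <- function(len) {
      last <- path[len]
      for (nx in nbrs[[last]]) {
        if (nx == s) {
          if (len >= 3L && path[2L] < last)
            res[[length(res) + 1L]] <<- path[seq_len(len)]
        } else if (nx > s && !inpath[nx] && len < d) {
          path[len + 1L] <<- nx
          inpath[nx] <<- TRUE
          dfs(len + 1L)
          inpath[nx] <<- FALSE
        }
      }
    }
    dfs(1L)
  }
  res
}

# All triangulations of a cycle (given as node sequence) whose chords exist
# in A; each triangulation is a list of sorted index triples.  Recursive
# polygon ear decomposition on the edge (poly[1], poly[2]).
.cycle_triangulations <- function(poly, A) {
  k <- length(poly)
  if (k == 3L) return(list(list(sort(poly))))
  out <- list()
  p1 <- poly[1L]; p2 <- poly[2L]
  for (m in 3:k) {
    pm <- poly[m]
    # triangle (p1, p2, pm) requires chords p2-pm and pm-p1 (boundary edges
    # when adjacent in the polygon)
    ok2 <- (m == 3L) || A[p2, pm]
    ok1 <- (m == k) || A[pm, p1]
    if (!ok2 || !ok1) next
    left <- poly[2:m]            # polygon p2..pm (closed by chord pm-p2)
    right <- poly[c(m:k, 1L)]    # polygon pm..pk,p1 (closed by chord p1-pm)
    lt <- if (length(left) >= 3L) .cycle_triangulations(left, A) else list(list())
    rt <- if (length(right) >= 3L) .cycle_triangulations(right, A) else list(list())
    for (l in lt) for (r in rt) {
      out[[length(out) + 1L]] <- c(list(sort(c(p1, p2, pm))), l, r)
    }
  }
  out
}

.faces_all_cycles <- function(A, W, d) {
  cycles <- .simple_cycles(A, d)
  faces <- vector("list", length(cycles))
  for (i in seq_along(cycles)) {
    cyc <- cycles[[i]]
    k <- length(cyc)
    if (k == 3L) {
      faces[[i]] <- .new_face(3L, cyc, list(sort(cyc)),
                              .tri_weight(W, cyc[1L], cyc[2L], cyc[3L]))
      next
    }
    tgs <- .cycle_triangulations(cyc, A)
    if (length(tgs)) {
      keys <- vapply(tgs, function(tg)
        paste(sort(vapply(tg, paste, "", collapse = ".")), collapse = "|"), "")
      tg <- tgs[[order(keys)[1L]]]
      w <- sum(vapply(tg, function(t) .tri_weight(W, t[1L], t[2L], t[3L]), 0))
      faces[[i]] <- .new_face(k, cyc, tg, w)
    } else {
      be <- .boundary_edges(cyc)
      faces[[i]] <- .new_face(k, cyc, list(), mean(W[be]))
    }
  }
  faces
}

# ---- local enumeration: chordal faces through one edge -------------------

# Faces of the chordal complex that contain edge (u, v) as a boundary
# edge.  Same face records as .faces_chordal, but only O(local) work.
.faces_through_edge <- function(A, W, u, v, d) {
  faces <- list()
  cn_uv <- which(A[u, ] & A[v, ])
  for (c in cn_uv) {
    t <- sort(c(u, v, c))
    faces[[length(faces) + 1L]] <-
      .new_face(3L, t, list(t), .tri_weight(W, u, v, c))
  }
  if (d >= 4L) {
    # e joins a chord endpoint and an apex: chord (a, b), apexes {x, y}
    for (swp in 1:2) {
      a <- if (swp == 1L) u else v   # chord endpoint on e
      x <- if (swp == 1L) v else u   # apex on e
      for (b in cn_uv) {
        ys <- which(A[a, ] & A[b, ])
        ys <- ys[ys != x]
        for (y in ys) {
          w <- .tri_weight(W, a, b, x) + .tri_weight(W, a, b, y)
          faces[[length(faces) + 1L]] <-
            .new_face(4L, c(a, x, b, y),
                      list(sort(c(a, b, x)), sort(c(a, b, y))), w)
        }
      }
    }
  }
  if (d >= 5L) {
    add5 <- function(h, s, t, x, y) {
      w <- .tri_weight(W, h, s, x) + .tri_weight(W, h, s, t) +
        .tri_weight(W, h, t, y)
      faces[[length(faces) + 1L]] <<-
        .new_face(5L, c(x, s, t, y, h),
                  list(sort(c(h, s, x)), sort(c(h, s, t)),
                       sort(c(h, t, y))), w)
    }
    # case A: e = {s, t}, the two non-hub vertices of the middle triangle
    for (h in cn_uv) {
      s <- u; t <- v
      xs <- which(A[h, ] & A[s, ]); xs <- xs[!(xs %in% c(h, s, t))]
      ys <- which(A[h, ] & A[t, ]); ys <- ys[!(ys %in% c(h, s, t))]
      for (x in xs) for (y in ys) if (y != x) add5(h, s, t, x, y)
    }
    for (swp in 1:2) {
      # case B: e = {h, x}, hub plus the apex glued on chord (h, s)
      h <- if (swp == 1L) u else v
      x <- if (swp == 1L) v else u
      ss <- which(A[h, ] & A[x, ])
      for (s in ss) {
        ts <- which(A[h, ] & A[s, ]); ts <- ts[ts != x & ts != h]
        for (t in ts) {
          ys <- which(A[h, ] & A[t, ])
          ys <- ys[!(ys %in% c(s, x, h, t))]
          for (y in ys) add5(h, s, t, x, y)
        }
      }
      # case C: e = {x, s}, apex plus its gluing mid vertex
      xx <- if (swp == 1L) u else v
      s <- if (swp == 1L) v else u
      hs <- which(A[xx, ] & A[s, ])
      for (h in hs) {
        ts <- which(A[h, ] & A[s, ]); ts <- ts[ts != xx & ts != h]
        for (t in ts) {
          ys <- which(A[h, ] & A[t, ])
          ys <- ys[!(ys %in% c(xx, s, h, t))]
          for (y in ys) add5(h, s, t, xx, y)
        }
      }
    }
  }
  faces
}

# ---- hanging edges, parallel edges, sequence count ----------------------

#' Hanging edges with respect to an edge
#'
#' An edge `e'` adjacent to `e` (sharing exactly one endpoint) is a hanging
#' edge of order `d` when no simple cycle with at most `d` edges contains
#' both `e` and `e'`.  Absence of hanging edges is exactly the condition
#' under which the full and the within-face curvature formulas coincide;
#' see [curvature_agreement()].
#'
#' @param net a [weighted_network()].
#' @param e an edge, as a pair of labels or node indices; must exist.
#' @param d cycle length bound.
#' @return data frame with columns `u`, `v` (labels) listing the hanging
#'   edges; zero rows when there are none.
#' @export
hanging_edges <- function(net, e, d = 5) {
  idx <- .edge_idx(net, e)
  W <- net$weights
  if (W[idx[1L], idx[2L]] <= 0)
    stop("edge does not exist: ", paste(net$labels[idx], collapse = ", "))
  A <- W > 0
  out <- list()
  for (swp in 1:2) {
    s <- idx[swp]            # shared endpoint of e and e'
    other_e <- idx[3L - swp] # far endpoint of e
    for (o in which(A[s, ])) {
      if (o == other_e) next
      # cycle of <= d edges through e and e' = {s, o} exists iff there is a
      # path from o to other_e of <= d - 2 edges avoiding s
      if (!.bfs_reachable(A, from = o, to = other_e, avoid = s,
                          max_len = d - 2L)) {
        out[[length(out) + 1L]] <- sort(c(s, o))
      }
    }
  }
  if (!length(out))
    return(data.frame(u = character(0), v = character(0),
                      stringsAsFactors = FALSE))
  m <- unique(do.call(rbind, out))
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  data.frame(u = net$labels[m[, 1L]], v = net$labels[m[, 2L]],
             stringsAsFactors = FALSE)
}

# breadth-first reachability with a hop bound, excluding node `avoid`
.bfs_reachable <- function(A, from, to, avoid, max_len) {
  if (max_len < 1L) return(FALSE)
  n <- nrow(A)
  seen <- logical(n)
  seen[c(from, avoid)] <- TRUE
  frontier <- from
  depth <- 0L
  while (length(frontier) && depth < max_len) {
    depth <- depth + 1L
    nxt <- integer(0)
    for (x in frontier) {
      nb <- which(A[x, ] & !seen)
      if (to %in% nb) return(TRUE)
      seen[nb] <- TRUE
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  FALSE
}

#' Parallel edges of an edge in the 2-complex
#'
#' Two edges are parallel when they share a common immediate predecessor
#' (an endpoint) or a common immediate successor (a 2-face having both as
#' boundary edges) in the face partial order, but not both.
#' `formula = "within_face"` restricts to parallel edges co-bounding a face
#' with `e` (which then cannot share an endpoint with `e`) and reports one
#' row per (edge, face) incidence, as consumed by the reduced curvature
#' formula.  `formula = "global"` applies the shared-endpoint XOR
#' shared-face rule and reports each qualifying edge once.
#'
#' @param net a [weighted_network()].
#' @param e an edge (pair of labels or indices).
#' @param faces a [enumerate_faces()] result for `net`.
#' @param formula `"within_face"` or `"global"`.
#' @return data frame with columns `u`, `v` and, for `"within_face"`,
#'   `face` (integer face id in `faces$faces`).
#' @export
parallel_edges <- function(net, e, faces,
                           formula = c("within_face", "global")) {
  formula <- match.arg(formula)
  if (!inherits(faces, "face_set") || faces$n != length(net$labels))
    stop("faces must be a face_set computed on the same network")
  idx <- .edge_idx(net, e)
  key <- .ekey(idx[1L], idx[2L])
  fids <- faces$edge_faces[[key]]
  if (formula == "within_face") {
    rows <- list()
    for (fi in fids) {
      f <- faces$faces[[fi]]
      be <- .boundary_edges(f$boundary)
      for (r in seq_len(nrow(be))) {
        ep <- sort(be[r, ])
        if (!any(ep %in% idx)) {
          rows[[length(rows) + 1L]] <- c(ep, fi)
        }
      }
    }
    if (!length(rows))
      return(data.frame(u = character(0), v = character(0),
                        face = integer(0), stringsAsFactors = FALSE))
    m <- do.call(rbind, rows)
    data.frame(u = net$labels[m[, 1L]], v = net$labels[m[, 2L]],
               face = m[, 3L], stringsAsFactors = FALSE)
  } else {
    A <- net$weights > 0
    shared_face <- character(0)
    for (fi in fids) {
      be <- .boundary_edges(faces$faces[[fi]]$boundary)
      keys <- .ekey(be[, 1L], be[, 2L])
      shared_face <- union(shared_face, setdiff(keys, key))
    }
    adj <- character(0)
    for (swp in 1:2) {
      s <- idx[swp]
      nb <- which(A[s, ]); nb <- nb[nb != idx[3L - swp]]
      adj <- union(adj, .ekey(rep.int(s, length(nb)), nb))
    }
    par <- union(setdiff(adj, shared_face), setdiff(shared_face, adj))
    if (!length(par))
      return(data.frame(u = character(0), v = character(0),
                        stringsAsFactors = FALSE))
    m <- do.call(rbind, lapply(strsplit(par, ":", fixed = TRUE),
                               function(s) as.integer(s)))
    m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
    data.frame(u = net$labels[m[, 1L]], v = net$labels[m[, 2L]],
               stringsAsFactors = FALSE)
  }
}

#' Count ordered node sequences of bounded length
#'
#' Closed-form count of ordered sequences of at most `d - 3` distinct nodes
#' drawn from a pool of `n - 3` nodes:
#' \deqn{\Lambda = \sum_{j=1}^{d-3} \binom{n-3}{j}\, j!}
#' This is the number of candidate internal paths that must all be broken
#' for an adjacent edge pair to have no short cycle through it, and so
#' measures how unlikely hanging edges are in dense networks.
#'
#' @param n node count, at least 3.
#' @param d face order, at least 4.
#' @return the count as a double (exact for moderate `n`, `d`).
#' @export
sequence_count <- function(n, d) {
  if (n < 3 || d < 4) stop("need n >= 3 and d >= 4")
  j <- seq_len(d - 3)
  sum(choose(n - 3, j) * factorial(j))
}
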