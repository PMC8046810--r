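#' Uniform neighbourhood distribution of a node
#'
#' The probability measure placing mass `1/deg(v)` on every neighbour of
#' `v` (zero idleness, unweighted).  This is the classical choice in
#' Ollivier-type curvature for graphs and reproduces the known edge
#' curvature range `[-2, 1]`.
#'
#' @param net a [weighted_network()].
#' @param v node label or index with degree at least 1.
#' @return an object of class `neighbor_distribution`: list with fields
#'   `center` (label) and `support` (named numeric vector of masses).
#' @export
neighbor_distribution <- function(net, v) {
  i <- if (is.numeric(v)) as.integer(v) else match(as.character(v), net$labels)
  if (is.na(i) || i < 1L || i > length(net$labels)) stop("unknown node: ", v)
  nb <- which(net$weights[i, ] > 0)
  if (!length(nb)) stop("isolated node has no neighbourhood distribution: ",
                        net$labels[i])
  mass <- rep(1 / length(nb), length(nb))
  names(mass) <- net$labels[nb]
  structure(list(center = net$labels[i], support = mass),
            class = "neighbor_distribution")
}

# hop distances from node `from` to all nodes (BFS); Inf when unreachable
.hop_distances <- function(A, from) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  dist[from] <- 0
  frontier <- from
  hop <- 0L
  while (length(frontier)) {
    hop <- hop + 1L
    nxt <- integer(0)
    for (x in frontier) {
      nb <- which(A[x, ] & !is.finite(dist))
      dist[nb] <- hop
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  dist
}

#' L1 Wasserstein distance between two node distributions
#'
#' Exact optimal-transport cost between two probability measures on the
#' nodes of a network, under the hop-count (shortest-path) ground metric.
#' The transportation problem is solved exactly by successive shortest
#' augmenting paths with integer arc costs, so the optimum is certified
#' rather than approximated; sign decisions near zero depend on this
#' exactness.
#'
#' @param net a [weighted_network()].
#' @param mu,nu [neighbor_distribution()] objects (or named mass vectors
#'   summing to one) supported on nodes of a common connected component.
#' @return the optimal transport cost (numeric scalar).
#' @export
wasserstein1 <- function(net, mu, nu) {
  a <- .as_mass(net, mu); b <- .as_mass(net, nu)
  if (abs(sum(a$mass) - 1) > 1e-9 || abs(sum(b$mass) - 1) > 1e-9)
    stop("masses must each sum to 1")
  A <- net$weights > 0
  cost <- matrix(0, length(a$nodes), length(b$nodes))
  for (r in seq_along(a$nodes)) {
    dall <- .hop_distances(A, a$nodes[r])
    cost[r, ] <- dall[b$nodes]
  }
  if (any(!is.finite(cost)))
    stop("supports lie in different connected components; W1 is infinite")
  .min_cost_transport(cost, a$mass, b$mass)$cost
}

.as_mass <- function(net, m) {
  if (inherits(m, "neighbor_distribution")) m <- m$support
  if (is.null(names(m))) stop("distribution must be a named mass vector")
  nodes <- match(names(m), net$labels)
  if (anyNA(nodes)) stop("distribution supported on unknown nodes")
  if (any(m < 0)) stop("negative mass")
  keep <- m > 0
  list(nodes = nodes[keep], mass = unname(m[keep]))
}

# Exact transportation problem via successive shortest augmenting paths
# (Bellman-Ford on the bipartite residual network).  Costs are finite
# non-negative; supplies and demands are positive and balanced.
.min_cost_transport <- function(cost, supply, demand, tol = 1e-12) {
  m <- length(supply); n <- length(demand)
  stopifnot(nrow(cost) == m, ncol(cost) == n)
  flow <- matrix(0, m, n)
  rs <- supply; rd <- demand
  total <- 0
  it <- 0L
  while (sum(rs) > tol) {
    it <- it + 1L
    if (it > 1000L * (m + n))
      stop("transport solver failed to converge")   # should be unreachable
    # Bellman-Ford from all unsaturated sources over residual arcs
    ds <- ifelse(rs > tol, 0, Inf)   # source potentials
    dd <- rep(Inf, n)
    pred_s <- rep(NA_integer_, n)    # best source feeding each sink
    pred_d <- rep(NA_integer_, m)    # best sink refunding each source
    repeat {
      changed <- FALSE
      for (j in seq_len(n)) {
        v <- ds + cost[, j]
        bi <- which.min(v)
        if (v[bi] + 1e-15 < dd[j]) { dd[j] <- v[bi]; pred_s[j] <- bi; changed <- TRUE }
      }
      for (i in seq_len(m)) {
        back <- which(flow[i, ] > tol)
        if (length(back)) {
          v <- dd[back] - cost[i, back]
          bj <- which.min(v)
          if (v[bj] + 1e-15 < ds[i]) {
            ds[i] <- v[bj]; pred_d[i] <- back[bj]; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    open <- which(rd > tol)
    j <- open[which.min(dd[open])]
    if (!is.finite(dd[j])) stop("no augmenting path; unbalanced transport problem")
    # trace the shortest-path tree back to a source whose distance came
    # from initialisation (pred_d[i] is NA exactly for those)
    path <- list()   # arcs as c(i, j, dir): dir +1 forward, -1 backward
    cur_j <- j
    steps <- 0L
    repeat {
      steps <- steps + 1L
      if (steps > 2L * (m + n) + 4L)
        stop("transport solver: predecessor trace failed")  # defensive
      i <- pred_s[cur_j]
      path[[length(path) + 1L]] <- c(i, cur_j, 1)
      if (is.na(pred_d[i])) break
      cur_j <- pred_d[i]
      path[[length(path) + 1L]] <- c(i, cur_j, -1)
    }
    delta <- min(rd[j], rs[path[[length(path)]][1L]])
    for (arc in path) if (arc[3L] < 0) delta <- min(delta, flow[arc[1L], arc[2L]])
    for (arc in path) {
      i <- arc[1L]; jj <- arc[2L]
      if (arc[3L] > 0) {
        flow[i, jj] <- flow[i, jj] + delta
        total <- total + delta * cost[i, jj]
      } else {
        flow[i, jj] <- flow[i, jj] - delta
        total <- total - delta * cost[i, jj]
      }
    }
    src <- path[[length(path)]][1L]
    rs[src] <- rs[src] - delta
    rd[j] <- rd[j] - delta
  }
  list(cost = total, plan = flow, iterations = it)
}

#' Ollivier-Ricci curvature of an edge
#'
#' \eqn{\kappa(e) = 1 - W_1(m_u, m_v)} for an edge e = \{u, v\}, where
#' `m_x` is the uniform neighbourhood distribution of `x` and the ground
#' distance is the hop metric (so `dist(u, v) = 1` for an edge).  The
#' value lies in `[-2, 1]`.
#'
#' @param net a [weighted_network()].
#' @param e an existing edge with non-isolated endpoints.
#' @return a numeric scalar in `[-2, 1]`.
#' @export
ollivier_curvature <- function(net, e) {
  idx <- .edge_idx(net, e)
  if (net$weights[idx[1L], idx[2L]] <= 0)
    stop("edge does not exist: ", paste(net$labels[idx], collapse = ", "))
  mu <- neighbor_distribution(net, idx[1L])
  nu <- neighbor_distribution(net, idx[2L])
  1 - wasserstein1(net, mu, nu)
}

#' Search for sign disagreements between the two curvatures
#'
#' Scans curated fixtures and random weighted graphs, recording one
#' witness edge for every realised combination of
#' (sign of 2-complex curvature, sign of Ollivier-Ricci curvature).
#' The two notions of curvature are known not to determine each other's
#' sign; this search exhibits the phenomenon empirically.  Edges where
#' either curvature is exactly zero are skipped (the sign is undefined at
#' zero).
#'
#' @param n_max maximal node count of the random graphs.
#' @param d face order for the 2-complex curvature (at least 5; smaller
#'   orders see too few faces for negative curvature to arise).
#' @param budget number of random graphs to examine.
#' @param seed integer seed for the random graph stream.
#' @param include_fixtures start from the named fixtures (`"K3"`,
#'   `"double_star"`, ...) before random search.
#' @return an object of class `sign_search`: list with `witnesses` (data
#'   frame with columns `sign_forman`, `sign_ollivier`, `source`, `u`,
#'   `v`, `forman`, `ollivier`), `networks` (the witness networks, named
#'   by sign combination, e.g. `"+1/-1"`), and `graphs_examined`.
#' @export
sign_disagreement_search <- function(n_max = 8, d = 5, budget = 10000,
                                     seed = 1, include_fixtures = TRUE) {
  if (d < 5) stop("d must be at least 5")
  found <- list()
  rows <- list()
  examined <- 0L
  consider <- function(net, source_name) {
    tab <- curvature_map(net, d = d, mode = "chordal")
    for (r in seq_len(nrow(tab))) {
      cf <- tab$curvature[r]
      if (cf == 0) next
      co <- ollivier_curvature(net, c(tab$u[r], tab$v[r]))
      if (co == 0) next
      key <- paste0(ifelse(cf > 0, "+1", "-1"), "/", ifelse(co > 0, "+1", "-1"))
      if (is.null(found[[key]])) {
        found[[key]] <<- net
        rows[[key]] <<- data.frame(
          sign_forman = sign(cf), sign_ollivier = sign(co),
          source = source_name, u = tab$u[r], v = tab$v[r],
          forman = cf, ollivier = co, stringsAsFactors = FALSE)
      }
      if (length(found) == 4L) return(TRUE)
    }
    FALSE
  }
  done <- FALSE
  if (include_fixtures) {
    for (fx in c("K3", "double_star", "star13", "chorded_C4", "K222")) {
      if (consider(fixture_network(fx), fx)) { done <- TRUE; break }
    }
  }
  if (!done && budget > 0) {
    for (g in seq_len(budget)) {
      net <- .with_seed(.derive_seed(seed, g), function() {
        n <- sample(4:n_max, 1L)
        p <- stats::runif(1L, 0.3, 0.9)
        random_weighted_network(n, p)
      })
      examined <- examined + 1L
      if (n_edges(net) == 0L) next
      if (consider(net, sprintf("random_%d", g))) break
    }
  }
  witnesses <- if (length(rows)) do.call(rbind, rows[order(names(rows))])
  else data.frame(sign_forman = numeric(0), sign_ollivier = numeric(0),
                  source = character(0), u = character(0), v = character(0),
                  forman = numeric(0), ollivier = numeric(0))
  rownames(witnesses) <- NULL
  if (length(found)) found <- found[order(names(found))]
  structure(list(witnesses = witnesses,
                 networks = found,
                 graphs_examined = examined),
            class = "sign_search")
}

#' @export
print.sign_search <- function(x, ...) {
  cat(sprintf("sign_search: %d sign combination(s) after %d random graphs\n",
              nrow(x$witnesses), x$graphs_examined))
  if (nrow(x$witnesses)) print(x$witnesses)
  invisible(x)
}
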