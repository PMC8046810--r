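#' Degree-preserving randomisation with a pinned node pair
#'
#' Markov-chain double-edge-swap randomisation: repeatedly picks two edges
#' \{a, b\} and \{c, d\} with four distinct endpoints uniformly at random
#' and proposes the rewiring \{a, d\}, \{c, b\} (the pairing is chosen at
#' random between the two possibilities).  A proposal is rejected when it
#' would create a duplicate edge, or when it would delete or create the
#' pinned pair, so the pinned pair's existence status and weight are
#' preserved exactly.  Weights travel with the rewired pairing
#' (`w(a, d) <- w(a, b)`, `w(c, b) <- w(c, d)`), so the degree sequence
#' and the multiset of edge weights are preserved exactly; node strengths
#' are not.  Accepted swaps count towards `n_swaps`; a proposal cap of
#' `100 * n_swaps` guarantees termination on rigid graphs.
#'
#' @param net a [weighted_network()].
#' @param pinned optional node pair (labels or indices) whose relation
#'   (edge present with its weight, or absent) must be preserved.
#' @param n_swaps number of accepted swaps; defaults to five times the
#'   edge count, a customary mixing length for this chain.
#' @param seed optional integer seed.
#' @return a new [weighted_network()] with attributes `swaps_performed`
#'   and `proposals`.
#' @export
edge_swap_randomize <- function(net, pinned = NULL, n_swaps = NULL,
                                seed = NULL) {
  W <- net$weights
  E <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  m <- nrow(E)
  if (is.null(n_swaps)) n_swaps <- 5L * m
  if (n_swaps < 0) stop("n_swaps must be non-negative")
  pin <- if (!is.null(pinned)) .edge_idx(net, pinned)
  if (n_swaps == 0L || m < 2L) {
    out <- net
    attr(out, "swaps_performed") <- 0L
    attr(out, "proposals") <- 0L
    return(out)
  }
  if (!.has_two_independent_edges(E)) {
    warning("fewer than 2 independent edges: network returned unchanged")
    out <- net
    attr(out, "swaps_performed") <- 0L
    attr(out, "proposals") <- 0L
    return(out)
  }
  .with_seed(seed, function() {
    eu <- unname(E[, 1L]); ev <- unname(E[, 2L])
    accepted <- 0L; proposals <- 0L
    cap <- 100 * n_swaps
    while (accepted < n_swaps && proposals < cap) {
      proposals <- proposals + 1L
      pick <- sample.int(m, 2L)
      a <- eu[pick[1L]]; b <- ev[pick[1L]]
      c_ <- eu[pick[2L]]; d_ <- ev[pick[2L]]
      if (stats::runif(1L) < 0.5) { tmp <- c_; c_ <- d_; d_ <- tmp }
      # proposed rewiring: {a,b},{c,d} -> {a,d},{c,b}
      if (length(unique(c(a, b, c_, d_))) < 4L) next
      if (a == d_ || c_ == b) next
      if (W[a, d_] > 0 || W[c_, b] > 0) next
      if (!is.null(pin)) {
        if (identical(sort(c(a, b)), pin) || identical(sort(c(c_, d_)), pin))
          next   # would delete the pinned pair
        if (identical(sort(c(a, d_)), pin) || identical(sort(c(c_, b)), pin))
          next   # would create it
      }
      wab <- W[a, b]; wcd <- W[c_, d_]
      W[a, b] <- 0; W[b, a] <- 0
      W[c_, d_] <- 0; W[d_, c_] <- 0
      W[a, d_] <- wab; W[d_, a] <- wab
      W[c_, b] <- wcd; W[b, c_] <- wcd
      eu[pick[1L]] <- min(a, d_); ev[pick[1L]] <- max(a, d_)
      eu[pick[2L]] <- min(c_, b); ev[pick[2L]] <- max(c_, b)
      accepted <- accepted + 1L
    }
    out <- weighted_network(W, labels = net$labels)
    attr(out, "swaps_performed") <- accepted
    attr(out, "proposals") <- proposals
    out
  })
}

.has_two_independent_edges <- function(E) {
  m <- nrow(E)
  if (m < 2L) return(FALSE)
  for (i in seq_len(m - 1L)) {
    disjoint <- E[-seq_len(i), 1L] != E[i, 1L] & E[-seq_len(i), 1L] != E[i, 2L] &
      E[-seq_len(i), 2L] != E[i, 1L] & E[-seq_len(i), 2L] != E[i, 2L]
    if (any(disjoint)) return(TRUE)
  }
  FALSE
}

#' Null ensemble of curvature differences for one edge
#'
#' Builds the null distribution of the curvature difference at an edge
#' under degree-preserving randomisation: in each of `R` replicates, both
#' input networks are independently randomised with the edge's endpoints
#' pinned, and the curvature difference at the edge is recorded.  The
#' observed difference is then standardised against these samples.
#' Replicate seeds are derived from the root seed by a counter scheme, so
#' results are reproducible and replicates independent.
#'
#' @param control,disease [weighted_network()] objects on the same labels.
#' @param e the edge (pair of labels or indices) under test.
#' @param d,mode curvature order and face mode, see [forman_curvature()].
#' @param R number of replicates (at least 2; 100 is customary).
#' @param swap_factor accepted swaps per replicate as a multiple of the
#'   network's edge count.
#' @param seed integer root seed.
#' @return an object of class `null_ensemble`: list with `edge`,
#'   `observed`, `samples` (length `R`), `z` (`NA` when the null has zero
#'   variance), `significant` (`|z| >= 2`), `seed`, `swaps_performed`
#'   (total accepted swaps over all chains).
#' @export
null_delta_ensemble <- function(control, disease, e, d = 5,
                                mode = c("chordal", "all_cycles"), R = 100,
                                swap_factor = 5, seed = NULL) {
  mode <- match.arg(mode)
  if (R < 2) stop("R must be at least 2")
  if (!identical(control$labels, disease$labels)) stop("label mismatch")
  idx <- .edge_idx(control, e)
  observed <- forman_curvature(control, idx, d = d, mode = mode) -
    forman_curvature(disease, idx, d = d, mode = mode)
  n1 <- max(1L, round(swap_factor * n_edges(control)))
  n2 <- max(1L, round(swap_factor * n_edges(disease)))
  samples <- numeric(R)
  swaps_total <- 0L
  root <- if (is.null(seed)) stats::runif(1L, 1, 2^30) else seed
  for (j in seq_len(R)) {
    g1 <- edge_swap_randomize(control, pinned = idx, n_swaps = n1,
                              seed = .derive_seed(root, 2L * j - 1L))
    g2 <- edge_swap_randomize(disease, pinned = idx, n_swaps = n2,
                              seed = .derive_seed(root, 2L * j))
    swaps_total <- swaps_total + attr(g1, "swaps_performed") +
      attr(g2, "swaps_performed")
    samples[j] <- forman_curvature(g1, idx, d = d, mode = mode) -
      forman_curvature(g2, idx, d = d, mode = mode)
  }
  z <- z_score(observed, samples)
  structure(list(edge = control$labels[idx], observed = observed,
                 samples = samples, z = z,
                 significant = is.finite(z) && abs(z) >= 2,
                 seed = seed, swaps_performed = swaps_total),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble for edge {%s, %s}: R = %d replicates\n",
              x$edge[1L], x$edge[2L], length(x$samples)))
  cat(sprintf("  observed delta %.4g; null mean %.4g, sd %.4g\n",
              x$observed, mean(x$samples),
              sqrt(mean((x$samples - mean(x$samples))^2))))
  if (is.na(x$z)) cat("  z undefined (zero-variance null)\n")
  else cat(sprintf("  z = %.1f%s\n", x$z,
                   if (x$significant) "  (|z| >= 2: significant)" else ""))
  invisible(x)
}

#' Z-score of an observation against null samples
#'
#' Standard score with the population standard deviation of the samples
#' (the replicates are the whole null ensemble).  Returns `NA` when the
#' samples have zero variance, since the score is undefined there.
#'
#' @param observed observed value.
#' @param samples numeric vector of at least 2 null replicates.
#' @return numeric scalar or `NA`.
#' @export
z_score <- function(observed, samples) {
  if (length(samples) < 2L) stop("need at least 2 null samples")
  mu <- mean(samples)
  sdev <- sqrt(mean((samples - mu)^2))
  if (sdev == 0) return(NA_real_)
  (observed - mu) / sdev
}
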