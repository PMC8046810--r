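---
title: "Curvature-based anomaly detection in weighted networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-based anomaly detection in weighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcurv)
```

## The problem

Given two snapshots of a weighted undirected network on a fixed node set —
in the motivating application, mean functional-connectivity matrices of a
healthy cohort and a patient cohort over 200 parcellated brain regions —
we want the node pairs whose *local higher-order structure* changed most.
Plain edge-weight differences see only the pair itself; a curvature-style
edge statistic also sees the triangles and short glued-triangle cycles an
edge participates in, and therefore reacts to rewiring of the local
mesoscale even when the edge's own weight barely moves.

## The curvature

`netcurv` assigns each edge the order-$d$ 2-complex Forman–Ricci
curvature.  The 2-complex is built on top of the graph by topological
association: nodes are 0-faces, edges are 1-faces, and the 2-faces of
order $k \le d$ are simple $k$-cycles that can be assembled by gluing
$k-2$ triangles of the graph along shared internal chords ("chordal"
cycles).  Weights extend the edge weights $\omega(e)$ (correlations):

* node: $\omega(v) = \frac{1}{\deg v}\sum_{e \ni v} \omega(e)$,
* triangle: mean of its three edge weights,
* order-$k$ face ($k > 3$): sum of the triangle weights of its gluing.

An edge is incident to a face only through the face's *boundary* cycle;
internal chords contribute only via the face weight.  The working formula
for an edge $e = \{u, v\}$ with $\omega(e) > 0$ is

$$
C(e) \;=\; \omega(e)\left[
\sum_{f \ni e} \frac{\omega(e)}{\omega(f)}
+ \sum_{x \sim e} \frac{\omega(x)}{\omega(e)}
- \sum_{\substack{e' \parallel e \\ e, e' \in f}}
  \frac{\sqrt{\omega(e)\,\omega(e')}}{\omega(f)}
\right],
$$

where the parallel sum runs over boundary edges $e'$ disjoint from $e$
within each shared face.  This is the computationally tractable
restriction of a more general formula in which the parallel relation
ranges over *all* edges sharing an endpoint or a face with $e$ — but not
both — each contributing an absolute-value term
(`forman_curvature_full()`).  The two coincide on any edge that has no
*hanging edges*: adjacent edges lying on no common simple cycle of length
at most $d$ (`hanging_edges()`, `curvature_agreement()`).  Hypercubes,
complete bipartite graphs with parts of size at least two ($d \ge 4$),
and complete multipartite graphs are hanging-edge-free, and the test
suite verifies the equality on them under random weight assignments; a
star graph shows the strict inequality.  The equality is also invariant
to rescaling all face weights, which the suite checks directly.

```{r}
k3 <- fixture_network("K3")
forman_curvature(k3, c(1, 2))         # 3.0 by hand
curvature_agreement(fixture_network("star13"), c(1, 2))[c("full", "reduced")]
```

### Face conventions

Two design points were genuinely open and are fixed as follows:

* **A multiply-triangulable cycle counts once per triangulation.**  The
  faces are constructed by gluing triangles, so the gluing — not just the
  boundary — is the object; a 4-cycle with both chords contributes two
  order-4 faces.  `enumerate_faces(..., dedupe_cycles = TRUE)` keeps only
  the lexicographically smallest triangulation per boundary for
  sensitivity analysis.
* **`all_cycles` mode.**  Under the chordal restriction, triangle-free
  graphs have no faces at all, which would make the hanging-edge
  equivalence vacuous there.  `mode = "all_cycles"` therefore lists every
  simple cycle of length $\le d$ exactly once as a face (non-chordal
  faces weigh the mean of their boundary edges — harmless, because the
  equivalence does not depend on face weights).  The empirical pipeline
  always uses `chordal`.

Enumeration is by sorted-adjacency triangle intersection and
chord-anchored merging (order-4: one chord and two apexes; order-5: a
middle triangle, a hub, and two glued apexes), never by generic cycle
search; $d$ is capped at 5 because the cost grows as $O(n^d)$.  A naive
oracle — brute-force cycle enumeration by subset and permutation,
followed by literal term-by-term evaluation — pins the optimized path on
every connected graph with up to 6 nodes and on random weighted graphs in
the test suite, to $10^{-9}$.

## Anomaly detection

`curvature_anomaly(control, disease)` computes the curvature of every
edge in both networks ($d = 5$, chordal) and the per-edge difference
$\Delta_e = C_{\mathrm{control}}(e) - C_{\mathrm{disease}}(e)$ over the
union of the edge sets (absent pairs have curvature 0 by convention).
Outliers are the edges with $|\Delta_e|$ above a cutoff; the default
`"auto"` cutoff is twice the *population* standard deviation of the
$\Delta_e$ set — the edge set is the whole population of interest, not a
sample.  For comparability with the edge-weight baseline
$\Lambda_e = \omega_1(e) - \omega_2(e) \in [-1, 1]$, the differences are
also normalised by the linear map
$\eta(\Delta) = (2\Delta - \mathrm{high} - \mathrm{low}) /
(\mathrm{high} - \mathrm{low})$ onto $[-1, 1]$ (degenerate constant case:
all zero).

```{r}
pair <- planted_pair(n = 20, p = 0.25, effect = 1.5, k = 2, seed = 42)
fit <- curvature_anomaly(pair$control, pair$disease)
fit
pair$target
```

## Statistical significance

For a focal edge, `null_delta_ensemble()` builds the null distribution of
$\Delta_e$ under degree-preserving randomisation: each replicate
independently rewires both networks by random double edge swaps
($\{a,b\}, \{c,d\} \to \{a,d\}, \{c,b\}$, random orientation, proposals
creating duplicates rejected) while *pinning* the focal pair — the tested
edge is never created or destroyed and keeps its weight — and records the
replicate difference.  The observed $\Delta_e$ is standardised against
the replicates (population standard deviation); $|z| \ge 2$ is flagged.
Defaults follow common practice: $5|E|$ accepted swaps per chain and 100
replicates.  Swap counting uses *accepted* swaps, with a proposal cap of
$100\times$ the target to guarantee termination on rigid graphs (a
single triangle, say, admits no valid swap and is returned unchanged with
a warning).  Weights travel with the rewired pairing, so the degree
sequence and the weight multiset are preserved exactly; node *strength*
is not preserved — a known limitation of weighted double-edge swaps.
Replicate seeds derive from the root seed by a counter scheme, so runs
are reproducible.

The test suite calibrates the machinery end to end: when the "disease"
network is itself an independent randomisation of the control network,
the fraction of tested edges flagged at $|z| \ge 2$ over 200 seeded edge
tests (one $G(24, 0.2)$ network, $R = 30$ replicates per test — sizes
chosen so the whole suite stays fast) must fall in $[0.01, 0.10]$.

## The Ollivier–Ricci comparator

The package also computes the classical Ollivier–Ricci edge curvature
$\kappa(e) = 1 - W_1(m_u, m_v)$, with $m_x$ the uniform distribution on
the neighbours of $x$ (zero idleness) and $W_1$ the exact optimal
transport cost under the hop metric.  This variant is a deliberate,
documented choice: it reproduces the known range $[-2, 1]$ for edge
curvature; a weighted variant is out of scope.  $W_1$ is solved exactly
by successive shortest augmenting paths on the bipartite transportation
network (integer arc costs), never by entropic approximation — sign
decisions near zero require exactness — and the solver is cross-checked
against an independent simplex LP oracle in the tests.

The two curvature notions do not determine each other's sign.
`sign_disagreement_search()` exhibits this empirically: it scans curated
fixtures (a triangle gives $(+,+)$, a double-star bridge $(+,-)$) and
random weighted graphs with at most `n_max` nodes, recording a witness
per realised sign combination; edges with curvature exactly zero are
excluded, the sign being undefined there.  The acceptance suite requires
at least three of the four combinations within a 10,000-graph budget.

## Synthetic data

The generators emulate *thresholded correlation networks*: symmetric,
zero diagonal, edge weights i.i.d. uniform on $[0.4, 1)$ — the regime
after the customary 0.4 sparsification threshold, so `sparsify()` is a
no-op on synthetic data.  They do not emulate per-subject sampling
variability, spatial autocorrelation of parcels, or the negative tail of
raw correlations; passing tests therefore demonstrate correctness of the
machinery on threshold-like topologies, not fidelity to fMRI noise.

`planted_pair()` plants a localised anomaly: all weights within radius 1
of a target edge are rescaled by `effect` (clamped to the valid range)
and `k` recruited nodes close new triangles through the target.  Two
design points matter and were settled by analysis of the curvature's
structure:

* the default target is an edge with **no pre-existing common
  neighbours**, low endpoint degree, and a full complement of clean
  recruits — otherwise the new triangles immediately glue with existing
  ones into order-4/5 faces whose parallel terms cancel the planted
  triangle terms, and the perturbation leaks into bystander edges;
* recruits prefer nodes with **no links into the target's radius-1
  neighbourhood** and are pairwise non-adjacent; new edges draw weights
  from the lowest decile of the weight range (fresh correlations just
  above threshold), which maximises the target's curvature response while
  barely moving its own weight — exactly the regime where the
  edge-weight baseline $\Lambda_e$ is blind and $\Delta_e$ is not.

With this construction, the planted edge attains the top $|\Delta_e|$
rank; the acceptance suite demands recovery in at least 19 of 20 seeded
pairs at $n = 30$, $p = 0.2$, effect $1.5$, $k = 3$.

## Numerical choices and degenerate inputs

* Accumulation is plain double arithmetic in a deterministic (sorted)
  order; reruns are bit-reproducible.
* Symmetry of input matrices is enforced to $10^{-9}$ on ingest (opt-in
  averaging for marginally asymmetric files); the diagonal is always
  zeroed; negative correlations survive loading and are removed by
  `sparsify()`, whose threshold applies *after* cohort averaging.
* Isolated nodes have node weight 0; zero-weight pairs have curvature 0
  without touching the face enumeration; a face of non-positive weight
  signals corrupt input and errors.
* `z_score()` returns `NA` on a zero-variance null (undefined score);
  `normalize_deltas()` maps a constant difference set to 0.
* Ties in outlier ranking break lexicographically by label pair, so
  reports are stable across platforms.

## Known limitations

* Faces stop at order 5 and dimension 2; higher orders and $k$-complexes
  are future work, and the full parallel-relation formula is practical
  only on small graphs.
* The null model randomises topology but not the weight-to-edge
  assignment beyond swap transport; node strengths drift.
* The Ollivier variant is fixed (uniform, zero idleness, hop metric);
  other idleness or ground metrics would change $\kappa$ and its sign
  pattern.
* Headline connectome analyses require the external UCLA matrices; the
  package ships only the nine-row focal-edge reference table for
  arithmetic consistency checks.
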